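# deterministic small fixtures used across test files

rand_gray <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

rand_mask <- function(h, w, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(h * w, 1, p), h, w)
}

# dark ridge of given thickness along a row, on a bright background
ridge_image <- function(n = 32, row = n %/% 2, bg = 200L, fg = 80L) {
  img <- matrix(bg, n, n)
  img[row, ] <- fg
  storage.mode(img) <- "integer"
  img
}

# direct (loop-based) between-class variance, independent of the package path
bcv_oracle <- function(g, tv) {
  mu_T <- sum((0:255) * g)
  bounds <- c(-1, tv, 255)
  total <- 0
  for (j in seq_len(length(bounds) - 1)) {
    bins <- seq(bounds[j] + 1, bounds[j + 1])
    if (bounds[j] + 1 > bounds[j + 1]) next
    w <- sum(g[bins + 1])
    if (w == 0) next
    mu <- sum(bins * g[bins + 1]) / w
    total <- total + w * (mu - mu_T)^2
  }
  total
}
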