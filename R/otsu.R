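#' Normalized 256-bin gray-level histogram
#'
#' Computes the relative frequency `g(m)` of each gray level `m = 0..255`.
#' This histogram is the sole input of the multilevel Otsu objective.
#'
#' @param img 8-bit integer grayscale matrix.
#' @return Object of class `gray_histogram`: list with `g` (length-256
#'   numeric summing to 1) and `n_pixels`.
#' @export
gray_histogram <- function(img) {
  assert_gray8(img)
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  structure(list(g = counts / length(img), n_pixels = length(img)),
            class = "gray_histogram")
}

#' Construct a histogram object from frequencies
#'
#' @param g Length-256 non-negative vector (normalized internally).
#' @param n_pixels Pixel count the frequencies refer to.
#' @export
as_gray_histogram <- function(g, n_pixels = 1L) {
  g <- as.numeric(g)
  if (length(g) != 256L) stop("g must have 256 bins")
  if (any(g < 0) || any(!is.finite(g))) stop("g must be finite and non-negative")
  s <- sum(g)
  if (s <= 0) stop("histogram has zero total mass")
  structure(list(g = g / s, n_pixels = as.integer(n_pixels)),
            class = "gray_histogram")
}

# validate a threshold vector: sorted distinct integers in [0, 254]
assert_thresholds <- function(tv) {
  if (length(tv) < 1) stop("at least one threshold required")
  if (any(tv != floor(tv)) || any(tv < 0) || any(tv > 254))
    stop("thresholds must be integers in [0, 254]")
  if (any(diff(tv) <= 0)) stop("thresholds must be strictly increasing")
  invisible(TRUE)
}

#' Between-class variance of a thresholded histogram
#'
#' The multilevel Otsu objective: with thresholds `t_1 < ... < t_Dim`
#' partitioning gray levels into `K = Dim + 1` classes (class `j` spans
#' `t_j < m <= t_{j+1}`, with `t_0 = -1`, `t_K = 255`),
#' `sigma_B^2 = sum_j w_j (mu_j - mu_T)^2` where `w_j` and `mu_j` are the
#' class probability and mean gray level and `mu_T` the global mean.
#' Empty classes contribute 0.
#'
#' @param h A `gray_histogram`.
#' @param tv Integer threshold vector (strictly increasing, in `[0, 254]`).
#' @return The between-class variance (non-negative scalar).
#' @export
between_class_variance <- function(h, tv) {
  stopifnot(inherits(h, "gray_histogram"))
  assert_thresholds(tv)
  g <- h$g
  s0 <- cumsum(g)                      # prefix mass
  s1 <- cumsum((0:255) * g)            # prefix first moment
  mu_T <- s1[256]
  # class j spans bins (lo_j .. hi_j) in 0-based gray levels
  hi <- c(tv, 255L) + 1L               # 1-based prefix index of class ends
  lo <- c(0L, tv + 1L)                 # 0-based class starts
  w  <- s0[hi] - c(0, s0[hi])[seq_along(hi)]
  m1 <- s1[hi] - c(0, s1[hi])[seq_along(hi)]
  nz <- w > 0
  sum(w[nz] * (m1[nz] / w[nz] - mu_T)^2)
}

# total histogram variance
total_variance <- function(h) {
  g <- h$g
  mu <- sum((0:255) * g)
  sum(g * ((0:255) - mu)^2)
}

#' Weighted within-class variance
#'
#' Companion of [between_class_variance()]; for any threshold vector the
#' decomposition `sigma_B^2 + sigma_W^2 = sigma_T^2` holds exactly.
#'
#' @inheritParams between_class_variance
#' @export
within_class_variance <- function(h, tv) {
  stopifnot(inherits(h, "gray_histogram"))
  assert_thresholds(tv)
  g <- h$g
  bounds <- c(-1L, as.integer(tv), 255L)
  total <- 0
  for (j in seq_len(length(bounds) - 1L)) {
    bins <- (bounds[j] + 1L):bounds[j + 1L]
    if (bounds[j] + 1L > bounds[j + 1L]) next
    w <- sum(g[bins + 1L])
    if (w <= 0) next
    mu <- sum(bins * g[bins + 1L]) / w
    total <- total + sum(g[bins + 1L] * (bins - mu)^2)
  }
  total
}

# class score matrix W[a+1, b+1] = (sum_{m=a}^{b} m g)^2 / (sum g) for
# 0-based gray levels a <= b; 0 for massless spans
class_score_matrix <- function(g) {
  s0 <- c(0, cumsum(g))
  s1 <- c(0, cumsum((0:255) * g))
  W <- matrix(0, 256, 256)
  for (a in 1:256) {
    b <- a:256
    m0 <- s0[b + 1L] - s0[a]
    m1 <- s1[b + 1L] - s1[a]
    v <- numeric(length(b))
    nz <- m0 > 0
    v[nz] <- m1[nz]^2 / m0[nz]
    W[a, b] <- v
  }
  W
}

#' Globally optimal multilevel Otsu thresholds
#'
#' Exact maximizer of [between_class_variance()] over all strictly
#' increasing integer threshold vectors, used as the oracle against which
#' the swarm searches are judged. Ties are broken by the lexicographically
#' smallest threshold vector. `method = "auto"` enumerates exhaustively for
#' `dim <= 2` and switches to an exact dynamic program (identical optimum,
#' same tie-break) for larger `dim`; `"exhaustive"` forces enumeration
#' (supported for `dim <= 3`), `"dp"` forces the dynamic program.
#'
#' @param h A `gray_histogram`.
#' @param dim Number of thresholds (1--7).
#' @param method One of `"auto"`, `"exhaustive"`, `"dp"`.
#' @return List with `thresholds` (integer vector) and `sigma_b2`.
#' @export
brute_force_optimal <- function(h, dim, method = c("auto", "exhaustive", "dp")) {
  stopifnot(inherits(h, "gray_histogram"))
  method <- match.arg(method)
  dim <- as.integer(dim)
  if (dim < 1L || dim > 7L) stop("dim must be in [1, 7]")
  occupied <- sum(h$g > 0)
  if (occupied < dim + 1L)
    warning("histogram has ", occupied, " occupied bins for ", dim + 1L,
            " classes; optimum will contain empty classes")
  g <- h$g
  mu_T <- sum((0:255) * g)
  if (method == "auto") method <- if (dim <= 2L) "exhaustive" else "dp"
  if (method == "exhaustive" && dim > 3L)
    stop("exhaustive enumeration supported for dim <= 3; use method = \"dp\"")
  W <- class_score_matrix(g)
  res <- if (method == "exhaustive") bf_exhaustive(W, dim) else bf_dp(W, dim)
  list(thresholds = res$thresholds,
       sigma_b2 = max(res$score - mu_T^2, 0))
}

# exhaustive enumeration over thresholds, ascending order -> first max is
# the lexicographically smallest optimum
bf_exhaustive <- function(W, dim) {
  best <- -Inf; best_tv <- NULL
  if (dim == 1L) {
    t1 <- 0:254
    v <- W[1, t1 + 1L] + W[cbind(t1 + 2L, 256L)]
    i <- which.max(v)
    return(list(thresholds = t1[i], score = v[i]))
  }
  if (dim == 2L) {
    for (t1 in 0:253) {
      t2 <- (t1 + 1L):254L
      v <- W[1, t1 + 1L] + W[cbind(t1 + 2L, t2 + 1L)] + W[cbind(t2 + 2L, 256L)]
      i <- which.max(v)
      if (v[i] > best) { best <- v[i]; best_tv <- c(t1, t2[i]) }
    }
    return(list(thresholds = best_tv, score = best))
  }
  for (t1 in 0:252) {
    w1 <- W[1, t1 + 1L]
    for (t2 in (t1 + 1L):253L) {
      t3 <- (t2 + 1L):254L
      v <- w1 + W[t1 + 2L, t2 + 1L] + W[cbind(t2 + 2L, t3 + 1L)] +
        W[cbind(t3 + 2L, 256L)]
      i <- which.max(v)
      if (v[i] > best) { best <- v[i]; best_tv <- c(t1, t2, t3[i]) }
    }
  }
  list(thresholds = best_tv, score = best)
}

# exact DP: B_k[s] = best score partitioning 0-based bins (s-1)..255 into k
# classes; split chosen smallest-first on ties, so greedy left-to-right
# reconstruction yields the lexicographically smallest optimal vector
bf_dp <- function(W, dim) {
  K <- dim + 1L
  B <- matrix(-Inf, nrow = K, ncol = 256)  # B[k, s]: s = 1-based start bin
  choice <- matrix(NA_integer_, nrow = K, ncol = 256)
  B[1, ] <- W[, 256]
  if (K >= 2) {
    for (k in 2:K) {
      # first class may end at e = s .. 255-(k-1) (1-based end bin)
      for (s in 1:(256 - k + 1L)) {
        e <- s:(256 - k + 1L)
        v <- W[s, e] + B[k - 1L, e + 1L]
        i <- which.max(v)  # first max = smallest split
        B[k, s] <- v[i]
        choice[k, s] <- e[i]
      }
    }
  }
  tv <- integer(dim)
  s <- 1L
  for (j in seq_len(dim)) {
    k <- K - j + 1L
    e <- choice[k, s]
    tv[j] <- e - 1L    # threshold = 0-based end bin of the class
    s <- e + 1L
  }
  list(thresholds = tv, score = B[K, 1])
}

#' Assign class labels by thresholding
#'
#' Label `j` (0-based) is assigned where `t_j < value <= t_{j+1}` with
#' `t_0 = -1` and `t_{Dim+1} = 255`, matching the class convention of the
#' between-class-variance objective.
#'
#' @param img 8-bit integer grayscale matrix.
#' @param tv Threshold vector.
#' @return Integer matrix of labels `0..Dim` with the shape of `img`.
#' @export
apply_thresholds <- function(img, tv) {
  assert_gray8(img)
  assert_thresholds(tv)
  lab <- findInterval(img, tv + 0.5)
  dim(lab) <- dim(img)
  storage.mode(lab) <- "integer"
  lab
}

#' Replace every pixel by its class mean gray level
#'
#' Produces the piecewise-constant reconstruction used when comparing the
#' image before and after segmentation (PSNR/SSIM/FSIM).
#'
#' @inheritParams apply_thresholds
#' @return 8-bit integer matrix; each pixel holds the rounded mean gray
#'   level of its threshold class.
#' @export
reconstruct_classes <- function(img, tv) {
  lab <- apply_thresholds(img, tv)
  out <- img
  for (j in unique(as.vector(lab))) {
    idx <- lab == j
    out[idx] <- round_half_up(mean(img[idx]))
  }
  storage.mode(out) <- "integer"
  out
}
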