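#' Configuration for the synthetic vessel phantom
#'
#' Defaults emulate the green channel of a fundus photograph: a bright,
#' mildly noisy background with a smooth illumination gradient, and dark
#' vessel trees with Gaussian cross-section profiles whose FWHM masks cover
#' roughly 5% of the field (a fundus-benchmark-like class imbalance).
#'
#' @param size `c(H, W)` in pixels.
#' @param n_trees Number of vessel trees seeded at the image border.
#' @param branch_prob Per-step branching probability of a growing vessel.
#' @param vessel_sigma_range Range of per-segment cross-section scales
#'   (pixels).
#' @param vessel_contrast Intensity drop of a vessel center below the
#'   background (gray levels).
#' @param background_level Mean background intensity (gray levels).
#' @param illumination_gradient Peak-to-peak amplitude of a linear
#'   illumination ramp (gray levels).
#' @param noise_sigma Gaussian pixel noise standard deviation (gray
#'   levels).
#' @param seed Integer seed making the phantom fully reproducible.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(size = c(256, 256), n_trees = 4,
                           branch_prob = 0.02,
                           vessel_sigma_range = c(1.0, 2.5),
                           vessel_contrast = 70, background_level = 170,
                           illumination_gradient = 25, noise_sigma = 8,
                           seed = 1) {
  if (any(size < 32)) stop("phantom size must be at least 32x32")
  if (vessel_contrast <= 0) stop("vessel_contrast must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (diff(vessel_sigma_range) < 0) stop("vessel_sigma_range must be ordered")
  structure(as.list(environment()), class = "phantom_config")
}

# stamp a Gaussian cross-section disc (max-combined) centered at (y, x)
stamp_profile <- function(canvas, y, x, sigma) {
  H <- nrow(canvas); W <- ncol(canvas)
  r <- ceiling(2.5 * sigma)
  ylo <- max(1, round(y) - r); yhi <- min(H, round(y) + r)
  xlo <- max(1, round(x) - r); xhi <- min(W, round(x) + r)
  if (ylo > yhi || xlo > xhi) return(canvas)
  yy <- ylo:yhi; xx <- xlo:xhi
  d2 <- outer((yy - y)^2, (xx - x)^2, "+")
  canvas[yy, xx] <- pmax(canvas[yy, xx], exp(-d2 / (2 * sigma^2)))
  canvas
}

#' Generate a synthetic fundus vessel phantom with ground truth
#'
#' Random branching vessel trees are grown from the image border as random
#' walks; each segment is rendered as a tube with a Gaussian cross-section
#' (scale drawn from `vessel_sigma_range`, shrinking towards branch tips).
#' The image is `background + illumination ramp + noise - contrast *
#' profile`, clipped to `[0, 255]`; the ground-truth mask marks pixels
#' within the full-width-at-half-maximum of a centerline profile
#' (`|d| <= sigma sqrt(2 ln 2)`), the standard caliber definition for
#' Gaussian vessel cross-sections. Bit-identical for identical
#' configurations.
#'
#' @param cfg A [phantom_config()].
#' @return Object of class `phantom`: list with `image` (8-bit integer
#'   matrix, vessels dark), `mask` (0/1 integer matrix) and `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  H <- cfg$size[1]; W <- cfg$size[2]
  profile <- matrix(0, H, W)   # vessel intensity profile in [0, 1]
  coremask <- matrix(0L, H, W) # within the profile FWHM of a centerline
  hwhm <- sqrt(2 * log(2))     # half-width at half-maximum, in sigmas
  stamp_mask <- function(y, x, sigma) {
    r <- ceiling(hwhm * sigma)
    ylo <- max(1, round(y) - r); yhi <- min(H, round(y) + r)
    xlo <- max(1, round(x) - r); xhi <- min(W, round(x) + r)
    if (ylo > yhi || xlo > xhi) return()
    yy <- ylo:yhi; xx <- xlo:xhi
    d2 <- outer((yy - y)^2, (xx - x)^2, "+")
    coremask[yy, xx] <<- pmax(coremask[yy, xx],
                              (d2 <= (hwhm * sigma)^2) * 1L)
  }
  # growth queue: each element (y, x, angle, sigma, budget)
  queue <- list()
  for (t in seq_len(cfg$n_trees)) {
    side <- sample(4, 1)
    pos <- switch(side,
      c(1, runif(1, 1, W), pi / 2),            # top edge, heading down
      c(H, runif(1, 1, W), -pi / 2),           # bottom edge, heading up
      c(runif(1, 1, H), 1, 0),                 # left edge, heading right
      c(runif(1, 1, H), W, pi))                # right edge, heading left
    sigma <- runif(1, mean(cfg$vessel_sigma_range), cfg$vessel_sigma_range[2])
    queue[[length(queue) + 1]] <-
      list(y = pos[1], x = pos[2], ang = pos[3], sigma = sigma,
           budget = round(0.7 * max(H, W)), depth = 0L)
  }
  while (length(queue) > 0) {
    seg <- queue[[1]]; queue[[1]] <- NULL
    y <- seg$y; x <- seg$x; ang <- seg$ang; sigma <- seg$sigma
    for (step in seq_len(seg$budget)) {
      profile <- stamp_profile(profile, y, x, sigma)
      stamp_mask(y, x, sigma)
      ang <- ang + rnorm(1, 0, 0.12)
      y <- y + sin(ang); x <- x + cos(ang)
      if (y < 1 || y > H || x < 1 || x > W) break
      if (seg$depth < 2L && runif(1) < cfg$branch_prob) {
        child_sigma <- max(cfg$vessel_sigma_range[1] * 0.8, sigma * 0.75)
        queue[[length(queue) + 1]] <-
          list(y = y, x = x, ang = ang + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
               sigma = child_sigma, budget = round((seg$budget - step) * 0.5),
               depth = seg$depth + 1L)
      }
      sigma <- max(cfg$vessel_sigma_range[1] * 0.8, sigma * 0.999)
    }
  }
  ramp <- matrix(seq(-0.5, 0.5, length.out = W), H, W, byrow = TRUE) *
    cfg$illumination_gradient
  noise <- matrix(rnorm(H * W, 0, cfg$noise_sigma), H, W)
  img <- cfg$background_level + ramp + noise - cfg$vessel_contrast * profile
  img <- round_half_up(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  structure(list(image = img, mask = coremask, config = cfg),
            class = "phantom")
}

#' Seeded random multimodal histogram
#'
#' Mixture of discretized Gaussians over the first `n_bins` gray levels
#' (padded with zeros to 256 bins), normalized to sum to 1; the standard
#' fixture for optimizer-vs-oracle tests.
#'
#' @param n_modes Number of mixture components (1--6).
#' @param n_bins Support width (`<= 256`).
#' @param seed Optional integer seed.
#' @return A `gray_histogram`.
#' @export
generate_histogram <- function(n_modes = 3, n_bins = 64, seed = NULL) {
  if (n_modes < 1 || n_modes > 6) stop("n_modes must be in [1, 6]")
  if (n_bins < 2 || n_bins > 256) stop("n_bins must be in [2, 256]")
  if (!is.null(seed)) set.seed(seed)
  bins <- 0:(n_bins - 1)
  wts <- runif(n_modes, 0.2, 1); wts <- wts / sum(wts)
  g <- numeric(256)
  for (k in seq_len(n_modes)) {
    mu <- runif(1, 0.05, 0.95) * (n_bins - 1)
    sdv <- runif(1, n_bins / 40, n_bins / 10)
    g[bins + 1] <- g[bins + 1] + wts[k] * exp(-(bins - mu)^2 / (2 * sdv^2))
  }
  as_gray_histogram(g, n_pixels = 1L)
}
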