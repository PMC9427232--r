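#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(255^2 / MSE)` over all pixels. Identical images have
#' zero MSE and return `Inf` (serialized as `null` in JSON reports).
#'
#' @param m,n Same-shape matrices on the 0--255 scale.
#' @param max_i Dynamic range (255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(m, n, max_i = 255) {
  assert_same_shape(m, n)
  mse <- mean((as.numeric(m) - as.numeric(n))^2)
  if (mse == 0) return(Inf)
  10 * log10(max_i^2 / mse)
}

#' Global-statistics structural similarity (SSIM)
#'
#' Luminance, contrast and structure factors computed from whole-image
#' means, standard deviations (denominator `H*W - 1`) and covariance; the
#' product `l*c*s` is returned. This is the single-window (global) form,
#' not the sliding-window variant.
#'
#' @param m,n Same-shape matrices on the 0--255 scale.
#' @param k1,k2 Stability constants (0.01, 0.03).
#' @param s_range Dynamic range `S` (255 for 8-bit).
#' @export
ssim <- function(m, n, k1 = 0.01, k2 = 0.03, s_range = 255) {
  assert_same_shape(m, n)
  b1 <- (k1 * s_range)^2
  b2 <- (k2 * s_range)^2
  b3 <- b2 / 2
  x <- as.numeric(m); y <- as.numeric(n)
  mu_x <- mean(x); mu_y <- mean(y)
  sd_x <- sd(x); sd_y <- sd(y)       # H*W - 1 denominator
  cov_xy <- sum((x - mu_x) * (y - mu_y)) / (length(x) - 1)
  l <- (2 * mu_x * mu_y + b1) / (mu_x^2 + mu_y^2 + b1)
  cc <- (2 * sd_x * sd_y + b2) / (sd_x^2 + sd_y^2 + b2)
  ss <- (cov_xy + b3) / (sd_x * sd_y + b3)
  l * cc * ss
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks return 1 by convention.
#'
#' @param a,b Binary masks (logical, 0/1, or 0/255).
#' @export
dice <- function(a, b) {
  a <- as_binary_mask(a, "a"); b <- as_binary_mask(b, "b")
  assert_same_shape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Jaccard index of two binary masks
#'
#' `|A n B| / |A u B|`; two empty masks return 1 by convention. Related to
#' Dice by `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @export
jaccard <- function(a, b) {
  a <- as_binary_mask(a, "a"); b <- as_binary_mask(b, "b")
  assert_same_shape(a, b)
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Pixelwise confusion counts of a predicted vessel mask
#'
#' @param gt,pred Binary masks (ground truth, prediction); 1 = vessel.
#' @return List with `Tp`, `TN`, `Fp`, `FN` (sums to the pixel count).
#' @export
confusion <- function(gt, pred) {
  gt <- as_binary_mask(gt, "gt"); pred <- as_binary_mask(pred, "pred")
  assert_same_shape(gt, pred)
  list(Tp = sum(gt == 1 & pred == 1), TN = sum(gt == 0 & pred == 0),
       Fp = sum(gt == 0 & pred == 1), FN = sum(gt == 1 & pred == 0))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Se = Tp/(Tp+FN)`, `Sp = TN/(TN+Fp)`, `Acc = (Tp+TN)/total`; a zero
#' denominator yields `NA` (serialized as `null`).
#'
#' @param cc List as returned by [confusion()].
#' @export
se_sp_acc <- function(cc) {
  tot <- cc$Tp + cc$TN + cc$Fp + cc$FN
  list(
    sensitivity = if (cc$Tp + cc$FN > 0) cc$Tp / (cc$Tp + cc$FN) else NA_real_,
    specificity = if (cc$TN + cc$Fp > 0) cc$TN / (cc$TN + cc$Fp) else NA_real_,
    accuracy = if (tot > 0) (cc$Tp + cc$TN) / tot else NA_real_
  )
}

#' Shannon entropy of a label image
#'
#' `H = -sum P_i log2 P_i` over the class proportions of the segmentation,
#' in bits; maximal (`log2 K`) for equal classes, 0 for a single class.
#'
#' @param labels Integer label matrix (e.g. from [apply_thresholds()]).
#' @export
shannon_entropy <- function(labels) {
  if (length(labels) < 1) stop("empty label image")
  p <- as.numeric(table(as.vector(labels))) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Region uniformity of a segmentation
#'
#' `U_R = 1 - (1/I) sum_k sum_{s in R_k} (gray_s - mean_k)^2 /
#' (max_k - min_k)^2`, summed over segmentation regions `R_k`; a region
#' with `max_k = min_k` contributes 0. The normalizer `I` defaults to the
#' total pixel count.
#'
#' @param img Grayscale matrix the segmentation was computed on.
#' @param labels Same-shape label matrix.
#' @param norm Normalizing constant `I` (default `length(img)`).
#' @export
region_uniformity <- function(img, labels, norm = length(img)) {
  assert_same_shape(img, labels)
  total <- 0
  for (j in unique(as.vector(labels))) {
    v <- as.numeric(img[labels == j])
    rng <- max(v) - min(v)
    if (rng == 0) next
    total <- total + sum((v - mean(v))^2) / rng^2
  }
  1 - total / norm
}

# ---- FSIM ------------------------------------------------------------------

# log-Gabor / angular-spread filter bank in the frequency domain.
# Returns a list of n_scale x n_orient filters (H x W matrices).
log_gabor_bank <- function(H, W, n_scale = 4, n_orient = 4,
                           min_wavelength = 6, mult = 2, sigma_onf = 0.55) {
  fx <- ((0:(W - 1)) - floor(W / 2)) / W
  fy <- ((0:(H - 1)) - floor(H / 2)) / H
  u <- matrix(fx, H, W, byrow = TRUE)
  v <- matrix(fy, H, W)
  radius <- sqrt(u^2 + v^2)
  radius[floor(H / 2) + 1, floor(W / 2) + 1] <- 1  # avoid log(0) at DC
  theta <- atan2(-v, u)
  sintheta <- sin(theta); costheta <- cos(theta)
  ifftshift2 <- function(m) {
    m[c((floor(H / 2) + 1):H, 1:floor(H / 2)),
      c((floor(W / 2) + 1):W, 1:floor(W / 2))]
  }
  theta_sigma <- pi / n_orient / 1.2
  filters <- vector("list", n_scale * n_orient)
  k <- 1
  for (o in seq_len(n_orient)) {
    ang <- (o - 1) * pi / n_orient
    ds <- sintheta * cos(ang) - costheta * sin(ang)
    dc <- costheta * cos(ang) + sintheta * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    for (s in seq_len(n_scale)) {
      wavelength <- min_wavelength * mult^(s - 1)
      f0 <- 1 / wavelength
      lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2))
      lg[floor(H / 2) + 1, floor(W / 2) + 1] <- 0
      filters[[k]] <- ifftshift2(lg * spread)
      k <- k + 1
    }
  }
  list(filters = filters, n_scale = n_scale, n_orient = n_orient)
}

#' Phase congruency map
#'
#' Frequency-domain feature-strength measure: for each orientation the
#' log-Gabor quadrature responses are summed over scales and the local
#' energy is normalized by the total response amplitude; orientations are
#' pooled additively. Values lie in `[0, 1]`; edges and ridges score high
#' regardless of contrast.
#'
#' @param img Grayscale matrix (any scale).
#' @param n_scale,n_orient,min_wavelength,mult,sigma_onf Log-Gabor bank
#'   parameters.
#' @param eps Stabilizer in the amplitude normalization.
#' @return Matrix of phase-congruency values with the shape of `img`.
#' @export
phase_congruency <- function(img, n_scale = 4, n_orient = 4,
                             min_wavelength = 6, mult = 2, sigma_onf = 0.55,
                             eps = 1e-4) {
  H <- nrow(img); W <- ncol(img)
  bank <- log_gabor_bank(H, W, n_scale, n_orient, min_wavelength, mult,
                         sigma_onf)
  IMG <- fft(matrix(as.numeric(img), H, W))
  energy_total <- matrix(0, H, W)
  amp_total <- matrix(0, H, W)
  k <- 1
  for (o in seq_len(bank$n_orient)) {
    sumE <- matrix(0, H, W); sumO <- matrix(0, H, W); sumA <- matrix(0, H, W)
    for (s in seq_len(bank$n_scale)) {
      resp <- fft(IMG * bank$filters[[k]], inverse = TRUE) / (H * W)
      # even (real) and odd (imaginary) quadrature components
      sumE <- sumE + Re(resp)
      sumO <- sumO + Im(resp)
      sumA <- sumA + Mod(resp)
      k <- k + 1
    }
    energy_total <- energy_total + sqrt(sumE^2 + sumO^2)
    amp_total <- amp_total + sumA
  }
  pc <- energy_total / (amp_total + eps)
  pmin(pmax(pc, 0), 1)
}

# Scharr gradient magnitude with reflect padding
scharr_gradient <- function(img) {
  gx <- matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3, 3) / 16
  gy <- t(gx)
  dx <- correlate2(img, gx)
  dy <- correlate2(img, gy)
  sqrt(dx^2 + dy^2)
}

#' Feature similarity index (FSIM)
#'
#' Combines a phase-congruency similarity `S_PC` and a gradient-magnitude
#' similarity `S_G` (Scharr operator) per pixel and pools them weighted by
#' the maximal phase congruency:
#' `FSIM = sum(S_PC * S_G * PCmax) / sum(PCmax)`.
#'
#' @param m,n Same-shape grayscale matrices, at least 32x32.
#' @param t1,t2 Stability constants for `S_PC` and `S_G` (0.85, 160).
#' @param ... Log-Gabor bank parameters passed to [phase_congruency()].
#' @return FSIM value in `[0, 1]`; 1 for identical images.
#' @export
fsim <- function(m, n, t1 = 0.85, t2 = 160, ...) {
  assert_same_shape(m, n)
  if (nrow(m) < 32 || ncol(m) < 32)
    stop("fsim requires images of at least 32x32 (filter-bank support)")
  pc1 <- phase_congruency(m, ...)
  pc2 <- phase_congruency(n, ...)
  g1 <- scharr_gradient(m)
  g2 <- scharr_gradient(n)
  s_pc <- (2 * pc1 * pc2 + t1) / (pc1^2 + pc2^2 + t1)
  s_g <- (2 * g1 * g2 + t2) / (g1^2 + g2^2 + t2)
  pcm <- pmax(pc1, pc2)
  if (sum(pcm) == 0) return(mean(s_pc * s_g))  # featureless pair
  sum(s_pc * s_g * pcm) / sum(pcm)
}

#' Full ten-indicator quality report
#'
#' Computes PSNR, SSIM and FSIM between the image before and after
#' segmentation (reference vs class-mean reconstruction), Shannon entropy
#' and region uniformity of the labeling, and -- when a ground-truth vessel
#' mask is supplied -- Dice, Jaccard, sensitivity, specificity and accuracy
#' of the predicted vessel mask.
#'
#' @param reference Grayscale image the segmentation was computed on.
#' @param reconstructed Class-mean reconstruction ([reconstruct_classes()]).
#' @param labels Label image ([apply_thresholds()]).
#' @param gt_mask,pred_mask Optional binary masks (ground truth, predicted
#'   vessels).
#' @return Object of class `metrics_report` (named list of indicators;
#'   mask metrics are `NA` when no ground truth is given).
#' @export
metrics_report <- function(reference, reconstructed, labels,
                           gt_mask = NULL, pred_mask = NULL) {
  rep <- list(
    psnr = psnr(reference, reconstructed),
    ssim = ssim(reference, reconstructed),
    fsim = fsim(reference, reconstructed),
    shannon_entropy = shannon_entropy(labels),
    region_uniformity = region_uniformity(reference, labels),
    dice = NA_real_, jaccard = NA_real_,
    sensitivity = NA_real_, specificity = NA_real_, accuracy = NA_real_
  )
  if (!is.null(gt_mask) && !is.null(pred_mask)) {
    rep$dice <- dice(gt_mask, pred_mask)
    rep$jaccard <- jaccard(gt_mask, pred_mask)
    rates <- se_sp_acc(confusion(gt_mask, pred_mask))
    rep[c("sensitivity", "specificity", "accuracy")] <- rates
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.na(v)) "NA" else format(v, digits = 6)))
  }
  invisible(x)
}
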