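#' Extract the green channel of an RGB fundus image
#'
#' Vessel contrast is strongest in the green channel of color fundus
#' photographs, so all downstream processing runs on it.
#'
#' @param rgb `H x W x 3` array of 8-bit intensities.
#' @return `H x W` integer matrix (the green channel, unchanged).
#' @export
extract_green <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("input must have exactly 3 channels")
  out <- rgb[, , 2]
  storage.mode(out) <- "integer"
  out
}

#' Oriented Gaussian matched-filter kernel
#'
#' A negative Gaussian vessel cross-section `-exp(-x'^2 / (2 sigma^2))`
#' swept along a segment of the given length oriented along the vessel
#' direction `theta` (`theta = 0` matches a horizontal vessel). In the
#' rotated frame the segment axis is `y' = x cos(theta) + y sin(theta)`
#' and the cross-section axis `x' = -x sin(theta) + y cos(theta)`; the
#' support is `|y'| <= length/2`, `|x'| <= 3 sigma`. The support mean is
#' subtracted so the weights sum to zero and a constant background gives
#' zero response; correlating with a dark (below-background) vessel then
#' yields a positive aligned response.
#'
#' @param sigma Vessel scale in pixels (`> 0`).
#' @param length Vessel-segment length in pixels (`>= 1`).
#' @param theta Orientation in radians, `[0, pi)`.
#' @return Object of class `gmf_kernel`: list with `weights` (odd-sized
#'   square matrix summing to 0), `sigma`, `length`, `theta`.
#' @export
gmf_kernel <- function(sigma, length = 9, theta = 0) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length < 1) stop("length must be >= 1")
  if (theta < 0 || theta >= pi) stop("theta must lie in [0, pi)")
  r <- ceiling(sqrt((3 * sigma)^2 + (length / 2)^2))
  xs <- -r:r
  x <- matrix(xs, 2 * r + 1, 2 * r + 1, byrow = TRUE)  # column offset
  y <- matrix(xs, 2 * r + 1, 2 * r + 1)                # row offset
  yr <- x * cos(theta) + y * sin(theta)   # along-vessel coordinate
  xr <- -x * sin(theta) + y * cos(theta)  # cross-section coordinate
  support <- abs(yr) <= length / 2 & abs(xr) <= 3 * sigma
  w <- matrix(0, 2 * r + 1, 2 * r + 1)
  w[support] <- -exp(-xr[support]^2 / (2 * sigma^2))
  w[support] <- w[support] - mean(w[support])  # zero-mean correction
  structure(list(weights = w, sigma = sigma, length = length, theta = theta),
            class = "gmf_kernel")
}

#' Matched-filter vessel enhancement
#'
#' Correlates the image with a bank of `n_orientations` evenly spaced
#' matched-filter kernels and keeps the per-pixel maximum response. The
#' negative-Gaussian kernel already yields positive maxima on the dark
#' vessels of a green-channel fundus image, so no intensity inversion is
#' applied by default; the result is min-max rescaled to `[0, 1]` (a
#' constant image maps to all zeros), leaving vessels bright.
#'
#' @param img 8-bit grayscale matrix.
#' @param sigma,length Kernel parameters ([gmf_kernel()]).
#' @param n_orientations Number of bank orientations (default 12, i.e.
#'   15-degree steps).
#' @param invert Invert the input (`255 - v`) before filtering; set `TRUE`
#'   for images whose vessels are brighter than the background.
#' @return Matrix in `[0, 1]` with vessels bright.
#' @export
gmf_enhance <- function(img, sigma = 1.5, length = 9, n_orientations = 12,
                        invert = FALSE) {
  assert_gray8(img)
  if (n_orientations < 1) stop("n_orientations must be >= 1")
  src <- if (invert) 255 - img else img + 0
  best <- matrix(-Inf, nrow(img), ncol(img))
  for (k in seq_len(n_orientations) - 1L) {
    kern <- gmf_kernel(sigma, length, k * pi / n_orientations)
    best <- pmax(best, correlate2(src, kern$weights))
  }
  minmax01(best)
}

#' Top-hat minus bot-hat vessel detail image
#'
#' `Img_top = Img - opening(Img, b)` keeps bright small-scale detail,
#' `Img_bot = Img - closing(Img, b)` is non-positive and marks dark
#' small-scale detail (the tiny end vessels). Their difference
#' `Img_top - Img_bot = closing - opening` is non-negative; it is min-max
#' rescaled to `[0, 1]`. Morphology uses a disc (or square) structuring
#' element with reflect padding at the borders.
#'
#' @param img 8-bit grayscale matrix.
#' @param radius Structuring-element radius in pixels (`>= 1`).
#' @param shape `"disc"` or `"square"`.
#' @return Matrix in `[0, 1]` (all zeros for a constant image).
#' @export
top_bot_hat <- function(img, radius = 5, shape = c("disc", "square")) {
  assert_gray8(img)
  shape <- match.arg(shape)
  if (radius < 1) stop("radius must be >= 1")
  size <- 2 * radius + 1
  if (size > nrow(img) || size > ncol(img))
    stop("structuring element larger than image")
  brush <- if (shape == "disc" && size >= 5) EBImage::makeBrush(size, "disc")
           else matrix(1, size, size)
  pad <- reflect_pad(img, radius)
  crop <- function(m) m[(radius + 1):(radius + nrow(img)),
                        (radius + 1):(radius + ncol(img))]
  op <- crop(EBImage::opening(pad, brush))
  cl <- crop(EBImage::closing(pad, brush))
  diffimg <- pmax((img - op) - (img - cl), 0)  # = closing - opening >= 0
  minmax01(diffimg)
}

#' Fuse the matched-filter and top/bot-hat images
#'
#' Each operand is min-max normalized to `[0, 1]` (a constant operand
#' normalizes to all zeros), combined as a convex weighted sum, and
#' rescaled to 8-bit integers `0..255`.
#'
#' @param enh,detail Same-shape matrices (any scale).
#' @param weights Length-2 non-negative weights summing to 1.
#' @return 8-bit integer matrix.
#' @export
fuse <- function(enh, detail, weights = c(0.5, 0.5)) {
  assert_same_shape(enh, detail)
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be two non-negative values summing to 1")
  combo <- weights[1] * minmax01(enh) + weights[2] * minmax01(detail)
  out <- round_half_up(255 * combo)
  storage.mode(out) <- "integer"
  out
}

#' Full vessel-enhancement preprocessing
#'
#' Green-channel extraction (for RGB input), matched-filter enhancement,
#' top/bot-hat detail extraction and fusion into the single 8-bit image the
#' threshold search consumes.
#'
#' @param img `H x W` 8-bit matrix or `H x W x 3` RGB array.
#' @param gmf List of [gmf_enhance()] options (`sigma`, `length`,
#'   `n_orientations`).
#' @param tophat List of [top_bot_hat()] options (`radius`, `shape`).
#' @param fusion_weights Passed to [fuse()].
#' @return List with `fused` (8-bit matrix), `enhanced`, `detail`, `green`.
#' @export
preprocess_fundus <- function(img, gmf = list(), tophat = list(),
                              fusion_weights = c(0.5, 0.5)) {
  green <- if (length(dim(img)) == 3L) extract_green(img) else img
  assert_gray8(green)
  enh <- do.call(gmf_enhance, c(list(img = green), gmf))
  det <- do.call(top_bot_hat, c(list(img = green), tophat))
  fused <- fuse(enh, det, fusion_weights)
  list(fused = fused, enhanced = enh, detail = det, green = green)
}
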