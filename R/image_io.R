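#' @importFrom stats fft rnorm runif sd var
#' @importFrom utils head tail
NULL

#' Read an image file as an 8-bit array
#'
#' Reads a PNG/TIFF/PPM image and returns either an `H x W` integer matrix
#' (grayscale) or an `H x W x 3` array (RGB), with intensities on the 0--255
#' scale and rows indexing image rows.
#'
#' @param path Path to an 8-bit image file (1 or 3 channels).
#' @return Integer matrix (grayscale) or 3-d array (RGB).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  # EBImage stores x (width) in the first dimension; transpose to rows = H
  if (length(dim(dat)) == 2L) {
    out <- round(t(dat) * 255)
    storage.mode(out) <- "integer"
    return(out)
  }
  nch <- dim(dat)[3]
  if (nch == 4L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(dat)[3] == 1L) {
    out <- round(t(dat[, , 1]) * 255)
    storage.mode(out) <- "integer"
    return(out)
  }
  if (dim(dat)[3] != 3L) stop("unsupported channel count: ", nch)
  out <- array(0L, dim = c(dim(dat)[2], dim(dat)[1], 3L))
  for (k in 1:3) out[, , k] <- as.integer(round(t(dat[, , k]) * 255))
  out
}

#' Write an 8-bit grayscale matrix or binary mask as PNG
#'
#' @param img `H x W` matrix with values in `[0, 255]`, or a 0/1 mask
#'   (written as 0/255).
#' @param path Output path (extension selects the format, PNG recommended).
#' @export
write_image <- function(img, path) {
  m <- as.matrix(img)
  if (all(m %in% c(0, 1))) m <- m * 255
  EBImage::writeImage(EBImage::Image(t(m / 255)), path)
  invisible(path)
}

# validate an 8-bit grayscale image matrix
assert_gray8 <- function(img, arg = "img") {
  if (!is.matrix(img) || nrow(img) < 1 || ncol(img) < 1)
    stop(arg, " must be a non-empty matrix")
  if (any(!is.finite(img))) stop(arg, " contains non-finite values")
  if (any(img < 0 | img > 255) || any(img != floor(img)))
    stop(arg, " must contain integers in [0, 255]")
  invisible(TRUE)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# validate a binary (0/1 or logical) mask, return 0/1 numeric matrix
as_binary_mask <- function(m, arg = "mask") {
  if (is.logical(m)) {
    mm <- m * 1
    dim(mm) <- dim(m)
    return(mm)
  }
  m <- as.matrix(m)
  u <- unique(as.vector(m))
  if (all(u %in% c(0, 255)) && any(u == 255)) m <- m / 255
  if (!all(m %in% c(0, 1))) stop(arg, " must be binary (0/1, logical or 0/255)")
  m
}

# min-max rescale to [0,1]; (numerically) constant input maps to all zeros
minmax01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 1e-9 * max(1, abs(hi), abs(lo)))
    return(array(0, dim = dim(x)))
  (x - lo) / (hi - lo)
}

# round half away from zero (R's round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

# reflect-pad a matrix by r rows/cols on each side
reflect_pad <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  if (r >= H || r >= W) stop("padding radius ", r, " too large for ",
                             H, "x", W, " image")
  ri <- c(r:1, 1:H, H:(H - r + 1))
  ci <- c(r:1, 1:W, W:(W - r + 1))
  m[ri, ci]
}

# 2-D correlation with reflect padding (kernel must have odd dims)
correlate2 <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  r <- max(kh, kw) %/% 2
  pad <- reflect_pad(img, r)
  # EBImage::filter2 convolves; rotate the kernel 180 deg for correlation,
  # then crop the padded ring
  res <- EBImage::filter2(pad, kern[kh:1, kw:1, drop = FALSE],
                          boundary = "circular")
  res[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img))]
}
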