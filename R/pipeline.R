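#' End-to-end vessel segmentation
#'
#' Runs the full pipeline on one image: preprocessing
#' ([preprocess_fundus()]), histogram, swarm threshold search, labeling,
#' class-mean reconstruction, vessel-mask extraction and (when a ground
#' truth is supplied) the ten-indicator quality report. Deterministic given
#' `(config, seed)`.
#'
#' @param image Path to an image file, an 8-bit matrix, or an RGB array.
#' @param dim Number of thresholds (default 3; the setting whose
#'   segmentations track expert masks most closely).
#' @param optimizer `"pmssa"` (default), `"mssa"` or `"pso"`.
#' @param seed Integer seed for the search.
#' @param gt_mask Optional binary ground-truth vessel mask.
#' @param vessel_classes Label classes counted as vessel in the predicted
#'   mask; default the top (brightest-after-enhancement) class `dim`.
#' @param preprocess List of options for [preprocess_fundus()] (`gmf`,
#'   `tophat`, `fusion_weights`).
#' @param optimizer_args Extra arguments for the optimizer (budgets etc.).
#' @return Object of class `segmentation_result`: thresholds, fitness
#'   (`-sigma_B^2`), label image, reconstruction, vessel mask, fused image,
#'   metrics report (or `NULL`), seed and config echo.
#' @export
segment_vessels <- function(image, dim = 3, optimizer = "pmssa", seed = 1,
                            gt_mask = NULL, vessel_classes = dim,
                            preprocess = list(), optimizer_args = list()) {
  if (is.character(image)) image <- read_image(image)
  pp <- do.call(preprocess_fundus, c(list(img = image), preprocess))
  h <- gray_histogram(pp$fused)
  res <- do.call(optimize_thresholds,
                 c(list(h = h, dim = dim, optimizer = optimizer, seed = seed),
                   optimizer_args))
  tv <- res$best_position
  labels <- apply_thresholds(pp$fused, tv)
  recon <- reconstruct_classes(pp$fused, tv)
  vmask <- matrix(as.integer(labels %in% vessel_classes),
                  nrow(labels), ncol(labels))
  metrics <- metrics_report(pp$fused, recon, labels,
                            gt_mask = gt_mask,
                            pred_mask = if (is.null(gt_mask)) NULL else vmask)
  structure(list(
    thresholds = tv, fitness = res$best_fitness, history = res$history,
    labels = labels, reconstructed = recon, vessel_mask = vmask,
    fused = pp$fused, metrics = metrics, seed = seed,
    config = list(dim = dim, optimizer = optimizer,
                  vessel_classes = vessel_classes,
                  preprocess = preprocess, optimizer_args = optimizer_args)
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n")
  cat("  optimizer :", x$config$optimizer, " dim:", x$config$dim,
      " seed:", x$seed, "\n")
  cat("  thresholds:", paste(x$thresholds, collapse = ", "), "\n")
  cat("  fitness   :", format(x$fitness, digits = 10),
      " (sigma_B^2 =", format(-x$fitness, digits = 10), ")\n")
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Serialize a segmentation result or comparison table as JSON
#'
#' Produces a deterministic JSON document (stable key order, full numeric
#' precision); reruns with an identical config and seed are byte-identical.
#' Non-finite metric values (e.g. PSNR of identical images) are written as
#' `null`.
#'
#' @param x A `segmentation_result` or data frame.
#' @param path Output path.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "segmentation_result")) {
    x <- list(thresholds = x$thresholds,
              fitness = x$fitness,
              history = x$history,
              seed = x$seed,
              config = x$config,
              metrics = lapply(unclass(x$metrics), function(v)
                if (is.null(v) || !is.finite(v)) NULL else v))
  }
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Compare optimizers across inputs, dimensions and seeds
#'
#' Runs every `(input, optimizer, dim, seed)` combination on the
#' between-class-variance objective and tabulates fitness, thresholds and
#' the exact-oracle fitness (for `dim <= 3`). Inputs may be
#' `gray_histogram` objects, 8-bit matrices, or `phantom` objects (their
#' image is preprocessed first).
#'
#' @param inputs List of inputs (named or not).
#' @param optimizers Character vector among `"pmssa"`, `"mssa"`, `"pso"`.
#' @param dims Integer vector of threshold counts.
#' @param seeds Integer vector of seeds.
#' @param preprocess Options for [preprocess_fundus()] applied to image
#'   inputs.
#' @param optimizer_args Extra optimizer arguments (shared).
#' @param oracle_dims Dimensions for which the exact oracle column is
#'   filled (default `dims[dims <= 3]`).
#' @return Data frame with one row per combination: `input`, `optimizer`,
#'   `dim`, `seed`, `fitness`, `thresholds` (JSON array string),
#'   `oracle_fitness`, `gap` (fitness minus oracle fitness, `>= 0`).
#' @export
compare_optimizers <- function(inputs, optimizers = c("pmssa", "mssa", "pso"),
                               dims = 2:3, seeds = 1L,
                               preprocess = list(), optimizer_args = list(),
                               oracle_dims = dims[dims <= 3]) {
  if (length(inputs) < 1) stop("at least one input required")
  if (length(optimizers) < 1) stop("at least one optimizer required")
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    names(inputs) <- paste0("input", seq_along(inputs))
  hists <- lapply(inputs, function(x) {
    if (inherits(x, "gray_histogram")) return(x)
    if (inherits(x, "phantom")) x <- x$image
    if (is.character(x)) x <- read_image(x)
    gray_histogram(do.call(preprocess_fundus, c(list(img = x), preprocess))$fused)
  })
  rows <- list()
  for (nm in names(hists)) {
    h <- hists[[nm]]
    oracle <- sapply(dims, function(d)
      if (d %in% oracle_dims) -brute_force_optimal(h, d)$sigma_b2 else NA_real_)
    names(oracle) <- as.character(dims)
    for (opt in optimizers) for (d in dims) for (s in seeds) {
      res <- do.call(optimize_thresholds,
                     c(list(h = h, dim = d, optimizer = opt, seed = s),
                       optimizer_args))
      of <- oracle[[as.character(d)]]
      rows[[length(rows) + 1]] <- data.frame(
        input = nm, optimizer = opt, dim = d, seed = s,
        fitness = res$best_fitness,
        thresholds = as.character(jsonlite::toJSON(res$best_position)),
        oracle_fitness = of,
        gap = if (is.na(of)) NA_real_ else res$best_fitness - of,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
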