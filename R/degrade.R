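# Programmatic image degradation (resolution and contrast) and the relative
# count / relative diameter benchmark curves, with 50%-of-maximum threshold
# metrics.

#' Lower image resolution by bin-averaging
#'
#' Each output pixel is the exact mean of a `bin x bin` block of the input;
#' trailing partial blocks are dropped, so output dimensions are
#' `floor(dim / bin)`.
#'
#' @param image numeric matrix.
#' @param bin integer block side, >= 1.
#' @return matrix of size `floor(dim(image) / bin)`.
#' @export
degrade_resolution <- function(image, bin) {
  image <- as.matrix(image)
  bin <- as.integer(bin)
  if (bin < 1L) config_error("bin must be >= 1")
  if (bin > nrow(image) || bin > ncol(image))
    config_error("bin exceeds an image dimension")
  if (bin == 1L) return(image)
  nr <- (nrow(image) %/% bin) * bin
  nc <- (ncol(image) %/% bin) * bin
  m <- image[seq_len(nr), seq_len(nc), drop = FALSE]
  # average rows within blocks, then columns
  rowg <- rep(seq_len(nr %/% bin), each = bin)
  colg <- rep(seq_len(nc %/% bin), each = bin)
  m1 <- rowsum(m, rowg) / bin
  out <- t(rowsum(t(m1), colg) / bin)
  dimnames(out) <- NULL
  out
}

#' RMS contrast of an image
#'
#' Standard deviation (population form) of the intensities after normalizing
#' the 8-bit range to `[0, 1]`; a full-range binary checkerboard has RMS
#' contrast 0.5.
#'
#' @param image numeric matrix on a `[0, max_value]` scale.
#' @param max_value full-scale intensity (default 255, i.e. 8-bit).
#' @return scalar in `[0, 0.5]` for in-range images.
#' @export
rms_contrast <- function(image, max_value = 255) {
  x <- as.numeric(image) / max_value
  sqrt(mean((x - mean(x))^2))
}

#' Compress an image's brightness range to a target RMS contrast
#'
#' Affine rescaling about the mean so that the RMS contrast of the normalized
#' intensities equals `target_rms`; the mean is preserved and the result is
#' quantized back to 8-bit integers. Only contrast *reduction* is allowed.
#'
#' @param image numeric matrix on a `[0, 255]` scale.
#' @param target_rms desired RMS contrast, `0 < target_rms <=` current.
#' @param quantize round to integer 8-bit levels (default TRUE).
#' @return degraded matrix on the same scale.
#' @export
degrade_contrast <- function(image, target_rms, quantize = TRUE) {
  image <- as.matrix(image)
  cur <- rms_contrast(image)
  if (target_rms <= 0) config_error("target_rms must be positive")
  if (target_rms > cur + 1e-12)
    config_error(sprintf(
      "target RMS contrast %.4g exceeds current %.4g (no contrast enhancement)",
      target_rms, cur))
  mu <- mean(image)
  out <- mu + (image - mu) * (target_rms / cur)
  if (quantize) out <- pmin(pmax(round(out), 0), 255)
  out
}

#' Degradation benchmark sweep
#'
#' Applies [run_oda()] to an image across a grid of resolution (bin-average)
#' and contrast degradation levels and records, per level, the relative count
#' and relative diameter against reference values. Detection failures are
#' recorded as `rel_count = 0` (count dropping to zero, not an error).
#'
#' @param image numeric matrix (original resolution, `[0, 255]` scale).
#' @param reference_count reference (manual / ground-truth) ommatidia count.
#' @param reference_diameter_px reference lens diameter in *original* pixels.
#' @param bins integer vector of bin-averaging factors (resolution sweep).
#' @param rms_targets numeric vector of RMS contrast targets (contrast sweep,
#'   applied at full resolution).
#' @param mask optional binary eye mask; bin-averaged (then re-thresholded at
#'   0.5) alongside the image in the resolution sweep.
#' @param ... further arguments passed to [run_oda()] (e.g. `n_fundamentals`).
#' @return data.frame with one row per degradation level and columns `kind`,
#'   `bin`, `px_per_diameter`, `rms_contrast`, `count`, `rel_count`,
#'   `diameter_px` (original-pixel units), `rel_diameter`, `runtime_s`.
#' @export
benchmark_sweep <- function(image, reference_count, reference_diameter_px,
                            bins = integer(0), rms_targets = numeric(0),
                            mask = NULL, ...) {
  if (reference_count <= 0 || reference_diameter_px <= 0)
    config_error("reference count and diameter must be positive")
  image <- as.matrix(image)
  one_level <- function(img, kind, bin, rms, msk) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(run_oda(img, mask = msk, ...), error = function(e) NULL)
    dt <- proc.time()[["elapsed"]] - t0
    count <- if (is.null(res)) 0L else res$count
    diam <- if (is.null(res) || is.na(res$diameter_mean)) NA_real_
            else res$diameter_mean / res$pixel_size * bin  # back to original px
    data.frame(kind = kind, bin = bin,
               px_per_diameter = reference_diameter_px / bin,
               rms_contrast = rms,
               count = count,
               rel_count = count / reference_count,
               diameter_px = diam,
               rel_diameter = if (is.na(diam)) 0 else diam / reference_diameter_px,
               runtime_s = dt)
  }
  rows <- list()
  for (b in bins) {
    img_b <- degrade_resolution(image, b)
    msk_b <- if (is.null(mask)) NULL else (degrade_resolution(mask, b) > 0.5) * 1L
    rows[[length(rows) + 1L]] <-
      one_level(img_b, "resolution", b, rms_contrast(img_b), msk_b)
  }
  for (tr in rms_targets) {
    img_c <- tryCatch(degrade_contrast(image, tr), error = function(e) NULL)
    if (is.null(img_c)) next
    rows[[length(rows) + 1L]] <-
      one_level(img_c, "contrast", 1L, rms_contrast(img_c), mask)
  }
  if (!length(rows))
    return(data.frame(kind = character(0), bin = integer(0),
                      px_per_diameter = numeric(0), rms_contrast = numeric(0),
                      count = integer(0), rel_count = numeric(0),
                      diameter_px = numeric(0), rel_diameter = numeric(0),
                      runtime_s = numeric(0)))
  do.call(rbind, rows)
}

#' Threshold resolution (or contrast) of a degradation sweep
#'
#' For counts: the lowest resolution (px per diameter) whose relative count
#' still exceeds 50% of the maximum relative count in the sweep. For
#' diameters: the lowest resolution whose relative diameter deviates from the
#' undegraded baseline by less than 50%.
#'
#' @param points data.frame from [benchmark_sweep()] (or with columns
#'   `px_per_diameter`, `rel_count`, `rel_diameter`).
#' @param metric `"count"` (default) or `"diameter"`.
#' @param x which abscissa to threshold over: `"px_per_diameter"` (default)
#'   or `"rms_contrast"`.
#' @return the threshold abscissa value, or `NA` if no point qualifies.
#' @export
threshold_resolution <- function(points, metric = c("count", "diameter"),
                                 x = "px_per_diameter") {
  metric <- match.arg(metric)
  if (!nrow(points)) return(NA_real_)
  ok <- if (metric == "count") {
    points$rel_count > 0.5 * max(points$rel_count)
  } else {
    baseline <- points$rel_diameter[which.max(points[[x]])]
    abs(points$rel_diameter - baseline) < 0.5 * baseline
  }
  if (!any(ok)) return(NA_real_)
  min(points[[x]][ok])
}
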