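# Static diagnostic plots (the non-interactive replacement for visual
# checking): reciprocal space with accepted peaks, and the annotated image.

#' Diagnostic plot of the 2D detection
#'
#' Two panels: the log power spectrum with the accepted fundamental peaks
#' circled, and the input image with detected centers superimposed. Intended
#' as a static check of a [run_oda()] run.
#'
#' @param image the input image matrix (or `calibrated_image`).
#' @param result an `ommatidia_set` from [run_oda()].
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, `NULL`.
#' @export
plot_oda <- function(image, result, file = NULL) {
  img <- as_calibrated_image(image)
  spec <- compute_reciprocal(img)
  fnd <- tryCatch(find_fundamentals(spec), error = function(e) NULL)
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  lp <- log(spec$power + .Machine$double.xmin)
  graphics::image(spec$fx, spec$fy, t(lp), col = grDevices::gray.colors(128),
                  xlab = "fx (cycles/px)", ylab = "fy (cycles/px)",
                  main = "reciprocal space")
  if (!is.null(fnd)) {
    graphics::points(fnd$peaks$fx, fnd$peaks$fy, col = "red", cex = 2, lwd = 2)
    graphics::points(-fnd$peaks$fx, -fnd$peaks$fy, col = "red", cex = 2, lwd = 2)
  }
  graphics::image(seq_len(ncol(img$pixels)), seq_len(nrow(img$pixels)),
                  t(img$pixels[rev(seq_len(nrow(img$pixels))), ]),
                  col = grDevices::gray.colors(128), xlab = "col (px)",
                  ylab = "row (px)", main = sprintf("%d ommatidia", result$count))
  if (result$count)
    graphics::points(result$centers[, "col"],
                     nrow(img$pixels) + 1 - result$centers[, "row"],
                     col = "red", pch = 3, cex = 0.6)
  invisible(NULL)
}
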