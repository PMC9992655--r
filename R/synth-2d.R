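#' Calibrated image container
#'
#' Bundles a grayscale intensity matrix with an optional pixel size
#' (micrometers per pixel) and an optional binary mask of the eye region.
#'
#' @param pixels numeric matrix of intensities (rows = image rows).
#' @param pixel_size length of one pixel in micrometers (default 1).
#' @param mask optional matrix of the same shape; any value above 50% of its
#'   maximum counts as foreground (a white silhouette on black).
#' @return An object of class `calibrated_image` with elements `pixels`,
#'   `pixel_size` and `mask` (binary 0/1 matrix or `NULL`).
#' @export
calibrated_image <- function(pixels, pixel_size = 1, mask = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || !all(is.finite(pixels)))
    io_error("image intensities must be finite numbers")
  if (any(dim(pixels) < 8L))
    io_error("image must be at least 8x8 pixels")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    config_error("pixel_size must be a single positive number")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(pixels)))
      io_error("mask shape must match image shape")
    mx <- max(mask)
    mask <- if (mx > 0) (mask > 0.5 * mx) * 1L else matrix(0L, nrow(mask), ncol(mask))
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, mask = mask),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

as_calibrated_image <- function(image, pixel_size = 1, mask = NULL) {
  if (inherits(image, "calibrated_image")) image
  else calibrated_image(image, pixel_size = pixel_size, mask = mask)
}

#' Generate a 2D sinusoidal grating
#'
#' `image(x, y) = offset + amplitude * sin(2 * pi * freq * (x cos t + y sin t))`
#' with `x` the column and `y` the row coordinate (pixels) and `t` the
#' orientation measured from the +x (column) axis.
#'
#' @param size image side length in pixels, or a length-2 vector (rows, cols).
#' @param freq spatial frequency in cycles per pixel; must lie in (0, 0.5).
#' @param orientation grating orientation in degrees.
#' @param amplitude sine amplitude (default 1).
#' @param offset constant offset (default 0, i.e. zero-mean).
#' @return numeric matrix.
#' @export
make_grating <- function(size, freq, orientation = 0, amplitude = 1, offset = 0) {
  if (length(size) == 1L) size <- c(size, size)
  if (freq <= 0 || freq >= 0.5)
    config_error("grating frequency must lie strictly inside (0, 0.5) cycles/px (Nyquist)")
  th <- orientation * pi / 180
  x <- matrix(seq_len(size[2]) - 1, size[1], size[2], byrow = TRUE)
  y <- matrix(seq_len(size[1]) - 1, size[1], size[2])
  offset + amplitude * sin(2 * pi * freq * (x * cos(th) + y * sin(th)))
}

# Hexagonal lattice node coordinates (row, col) covering a frame with a margin.
# Rows are spaced sqrt(3)/2 * spacing apart; alternate rows offset by spacing/2.
# The whole lattice can be rotated about the frame center.
hex_lattice_nodes <- function(size, spacing, orientation = 0, margin = 0) {
  nr <- size[1]; nc <- size[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  row_step <- spacing * sqrt(3) / 2
  # generate on an axis-aligned lattice large enough to cover the rotated frame
  half_diag <- sqrt(nr^2 + nc^2) / 2 + spacing
  i <- seq(-ceiling(half_diag / row_step), ceiling(half_diag / row_step))
  j <- seq(-ceiling(half_diag / spacing), ceiling(half_diag / spacing))
  g <- expand.grid(i = i, j = j)
  u <- g$j * spacing + (g$i %% 2) * spacing / 2   # lattice x
  v <- g$i * row_step                             # lattice y
  th <- orientation * pi / 180
  x <- cx + u * cos(th) - v * sin(th)
  y <- cy + u * sin(th) + v * cos(th)
  keep <- x >= 1 + margin & x <= nc - margin & y >= 1 + margin & y <= nr - margin
  cbind(row = y[keep], col = x[keep])
}

#' Generate a synthetic hexagonal-lattice eye image
#'
#' Renders a Gaussian bright spot at every node of a hexagonal lattice
#' (emulating the high-contrast reflection at the center of each facet),
#' optionally adds Gaussian pixel noise, and returns both the image and the
#' exact ground-truth center list for parameter-recovery tests.
#'
#' @param size frame side in pixels, or (rows, cols).
#' @param spacing center-to-center lattice spacing in pixels (>= 3).
#' @param orientation lattice rotation in degrees.
#' @param spot_sigma Gaussian spot standard deviation in px
#'   (default `spacing / 4`).
#' @param contrast peak spot amplitude above background, in intensity units of
#'   an 8-bit-like 0-255 scale (default 200).
#' @param noise_sigma additive Gaussian noise s.d. (same units; default 0).
#' @param seed integer seed controlling the noise only; ground-truth centers
#'   are independent of it.
#' @param margin border (px) the ground-truth centers keep from the frame
#'   edge (default 0). Spots are rendered with overscan regardless: lattice
#'   nodes slightly outside the frame still contribute their intensity tails,
#'   as in a cropped micrograph of a larger eye.
#' @return list with `image` (matrix), `centers` (matrix with columns
#'   `row`, `col`; the ground truth inside the margin), `mask` (binary
#'   matrix, white exactly over the ground-truth region, mirroring the eye
#'   silhouette masks used on real micrographs), `spacing`, `orientation`.
#' @export
make_hex_lattice_image <- function(size, spacing, orientation = 0,
                                   spot_sigma = spacing / 4, contrast = 200,
                                   noise_sigma = 0, seed = 1L, margin = 0) {
  if (length(size) == 1L) size <- c(size, size)
  if (spacing < 3) config_error("lattice spacing must be >= 3 px")
  overscan <- ceiling(4 * spot_sigma) + spacing
  nodes_all <- hex_lattice_nodes(size, spacing, orientation, margin = -overscan)
  nodes <- nodes_all[nodes_all[, 1] >= 1 + margin & nodes_all[, 1] <= size[1] - margin &
                     nodes_all[, 2] >= 1 + margin & nodes_all[, 2] <= size[2] - margin,
                     , drop = FALSE]
  img <- matrix(20, size[1], size[2])  # dim background
  # render each Gaussian spot on a local window (4 sigma)
  w <- ceiling(4 * spot_sigma)
  for (k in seq_len(nrow(nodes_all))) {
    r0 <- nodes_all[k, 1]; c0 <- nodes_all[k, 2]
    r_lo <- max(1, floor(r0 - w)); r_hi <- min(size[1], ceiling(r0 + w))
    c_lo <- max(1, floor(c0 - w)); c_hi <- min(size[2], ceiling(c0 + w))
    if (r_lo > r_hi || c_lo > c_hi) next
    rr <- r_lo:r_hi
    cc <- c_lo:c_hi
    dr <- (rr - r0)^2
    dc <- (cc - c0)^2
    img[rr, cc] <- img[rr, cc] +
      contrast * exp(-outer(dr, dc, "+") / (2 * spot_sigma^2))
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    img <- img + matrix(rnorm(length(img), 0, noise_sigma), size[1], size[2])
  }
  mask <- matrix(0L, size[1], size[2])
  mask[(1 + ceiling(margin)):(size[1] - ceiling(margin)),
       (1 + ceiling(margin)):(size[2] - ceiling(margin))] <- 1L
  list(image = img, centers = nodes, mask = mask,
       spacing = spacing, orientation = orientation)
}
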