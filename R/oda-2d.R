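# The 2D ommatidia detecting pipeline:
#   image -> power spectrum -> fundamental lattice gratings -> low-pass
#   reconstruction -> local maxima (= lens centers) -> neighbor-distance
#   diameters.

fftshift_index <- function(n) ((seq_len(n) - 1 - floor(n / 2)) %% n) + 1

freq_axis <- function(n) (seq_len(n) - 1 - floor(n / 2)) / n

#' Compute the centered 2D power spectrum of an image
#'
#' Subtracts the image mean and returns the squared modulus of the 2D FFT with
#' the DC component shifted to the grid center. Because the power spectrum is
#' the Fourier transform of the spatial autocorrelation (Wiener-Khinchin), it
#' amplifies periodic structure relative to the raw amplitude spectrum, which
#' is what the lattice-peak search operates on. The displayed/searched power
#' uses a 2D Hann window (suppressing the envelope sidelobes a finite lattice
#' patch would otherwise spray along its axes); the raw unwindowed transform
#' is kept alongside for the low-pass reconstruction.
#'
#' @param image a `calibrated_image`, or a numeric matrix.
#' @return object of class `reciprocal_spectrum`: `power` (centered, Hann
#'   windowed), `fx`/`fy` frequency axes in cycles/px (columns/rows), and the
#'   unshifted complex transform used later for filtering.
#' @export
compute_reciprocal <- function(image) {
  img <- as_calibrated_image(image)
  px <- img$pixels - mean(img$pixels)
  if (all(px == 0)) no_signal_error()
  nr <- nrow(px); nc <- ncol(px)
  Fc <- stats::fft(px)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  w <- outer(hann(nr), hann(nc))
  pw <- px * w
  P <- Mod(stats::fft(pw - mean(pw)))^2
  Ps <- P[fftshift_index(nr), fftshift_index(nc)]
  structure(list(power = Ps,
                 fy = freq_axis(nr), fx = freq_axis(nc),
                 fft = Fc, image_mean = mean(img$pixels),
                 dim = c(nr, nc)),
            class = "reciprocal_spectrum")
}

#' @export
print.reciprocal_spectrum <- function(x, ...) {
  cat(sprintf("<reciprocal_spectrum> %d x %d, freq resolution %.4g cyc/px\n",
              x$dim[1], x$dim[2], 1 / min(x$dim)))
  invisible(x)
}

fold_half_plane <- function(v) {
  # point symmetry: report each grating once, with fx > 0 (or fx == 0, fy > 0)
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) -v else v
}

orientation_deg <- function(fx, fy) {
  a <- atan2(fy, fx) * 180 / pi
  a[a <= -90] <- a[a <= -90] + 180
  a[a > 90] <- a[a > 90] - 180
  a
}

#' Find the fundamental lattice gratings in a power spectrum
#'
#' Searches the centered power spectrum for the significant local maxima
#' closest to the DC center: the fundamental gratings of the facet lattice
#' (three axes for a hexagonal lattice, two for a square one). Candidate peaks
#' must exceed `median + k_mad * MAD` of the log-power within their radial
#' frequency band; peaks lying at an integer multiple (2x, 3x) of an accepted
#' lower-frequency peak's frequency vector are rejected as harmonics.
#'
#' @param spectrum a `reciprocal_spectrum` from [compute_reciprocal()].
#' @param n_fundamentals 3 (hexagonal lattice) or 2 (square lattice, or noisy
#'   images where the third axis is unreliable).
#' @param k_mad significance multiplier for the radial-band MAD of the raw
#'   power (default 25; see Details in the package vignette).
#' @param dc_exclude radial frequency below which peaks are ignored; default
#'   `4 / min(dim)` (the DC lobe spans several bins).
#' @param harmonic_tol relative tolerance for harmonic rejection (default 0.1).
#' @param rel_threshold minimum peak power as a fraction of the strongest
#'   significant peak (default 0.01); see [significant_peaks()].
#' @return object of class `fundamental_set`: data.frame `peaks` with columns
#'   `fx`, `fy`, `radial_freq`, `orientation`, `magnitude`, plus
#'   `fft_diameter_px = 1 / mean(radial_freq)`.
#' @export
find_fundamentals <- function(spectrum, n_fundamentals = 3, k_mad = 25,
                              dc_exclude = NULL, harmonic_tol = 0.1,
                              rel_threshold = 0.01) {
  stopifnot(inherits(spectrum, "reciprocal_spectrum"))
  if (!n_fundamentals %in% c(2, 3))
    config_error("n_fundamentals must be 2 or 3")
  pk <- significant_peaks(spectrum, k_mad = k_mad, dc_exclude = dc_exclude,
                          rel_threshold = rel_threshold)
  pf <- cbind(pk$fx, pk$fy)
  r <- pk$radial_freq
  nr <- spectrum$dim[1]; nc <- spectrum$dim[2]
  bin <- 1 / min(nr, nc)
  acc <- integer(0)
  for (i in seq_along(r)) {
    if (length(acc) >= n_fundamentals) break
    dup <- FALSE; harm <- FALSE
    for (j in acc) {
      if (sqrt(sum((pf[i, ] - pf[j, ])^2)) < 1.5 * bin ||
          sqrt(sum((pf[i, ] + pf[j, ])^2)) < 1.5 * bin) { dup <- TRUE; break }
      for (m in 2:3) {
        for (s in c(1, -1)) {
          g <- m * s * pf[j, ]
          if (sqrt(sum((pf[i, ] - g)^2)) < harmonic_tol * sqrt(sum(g^2))) harm <- TRUE
        }
      }
      if (harm) break
    }
    if (!dup && !harm) acc <- c(acc, i)
  }
  if (length(acc) < n_fundamentals)
    lattice_not_found_error(sprintf(
      "found only %d significant fundamental peak(s), need %d",
      length(acc), n_fundamentals))
  peaks <- pk[acc, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks,
                 fft_diameter_px = 1 / mean(peaks$radial_freq)),
            class = "fundamental_set")
}

#' Significant off-DC peaks of a power spectrum
#'
#' The peak primitive behind [find_fundamentals()]: local maxima of the
#' (log-scaled) centered power spectrum, outside the DC exclusion radius,
#' whose raw power exceeds `median + k_mad * MAD` of their radial frequency
#' band and reaches at least `rel_threshold` of the strongest such peak.
#' Band statistics use the raw power scale: genuine lattice peaks sit
#' hundreds to millions of MADs above their annulus, while the extreme order
#' statistics of a featureless (noise) spectrum stay near 12, so the default
#' `k_mad = 25` separates the regimes with a wide margin on both sides. The
#' relative threshold discards low-frequency leakage structure that is
#' locally significant but orders of magnitude below the lattice gratings.
#'
#' @inheritParams find_fundamentals
#' @param rel_threshold minimum peak power as a fraction of the strongest
#'   significant peak (default 0.01).
#' @return data.frame with columns `fx`, `fy` (folded to the half-plane
#'   `fx > 0`), `radial_freq`, `orientation` (degrees in (-90, 90]),
#'   `magnitude`, sorted by increasing radial frequency.
#' @export
significant_peaks <- function(spectrum, k_mad = 25, dc_exclude = NULL,
                              rel_threshold = 0.01) {
  stopifnot(inherits(spectrum, "reciprocal_spectrum"))
  P <- spectrum$power
  nr <- nrow(P); nc <- ncol(P)
  if (is.null(dc_exclude)) dc_exclude <- 4 / min(nr, nc)
  logP <- log(P + .Machine$double.xmin)
  fr <- sqrt(outer(spectrum$fy^2, spectrum$fx^2, "+"))
  band_width <- 1 / min(nr, nc)
  band <- pmin(floor(fr / band_width), floor(0.5 / band_width)) + 1L
  bandf <- factor(band, levels = seq_len(max(band)))
  med <- as.numeric(tapply(P, bandf, stats::median))
  madv <- pmax(as.numeric(tapply(P, bandf, stats::mad)), .Machine$double.xmin)
  thr <- matrix(med[band] + k_mad * madv[band], nr, nc)
  is_peak <- (logP == max_filter(logP, 2)) & (P > thr) & (fr > dc_exclude)
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    lattice_not_found_error("no significant off-DC peaks (no periodic lattice detected)")
  mag <- P[idx]
  keep <- mag >= rel_threshold * max(mag)
  idx <- idx[keep, , drop = FALSE]; mag <- mag[keep]
  pf <- t(vapply(seq_len(nrow(idx)), function(i)
    fold_half_plane(c(spectrum$fx[idx[i, 2]], spectrum$fy[idx[i, 1]])),
    numeric(2)))
  r <- sqrt(rowSums(pf^2))
  o <- order(r, -mag)
  pf <- pf[o, , drop = FALSE]; r <- r[o]; mag <- mag[o]
  # each grating appears twice (point symmetry); report it once
  bin <- 1 / min(nr, nc)
  keep <- logical(length(r))
  for (i in seq_along(r)) {
    keep[i] <- !any(keep & sqrt((pf[, 1] - pf[i, 1])^2 +
                                  (pf[, 2] - pf[i, 2])^2) < 1.5 * bin)
  }
  data.frame(fx = pf[keep, 1], fy = pf[keep, 2], radial_freq = r[keep],
             orientation = orientation_deg(pf[keep, 1], pf[keep, 2]),
             magnitude = mag[keep])
}

#' @export
print.fundamental_set <- function(x, ...) {
  cat(sprintf("<fundamental_set> %d gratings, fft diameter %.2f px\n",
              nrow(x$peaks), x$fft_diameter_px))
  print(x$peaks, digits = 4)
  invisible(x)
}

#' Low-pass reconstruct an image from its fundamental gratings
#'
#' Zeroes all frequencies whose radial magnitude exceeds
#' `cutoff_factor * max(fundamental radial frequency)` and inverts the FFT.
#' The default factor 1.25 passes the fundamentals (and DC) while blocking
#' their first harmonics at twice the frequency, yielding a smoothed image
#' whose local maxima sit near facet centers.
#'
#' @param spectrum a `reciprocal_spectrum`.
#' @param fundamentals a `fundamental_set`.
#' @param cutoff_factor multiple of the largest fundamental radial frequency
#'   retained (default 1.25).
#' @return real-valued matrix, same shape as the input image.
#' @export
lowpass_reconstruct <- function(spectrum, fundamentals, cutoff_factor = 1.25) {
  stopifnot(inherits(spectrum, "reciprocal_spectrum"),
            inherits(fundamentals, "fundamental_set"))
  cutoff <- cutoff_factor * max(fundamentals$peaks$radial_freq)
  nr <- spectrum$dim[1]; nc <- spectrum$dim[2]
  fy <- pmin(seq_len(nr) - 1, nr - (seq_len(nr) - 1)) / nr
  fx <- pmin(seq_len(nc) - 1, nc - (seq_len(nc) - 1)) / nc
  keep <- sqrt(outer(fy^2, fx^2, "+")) <= cutoff
  Fc <- spectrum$fft
  Fc[!keep] <- 0
  Re(stats::fft(Fc, inverse = TRUE)) / (nr * nc) + spectrum$image_mean
}

ommatidia_set <- function(centers, diameters_px, fft_diameter_px, pixel_size) {
  n <- nrow(centers)
  diam_um <- diameters_px * pixel_size
  ok <- !is.na(diam_um)
  structure(list(centers = centers,
                 count = n,
                 diameters_px = diameters_px,
                 diameters_um = diam_um,
                 diameter_mean = if (any(ok)) mean(diam_um[ok]) else NA_real_,
                 diameter_sd = if (sum(ok) > 1) stats::sd(diam_um[ok]) else NA_real_,
                 fft_diameter_px = fft_diameter_px,
                 pixel_size = pixel_size),
            class = "ommatidia_set")
}

#' @export
print.ommatidia_set <- function(x, ...) {
  cat(sprintf("<ommatidia_set> %d ommatidia, lens diameter %.2f +/- %.2f um (fft est. %.2f px)\n",
              x$count, x$diameter_mean, x$diameter_sd, x$fft_diameter_px))
  invisible(x)
}

#' @export
as.data.frame.ommatidia_set <- function(x, ...) {
  n <- x$count
  data.frame(id = seq_len(n),
             row_px = if (n) x$centers[, "row"] else numeric(0),
             col_px = if (n) x$centers[, "col"] else numeric(0),
             diameter_px = if (n) x$diameters_px else numeric(0),
             diameter_um = if (n) x$diameters_um else numeric(0))
}

#' Measure per-facet lens diameters from detected centers
#'
#' The per-center diameter is the median distance from a center to its lattice
#' neighbors, where neighbors are the centers within `1.5 * fft_diameter_px`
#' (the hexagonal first shell). Note the FFT-derived diameter itself equals
#' the lattice *row* spacing (`sqrt(3)/2` of the center spacing), so it is
#' used only to bound the neighbor search, not as the diameter.
#'
#' @param centers numeric matrix with columns `row`, `col` (px).
#' @param fft_diameter_px reciprocal of the mean fundamental frequency, px.
#' @param pixel_size micrometers per pixel.
#' @return list with `diameters_px` (per center; `NA` for isolated centers),
#'   `diameter_mean` and `diameter_sd` in micrometers.
#' @export
measure_diameters <- function(centers, fft_diameter_px, pixel_size = 1) {
  if (is.null(nrow(centers)) || nrow(centers) < 2L)
    undefined_error("diameter needs at least 2 detected centers")
  n <- nrow(centers)
  lim2 <- (1.5 * fft_diameter_px)^2
  d_px <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d2 <- (centers[, 1] - centers[i, 1])^2 + (centers[, 2] - centers[i, 2])^2
    nb <- d2 > 0 & d2 <= lim2
    if (any(nb)) d_px[i] <- stats::median(sqrt(d2[nb]))
  }
  um <- d_px * pixel_size
  ok <- !is.na(um)
  list(diameters_px = d_px,
       diameter_mean = if (any(ok)) mean(um[ok]) else NA_real_,
       diameter_sd = if (sum(ok) > 1) stats::sd(um[ok]) else NA_real_)
}

#' Detect facet centers in a smoothed image
#'
#' Local maxima of the low-pass reconstruction, with minimum-distance
#' suppression at 25% of the FFT-derived facet diameter, optionally restricted
#' to a mask.
#'
#' @param smoothed image matrix from [lowpass_reconstruct()].
#' @param fundamentals a `fundamental_set`.
#' @param mask optional binary matrix; centers outside it are dropped.
#' @param pixel_size micrometers per pixel (for diameter summaries).
#' @param min_distance_factor fraction of `fft_diameter_px` used as the
#'   minimum separation between accepted maxima (default 0.25).
#' @param subpixel quadratic sub-pixel refinement of maxima (default FALSE).
#' @return an `ommatidia_set`.
#' @export
detect_centers <- function(smoothed, fundamentals, mask = NULL, pixel_size = 1,
                           min_distance_factor = 0.25, subpixel = FALSE) {
  stopifnot(inherits(fundamentals, "fundamental_set"))
  min_dist <- min_distance_factor * fundamentals$fft_diameter_px
  mbin <- NULL
  if (!is.null(mask)) {
    mx <- max(mask)
    mbin <- if (mx > 0) mask > 0.5 * mx else matrix(FALSE, nrow(mask), ncol(mask))
  }
  pk <- find_local_maxima(smoothed, min_distance = min_dist,
                          subpixel = subpixel, mask = mbin)
  centers <- pk[, c("row", "col"), drop = FALSE]
  if (nrow(centers) >= 2L) {
    dm <- measure_diameters(centers, fundamentals$fft_diameter_px, pixel_size)
  } else {
    dm <- list(diameters_px = rep(NA_real_, nrow(centers)),
               diameter_mean = NA_real_, diameter_sd = NA_real_)
  }
  ommatidia_set(centers, dm$diameters_px, fundamentals$fft_diameter_px, pixel_size)
}

#' Run the full 2D ommatidia detecting pipeline
#'
#' Composes [compute_reciprocal()], [find_fundamentals()],
#' [lowpass_reconstruct()] and [detect_centers()]. Deterministic for a fixed
#' input and configuration.
#'
#' @inheritParams compute_reciprocal
#' @inheritParams find_fundamentals
#' @inheritParams detect_centers
#' @param mask optional binary eye silhouette (white on black); overrides the
#'   mask carried by a `calibrated_image`.
#' @param pixel_size micrometers per pixel; overrides a `calibrated_image`'s.
#' @param cutoff_factor see [lowpass_reconstruct()].
#' @return an `ommatidia_set`.
#' @examples
#' syn <- make_hex_lattice_image(128, spacing = 12)
#' res <- run_oda(syn$image)
#' res$count == nrow(syn$centers)
#' @export
run_oda <- function(image, n_fundamentals = 3, mask = NULL, pixel_size = NULL,
                    cutoff_factor = 1.25, min_distance_factor = 0.25,
                    k_mad = 25, subpixel = FALSE) {
  img <- as_calibrated_image(image)
  if (is.null(mask)) mask <- img$mask
  if (is.null(pixel_size)) pixel_size <- img$pixel_size
  spec <- compute_reciprocal(img)
  fnd <- find_fundamentals(spec, n_fundamentals = n_fundamentals, k_mad = k_mad)
  sm <- lowpass_reconstruct(spec, fnd, cutoff_factor = cutoff_factor)
  detect_centers(sm, fnd, mask = mask, pixel_size = pixel_size,
                 min_distance_factor = min_distance_factor, subpixel = subpixel)
}
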