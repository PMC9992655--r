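# Shared fixtures (memoised: the 3D pipelines are reused by several files)
# and small independent oracles.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# --- 3D fixtures ----------------------------------------------------------

# spherical eye: D = 20 um on an R = 800 um sphere, 45 x 45 deg patch
# (~1150 cones), 1 um positional noise
spherical_eye <- function() memo("spherical_eye", {
  spec <- synthetic_eye_spec(lens_diameter = 20, radius_h = 800,
                             extent_deg = c(45, 45), noise_sigma = 1, seed = 2)
  make_synthetic_eye3d(spec)
})

spherical_result <- function() memo("spherical_result", {
  run_oda3d(eye_point_cloud(spherical_eye()$points),
            run_config(lens_diameter_guess_um = 20))
})

# oval eye with R_v = 3 R_h and a regular hexagonal lattice, zero skew
oval_eye <- function() memo("oval_eye", {
  spec <- synthetic_eye_spec(lens_diameter = 20, radius_h = 400,
                             radius_v = 1200, extent_deg = c(50, 25),
                             noise_sigma = 1, seed = 4)
  make_synthetic_eye3d(spec)
})

oval_result <- function() memo("oval_result", {
  run_oda3d(eye_point_cloud(oval_eye()$points),
            run_config(lens_diameter_guess_um = 20, neighborhood_radius = 2))
})

# match pipeline clusters to generator cones; returns truth row index per
# cluster, plus truth axes/centroids rotated into the pipeline's eye frame
match_truth <- function(result, eye) {
  Rm <- result$section$rotation
  ctr <- result$sphere$center
  tc <- sweep(as.matrix(eye$truth[, c("cx", "cy", "cz")]), 2, ctr) %*% t(Rm)
  rec <- result$records
  m <- vapply(seq_len(nrow(rec)), function(k)
    which.min(colSums((t(tc) - c(rec$x[k], rec$y[k], rec$z[k]))^2)), integer(1))
  list(map = m,
       centroids = tc,
       axes = as.matrix(eye$truth[, c("ax", "ay", "az_")]) %*% t(Rm),
       ideal = as.matrix(eye$truth[, c("ix", "iy", "iz")]) %*% t(Rm))
}

# --- 2D helpers -----------------------------------------------------------

# Gaussian spots at given centers (rows, cols), used for square lattices
render_spots <- function(size, centers, sigma, contrast = 200, background = 20) {
  img <- matrix(background, size[1], size[2])
  w <- ceiling(4 * sigma)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    rr <- max(1, floor(r0 - w)):min(size[1], ceiling(r0 + w))
    cc <- max(1, floor(c0 - w)):min(size[2], ceiling(c0 + w))
    img[rr, cc] <- img[rr, cc] +
      contrast * exp(-outer((rr - r0)^2, (cc - c0)^2, "+") / (2 * sigma^2))
  }
  img
}

square_lattice_image <- function(size, spacing, margin = spacing) {
  rows <- seq(1 + margin, size - margin, by = spacing)
  cols <- seq(1 + margin, size - margin, by = spacing)
  centers <- as.matrix(expand.grid(row = rows, col = cols))
  mask <- matrix(0L, size, size)
  half <- floor(spacing / 2)
  mask[(min(rows) - half):(max(rows) + half),
       (min(cols) - half):(max(cols) + half)] <- 1L
  list(image = render_spots(c(size, size), centers, spacing / 4),
       centers = centers, mask = mask)
}

# brute-force local-maximum oracle: neighborhood scan + the same greedy
# min-distance rule, written as plain loops
brute_force_maxima <- function(m, min_distance) {
  r <- max(1L, ceiling(min_distance))
  nr <- nrow(m); nc <- ncol(m)
  cand <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nb <- m[max(1, i - r):min(nr, i + r), max(1, j - r):min(nc, j + r)]
    if (m[i, j] == max(nb)) cand <- rbind(cand, c(i, j, m[i, j]))
  }
  if (is.null(cand)) return(matrix(numeric(0), 0, 3))
  cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  acc <- NULL
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, ]
    if (is.null(acc) ||
        all((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2 >= min_distance^2))
      acc <- rbind(acc, p)
  }
  colnames(acc) <- c("row", "col", "value")
  rownames(acc) <- NULL
  acc
}

# direct O(N^2)-per-axis DFT (matrix form), independent of stats::fft
direct_power_spectrum <- function(img) {
  n <- nrow(img); m <- ncol(img)
  x <- img - mean(img)
  Wn <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  Wm <- exp(-2i * pi * outer(0:(m - 1), 0:(m - 1)) / m)
  Mod(Wn %*% x %*% Wm)^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
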