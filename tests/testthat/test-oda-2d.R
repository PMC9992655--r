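# The 2D detector, stage by stage and end to end.

test_that("the power spectrum locates a grating at its frequency and orientation", {
  g <- make_grating(512, 0.05, 45)
  sp <- compute_reciprocal(g)
  pk <- significant_peaks(sp)
  expect_lt(abs(pk$radial_freq[1] - 0.05), 0.005)
  expect_lt(abs(pk$orientation[1] - 45), 2)
  # DC sits at the grid center and is zero after mean subtraction
  expect_lt(sp$power[257, 257], 1e-10 * max(sp$power))
})

test_that("constant images raise a no-signal error", {
  expect_error(compute_reciprocal(matrix(7, 32, 32)), class = "oda_no_signal")
})

test_that("two orthogonal gratings give two symmetric peak pairs (direct-DFT oracle)", {
  img <- make_grating(64, 0.125, 0) + make_grating(64, 0.125, 90)
  sp <- compute_reciprocal(img)
  # oracle: direct DFT, independent implementation
  P_direct <- direct_power_spectrum(img)
  P_pkg <- Mod(sp$fft)^2
  expect_equal(P_pkg, P_direct, tolerance = 1e-6)
  pk <- significant_peaks(sp)
  expect_equal(nrow(pk), 2L)
  expect_setequal(round(pk$orientation), c(0, 90))
  expect_equal(pk$radial_freq, c(0.125, 0.125), tolerance = 1e-6)
})

test_that("hexagonal lattices yield three fundamentals at the reciprocal-lattice frequency", {
  syn <- make_hex_lattice_image(512, 20)
  fnd <- find_fundamentals(compute_reciprocal(syn$image))
  f_expected <- 2 / (sqrt(3) * 20)   # reciprocal hexagonal lattice
  expect_equal(nrow(fnd$peaks), 3L)
  expect_equal(fnd$peaks$radial_freq, rep(f_expected, 3), tolerance = 0.03)
  gaps <- diff(sort(fnd$peaks$orientation))
  expect_equal(gaps, c(60, 60), tolerance = 3)
  expect_equal(fnd$fft_diameter_px, sqrt(3) / 2 * 20, tolerance = 0.6)
})

test_that("rotating the lattice shifts peak orientations but not frequencies", {
  f0 <- find_fundamentals(compute_reciprocal(make_hex_lattice_image(512, 20)$image))
  f1 <- find_fundamentals(compute_reciprocal(
    make_hex_lattice_image(512, 20, orientation = 10)$image))
  expect_equal(sort(f1$peaks$radial_freq), sort(f0$peaks$radial_freq),
               tolerance = 0.02)
  shift <- (sort(f1$peaks$orientation) - sort(f0$peaks$orientation)) %% 60
  expect_equal(shift, rep(10, 3), tolerance = 1.5)
})

test_that("featureless images raise lattice-not-found", {
  set.seed(11)
  wn <- matrix(rnorm(256^2), 256, 256)
  expect_error(find_fundamentals(compute_reciprocal(wn)),
               class = "oda_lattice_not_found")
})

test_that("low-pass reconstruction keeps fundamentals, DC, and removes 4f noise", {
  # on-bin frequency (16/256) so spectral leakage does not blur the check
  g <- make_grating(256, 0.0625, 30, offset = 5) + make_grating(256, 0.0625, 120)
  sp <- compute_reciprocal(g)
  fnd <- find_fundamentals(sp, n_fundamentals = 2)
  sm <- lowpass_reconstruct(sp, fnd)
  expect_gt(stats::cor(as.vector(sm), as.vector(g)), 0.99)
  expect_equal(mean(sm), mean(g), tolerance = 1e-9)  # DC preserved

  lat <- make_hex_lattice_image(256, 20)$image
  noise <- make_grating(256, 4 * 2 / (sqrt(3) * 20), 15, amplitude = 30)
  spn <- compute_reciprocal(lat + noise)
  fndn <- find_fundamentals(spn)
  smn <- lowpass_reconstruct(spn, fndn)
  band_power <- function(img, f, tol = 0.01) {
    spp <- compute_reciprocal(img)
    fr <- sqrt(outer(spp$fy^2, spp$fx^2, "+"))
    sum(spp$power[abs(fr - f) < tol])
  }
  f4 <- 4 * 2 / (sqrt(3) * 20)
  expect_lt(band_power(smn, f4), 0.01 * band_power(lat + noise, f4))
})

test_that("center detection is exact on clean lattices and empty under an empty mask", {
  syn <- make_hex_lattice_image(256, 20, margin = 20)
  sp <- compute_reciprocal(syn$image)
  fnd <- find_fundamentals(sp)
  sm <- lowpass_reconstruct(sp, fnd)
  res <- detect_centers(sm, fnd, mask = syn$mask)
  expect_equal(res$count, nrow(syn$centers))
  d <- vapply(seq_len(res$count), function(i)
    min(sqrt((syn$centers[, 1] - res$centers[i, 1])^2 +
             (syn$centers[, 2] - res$centers[i, 2])^2)), numeric(1))
  expect_lt(max(d), 1)
  res0 <- detect_centers(sm, fnd, mask = matrix(0, 256, 256))
  expect_equal(res0$count, 0L)
})

test_that("noisy lattices are counted within 2 percent", {
  for (seed in c(5, 9)) {
    syn <- make_hex_lattice_image(256, 20, margin = 20, noise_sigma = 20,
                                  seed = seed)
    res <- run_oda(syn$image, mask = syn$mask)
    expect_lt(abs(res$count / nrow(syn$centers) - 1), 0.02)
  }
})

test_that("diameters equal the lattice spacing and scale with pixel size", {
  syn <- make_hex_lattice_image(256, 20, margin = 20)
  res1 <- run_oda(syn$image, mask = syn$mask, pixel_size = 1)
  expect_equal(res1$diameter_mean, 20, tolerance = 0.05)
  res2 <- run_oda(syn$image, mask = syn$mask, pixel_size = 0.5)
  expect_equal(res2$diameter_mean, 10, tolerance = 0.025)
  expect_error(measure_diameters(matrix(c(5, 5), 1), 17), class = "oda_undefined")
})

test_that("the pipeline is invariant to 90-degree rotation and intensity scaling", {
  syn <- make_hex_lattice_image(256, 20, margin = 20)
  rot90 <- function(m) t(m[nrow(m):1, ])
  res <- run_oda(syn$image, mask = syn$mask)
  res_rot <- run_oda(rot90(syn$image), mask = rot90(syn$mask))
  expect_equal(res_rot$count, res$count)
  # intensity scaling: same count, same positions (up to half-pixel plateau
  # ties on symmetry rows, where two-pixel plateaus split or merge)
  res_scaled <- run_oda(syn$image * 3.7, mask = syn$mask)
  expect_equal(res_scaled$count, res$count)
  d <- vapply(seq_len(res$count), function(i)
    min(sqrt((res$centers[, 1] - res_scaled$centers[i, 1])^2 +
             (res$centers[, 2] - res_scaled$centers[i, 2])^2)), numeric(1))
  expect_lt(max(d), 0.75)
})

test_that("two-fundamental mode recovers square lattices", {
  sq <- square_lattice_image(256, 16)
  res <- run_oda(sq$image, n_fundamentals = 2, mask = sq$mask)
  expect_equal(res$count, nrow(sq$centers))
  # square lattices have 4 nearest neighbors at the spacing and 4 diagonal
  # ones at sqrt(2) times it inside the neighbor radius, so the per-center
  # median sits between the two shells
  expect_gte(res$diameter_mean, 16)
  expect_lte(res$diameter_mean, 16 * sqrt(2))
})

test_that("counts track the ground truth across lattice geometries", {
  cfgs <- list(list(size = 256, a = 12), list(size = 512, a = 20),
               list(size = 256, a = 20, orient = 10))
  for (cfg in cfgs) {
    syn <- make_hex_lattice_image(cfg$size, cfg$a, margin = cfg$a,
                                  orientation = cfg$orient %||% 0)
    res <- run_oda(syn$image, mask = syn$mask)
    expect_equal(res$count, nrow(syn$centers),
                 info = sprintf("size %d spacing %d", cfg$size, cfg$a))
    expect_lt(abs(res$diameter_mean / cfg$a - 1), 0.05)
  }
})
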