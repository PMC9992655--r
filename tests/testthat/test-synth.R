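# Ground-truth generators: gratings, hexagonal lattice images, 3D eyes.

test_that("gratings have the requested period, orientation symmetry and Nyquist guard", {
  g <- make_grating(64, 0.125, 0)   # period 8 px along x (columns)
  expect_equal(g[, 1:56], g[, 9:64], tolerance = 1e-12)
  # a grating and its 180-degree rotation are the same physical pattern up
  # to phase: identical power spectra
  expect_equal(compute_reciprocal(make_grating(32, 0.1, 30))$power,
               compute_reciprocal(make_grating(32, 0.1, 210))$power,
               tolerance = 1e-9)
  expect_true(all(make_grating(16, 0.1, 0, amplitude = 0, offset = 2) == 2))
  expect_error(make_grating(32, 0.6, 0), class = "oda_config_error")
  expect_error(make_grating(32, 0, 0), class = "oda_config_error")
})

test_that("hex lattice images are reproducible, noise leaves centers fixed, and counts match packing", {
  a <- make_hex_lattice_image(128, 10, noise_sigma = 5, seed = 1)
  b <- make_hex_lattice_image(128, 10, noise_sigma = 5, seed = 1)
  expect_identical(a, b)
  c2 <- make_hex_lattice_image(128, 10, noise_sigma = 5, seed = 2)
  expect_identical(a$centers, c2$centers)
  expect_false(identical(a$image, c2$image))
  # hexagonal packing: one center per a^2 * sqrt(3)/2 of area
  n_expected <- 512^2 / (20^2 * sqrt(3) / 2)
  n <- nrow(make_hex_lattice_image(512, 20)$centers)
  expect_gt(n, 0.92 * n_expected)
  expect_lt(n, 1.08 * n_expected)
  expect_error(make_hex_lattice_image(64, 2), class = "oda_config_error")
})

test_that("zero-skew synthetic eyes have exactly radial axes through the sphere center", {
  eye <- spherical_eye()
  tr <- eye$truth
  expect_true(all(tr$skew_deg < 1e-5))
  # lens position = R * axis for a sphere: p x a = 0
  cr <- cbind(tr$y * tr$az_ - tr$z * tr$ay,
              tr$z * tr$ax - tr$x * tr$az_,
              tr$x * tr$ay - tr$y * tr$ax)
  expect_lt(max(abs(cr)), 1e-6 * 800)
})

test_that("constant skew fields tilt anatomical axes by the requested angle", {
  spec <- synthetic_eye_spec(lens_diameter = 20, radius_h = 500,
                             extent_deg = c(30, 30), skew = 10, seed = 1)
  eye <- make_synthetic_eye3d(spec)
  # central cone looks along +x, the tilt target direction: no tilt possible
  interior <- abs(eye$truth$azimuth) + abs(eye$truth$elevation) > 5
  expect_equal(unname(stats::median(eye$truth$skew_deg[interior])), 10,
               tolerance = 1e-6)
})

test_that("oval eyes space their rows by the vertical-radius construction formula", {
  eye <- oval_eye()
  d_el <- diff(sort(unique(round(eye$truth$elevation, 6))))
  expect_equal(stats::median(d_el), (sqrt(3) / 2) * 20 / 1200 * 180 / pi,
               tolerance = 1e-6)
  # within-row azimuth steps follow the horizontal radius
  row0 <- eye$truth[abs(eye$truth$elevation) < 1e-9, ]
  expect_equal(stats::median(diff(sort(row0$azimuth))), 20 / 400 * 180 / pi,
               tolerance = 1e-6)
})

test_that("voxelization and stack loading invert each other on the cone set", {
  spec <- synthetic_eye_spec(lens_diameter = 20, radius_h = 300,
                             extent_deg = c(20, 20), noise_sigma = 0.5,
                             points_per_cone = 6, seed = 3)
  eye <- make_synthetic_eye3d(spec)
  vox <- voxelize_eye3d(eye, voxel_size = 5)
  cloud <- load_stack(vox$stack, voxel_size = 5, density_range = c(100, 255))
  n_cone_vox <- sum(vox$stack == 200)
  expect_equal(nrow(cloud$coords), n_cone_vox)
  # coordinates are indices times the voxel size
  expect_true(all(cloud$coords %% 5 == 0))
  expect_error(load_stack(vox$stack, 5, c(300, 400)), class = "oda_io_error")
  expect_error(load_stack(vox$stack, -1, c(100, 255)), class = "oda_config_error")
})
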