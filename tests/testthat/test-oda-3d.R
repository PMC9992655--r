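# Volumetric pipeline: stack loading, raster detection, clustering,
# correction, and per-cone / per-pair measurements.

test_that("stack loading errors name the offending slice on shape mismatch", {
  d <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.5, 8, 8), file.path(d, "s1.tif"))
  tiff::writeTIFF(matrix(0.5, 8, 8), file.path(d, "s2.tif"))
  tiff::writeTIFF(matrix(0.5, 9, 8), file.path(d, "s3.tif"))
  expect_error(read_stack(d), "s3", class = "oda_io_error")
})

test_that("raster detection finds the cone lattice within 2 percent", {
  res <- spherical_result()
  eye <- spherical_eye()
  expect_lt(abs(nrow(res$centers) / nrow(eye$truth) - 1), 0.02)
})

test_that("window size barely changes the detected center count", {
  res <- spherical_result()
  sec <- res$section
  c23 <- rasterize_and_detect(sec, window_deg = 23, expected_diameter_um = 20)
  expect_lt(abs(nrow(c23) / nrow(res$centers) - 1), 0.01)
})

test_that("two well-separated cones partition perfectly; one center takes all", {
  p1 <- matrix(rnorm(60, 0, 1), 20, 3) + matrix(c(800, 0, 0), 20, 3, byrow = TRUE)
  p2 <- matrix(rnorm(60, 0, 1), 20, 3) + matrix(c(800, 40, 0), 20, 3, byrow = TRUE)
  p <- rbind(p1, p2)
  # minimal synthetic cross-section (sphere centered at origin)
  sphere <- structure(list(center = c(0, 0, 0), radius = 800,
                           residuals = rep(0, 40)), class = "sphere_fit")
  cs <- suppressWarnings(make_cross_section(p, sphere))
  # centers taken from two supporting points, in the section's own frame
  centers <- cbind(x = cs$coords_eye[c(1, 21), 1], y = cs$coords_eye[c(1, 21), 2],
                   z = cs$coords_eye[c(1, 21), 3],
                   elevation = cs$spherical[c(1, 21), 1],
                   azimuth = cs$spherical[c(1, 21), 2],
                   point = c(1, 21))
  cl <- assign_clusters(cs, centers)
  expect_equal(cl$labels, rep(1:2, each = 20))
  one <- assign_clusters(cs, centers[1, , drop = FALSE])
  expect_true(all(one$labels == 1L))
  expect_error(assign_clusters(cs, centers[0, , drop = FALSE]),
               class = "oda_config_error")
})

test_that("zero-skew eyes are clustered at better than 99 percent accuracy", {
  res <- spherical_result()
  eye <- spherical_eye()
  mt <- match_truth(res, eye)
  acc <- mean(mt$map[res$clusters$labels] == eye$labels)
  expect_gt(acc, 0.99)
})

test_that("perfectly segmented clean clusters are never flagged; pipeline flags stay rare", {
  res <- spherical_result()
  eye <- spherical_eye()
  # ideal segmentation: generator truth labels on the pipeline's section
  K <- nrow(eye$truth)
  cen <- t(vapply(seq_len(K), function(k)
    colMeans(res$section$coords_eye[eye$labels == k, , drop = FALSE]),
    numeric(3)))
  ideal <- structure(list(labels = eye$labels, centroids = cen,
                          centers_angular = NULL,
                          problematic = rep(FALSE, K), section = res$section),
                     class = "cluster_set")
  cl2 <- correct_problem_clusters(ideal, seed = 1)
  expect_equal(attr(cl2, "n_flagged_before"), 0L)
  expect_identical(cl2$labels, eye$labels)
  # the real pipeline on a clean eye flags at most about one percent
  cl3 <- correct_problem_clusters(res$clusters, seed = 1)
  expect_lte(attr(cl3, "n_flagged_before"), 0.01 * K)
})

test_that("the correction objective is mean distance plus unit aspect for isotropic clusters", {
  # points on a circle in the y-z plane around one centroid: projecting along
  # +x leaves every point at the same distance and an isotropic footprint
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- cbind(0, 3 * cos(th), 3 * sin(th))
  cen <- matrix(c(0, 0, 0), 1)
  obj <- ommatidia:::correction_objective(c(0, 0), pts, cen)
  expect_equal(obj$value, 3 + 1, tolerance = 1e-9)
})

test_that("correction reduces the number of problematic clusters on a skewed eye", {
  eye <- memo("skewed_eye", {
    spec <- synthetic_eye_spec(lens_diameter = 20, radius_h = 400,
                               radius_v = 1200, extent_deg = c(26, 14),
                               noise_sigma = 1, seed = 6, skew = 20)
    make_synthetic_eye3d(spec)
  })
  cloud <- eye_point_cloud(eye$points)
  sphere <- fit_sphere(cloud$coords)
  sec <- make_cross_section(cloud, sphere,
                            expected_angular_diameter_deg = 20 / sphere$radius * 180 / pi)
  ctr <- rasterize_and_detect(sec, expected_diameter_um = 20)
  cl <- assign_clusters(sec, ctr)
  cl2 <- correct_problem_clusters(cl, seed = 1)
  expect_gt(attr(cl2, "n_flagged_before"), 0L)
  expect_lt(sum(cl2$problematic), attr(cl2, "n_flagged_before"))
})

test_that("per-cone measures recover diameter and near-zero skew on a spherical eye", {
  res <- spherical_result()
  rec <- res$records
  expect_lt(abs(mean(rec$diameter_um, na.rm = TRUE) / 20 - 1), 0.05)
  expect_lt(stats::median(rec$skew_deg, na.rm = TRUE), 2)
  # adjusted diameter never exceeds the raw diameter
  ok <- !is.na(rec$adjusted_diameter_um)
  expect_true(all(rec$adjusted_diameter_um[ok] <= rec$diameter_um[ok] + 1e-9))
  # axes are unit vectors
  nrm <- sqrt(rec$anat_x^2 + rec$anat_y^2 + rec$anat_z^2)
  expect_equal(nrm[!is.na(nrm)], rep(1, sum(!is.na(nrm))), tolerance = 1e-9)
})

test_that("uniformly tilted cones report their tilt as skewness", {
  res10 <- memo("tilted_result", {
    spec <- synthetic_eye_spec(lens_diameter = 20, radius_h = 500,
                               extent_deg = c(30, 30), noise_sigma = 1,
                               skew = 10, seed = 7)
    run_oda3d(eye_point_cloud(make_synthetic_eye3d(spec)$points),
              run_config(lens_diameter_guess_um = 20, correct_clusters = FALSE))
  })
  expect_equal(stats::median(res10$records$skew_deg, na.rm = TRUE), 10,
               tolerance = 2)
})

test_that("interommatidial angles match the lens-spacing-over-radius prediction", {
  res <- spherical_result()
  io <- res$pairs$io_total_deg
  io <- io[!is.na(io)]
  expected <- 20 / 800 * 180 / pi
  expect_lt(abs(stats::median(io) / expected - 1), 0.10)
  # orientation convention
  expect_true(all(res$pairs$orientation_deg > -90 + 1e-9 |
                    is.na(res$pairs$orientation_deg)))
  expect_true(all(res$pairs$orientation_deg <= 90 + 1e-9, na.rm = TRUE))
  # hypotenuse identity
  ok <- !is.na(io)
  expect_equal(res$pairs$io_total_deg[ok],
               sqrt(res$pairs$io_h_deg[ok]^2 + res$pairs$io_v_deg[ok]^2),
               tolerance = 1e-9)
})

test_that("parallel averaged axes give a zero interommatidial angle", {
  rec <- spherical_result()$records[1:8, ]
  rec$avg_x <- 1; rec$avg_y <- 0; rec$avg_z <- 0
  attr(rec, "adjacency") <- cbind(1:4, 5:8)
  attr(rec, "median_diameter") <- 20
  class(rec) <- c("ommatidium_records", "data.frame")
  pr <- measure_io_pairs(rec)
  expect_equal(pr$io_total_deg, rep(0, 4), tolerance = 1e-9)
})

test_that("spreadsheets round-trip and keep referential integrity", {
  res <- spherical_result()
  d <- withr::local_tempdir()
  paths <- export_spreadsheets(res$records, res$pairs, file.path(d, "eye"))
  cones <- utils::read.csv(paths[1])
  pairs <- utils::read.csv(paths[2])
  expect_equal(nrow(cones), nrow(res$records))
  expect_equal(nrow(pairs), nrow(res$pairs))
  expect_true(all(pairs$cone_i %in% cones$id))
  expect_true(all(pairs$cone_j %in% cones$id))
  expect_equal(cones$diameter_um, res$records$diameter_um, tolerance = 1e-6)
})

test_that("the pipeline is equivariant under rigid motion", {
  eye <- spherical_eye()
  cfg <- run_config(lens_diameter_guess_um = 20)
  base <- spherical_result()$summary
  th <- 25 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  moved <- eye$points %*% t(Rz) + matrix(c(500, -200, 120), nrow(eye$points),
                                         3, byrow = TRUE)
  got <- run_oda3d(eye_point_cloud(moved), cfg)$summary
  expect_equal(got$count, base$count)
  expect_equal(got$diameter_mean_um, base$diameter_mean_um, tolerance = 1e-6)
  expect_equal(got$skew_median_deg, base$skew_median_deg, tolerance = 1e-6)
  expect_equal(got$io_median_deg, base$io_median_deg, tolerance = 1e-6)
})

test_that("end-to-end load_stack feeds the pipeline (voxelized synthetic eye)", {
  eye <- memo("vox_eye", {
    spec <- synthetic_eye_spec(lens_diameter = 24, radius_h = 500,
                               extent_deg = c(35, 35), noise_sigma = 0.5,
                               points_per_cone = 16, cone_length = 50, seed = 8)
    make_synthetic_eye3d(spec)
  })
  vox <- voxelize_eye3d(eye, voxel_size = 3)
  d <- withr::local_tempdir()
  write_stack(vox$stack, d)
  cloud <- load_stack(d, voxel_size = 3, density_range = c(100, 255))
  res <- run_oda3d(cloud, run_config(lens_diameter_guess_um = 24))
  # voxel quantization at 3 um on a 24 um lattice loosens the tolerances
  expect_lt(abs(res$summary$count / nrow(eye$truth) - 1), 0.08)
  expect_lt(abs(res$summary$diameter_mean_um / 24 - 1), 0.08)
})
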