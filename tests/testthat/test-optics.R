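# Closed-form optical geometry and the oval-eye / field-of-view analyses.

test_that("the small-angle relation links diameter, radius and angle both ways", {
  expect_equal(spherical_io_angle(100, 100), 180 / pi)   # 1 rad
  expect_equal(spherical_io_angle(20, 1146), 1.000, tolerance = 1e-3)
  expect_equal(spherical_io_angle(0, 50), 0)
  expect_error(spherical_io_angle(10, 0), class = "oda_config_error")
  expect_error(radius_from_io(10, 0), class = "oda_config_error")
  # inverse identity across magnitudes
  for (R in c(0.5, 10, 1000, 2e5)) {
    expect_equal(radius_from_io(17, spherical_io_angle(17, R)), R,
                 tolerance = 1e-12 * R)
  }
})

test_that("skew forshortens the aperture by the cosine of the skew angle", {
  expect_equal(adjusted_diameter(20, 0), 20)
  expect_equal(adjusted_diameter(21.79, 12.81), 21.25, tolerance = 0.005)
  expect_equal(adjusted_diameter(20, 90), 0, tolerance = 1e-12)
  expect_error(adjusted_diameter(20, -1), class = "oda_config_error")
  expect_error(adjusted_diameter(20, 91), class = "oda_config_error")
})

test_that("the total interommatidial angle is the hypotenuse of its components", {
  expect_equal(total_io_angle(0.3, 0.4), 0.5)
  expect_equal(total_io_angle(0.7, 0), 0.7)
  expect_equal(total_io_angle(0, 1.2), 1.2)
  expect_true(total_io_angle(0.5, 0.2) == total_io_angle(0.2, 0.5))
  expect_error(total_io_angle(-0.1, 0.4), class = "oda_config_error")
  expect_equal(eye_parameter(20, 1), 20 * pi / 180)
})

test_that("oval-eye analysis recovers the lattice geometry from synthetic pairs", {
  # construct a pair table straight from the hexagonal-lattice geometry:
  # horizontal pairs at 0 deg carry (2 dphi_h, ~0); diagonal pairs at +/-60
  # carry (dphi_h, dphi_v)
  set.seed(3)
  dphi_h <- 0.8; dphi_v <- 0.6; n <- 300
  mk <- function(orient, h, v, n) data.frame(
    orientation_deg = orient + rnorm(n, 0, 3),
    io_h_deg = pmax(0, h + rnorm(n, 0, 0.05)),
    io_v_deg = pmax(0, v + rnorm(n, 0, 0.05)))
  pairs <- rbind(mk(0, 2 * dphi_h, 0.02, n), mk(60, dphi_h, dphi_v, n),
                 mk(-60, dphi_h, dphi_v, n))
  pairs$io_total_deg <- sqrt(pairs$io_h_deg^2 + pairs$io_v_deg^2)
  ov <- oval_eye_analysis(pairs, mean_diameter_um = 20)
  expect_true(ov$complete)
  expect_equal(sort(ov$modes), c(-60, 0, 60), tolerance = 2)
  expect_equal(ov$dphi_h, dphi_h, tolerance = 0.02)
  expect_equal(ov$dphi_v, dphi_v, tolerance = 0.02)
  # horizontal pairs carry twice the horizontal component of diagonal pairs
  horiz <- which.min(abs(ov$per_mode$mode_deg))
  expect_equal(ov$per_mode$io_h_deg[horiz],
               2 * mean(ov$per_mode$io_h_deg[-horiz]), tolerance = 0.05)
})

test_that("oval-eye analysis on the segmented oval eye finds 0/±60 modes and the radius factor", {
  res <- oval_result()
  ov <- oval_eye_analysis(res$pairs,
                          mean_diameter_um = res$summary$diameter_mean_um)
  expect_true(ov$complete)
  expect_equal(sort(abs(ov$modes)), c(0, 60, 60), tolerance = 3)
  # generator: R_v = 3 R_h; axis radii recover the factor within 15%
  expect_lt(abs(ov$ratio_Rv_Rh_axis / 3 - 1), 0.15)
  # diagonal-pair intersection radius exceeds the horizontal-pair one
  expect_gt(ov$ratio_Rd_Rh, 1.2)
})

test_that("spherical eyes see their angular extent in the world projection", {
  # records built from generator truth: radial axes, 60 x 60 deg patch
  spec <- synthetic_eye_spec(lens_diameter = 20, radius_h = 1000,
                             extent_deg = c(60, 60), noise_sigma = 0, seed = 1)
  eye <- make_synthetic_eye3d(spec)
  rec <- data.frame(id = eye$truth$id, x = eye$truth$x, y = eye$truth$y,
                    z = eye$truth$z, anat_x = eye$truth$ax,
                    anat_y = eye$truth$ay, anat_z = eye$truth$az_)
  vf <- world_project(rec, eye_center = c(0, 0, 0), projection_radius = 1e5)
  expect_equal(vf$fov_horizontal, 60, tolerance = 1)
  expect_equal(vf$fov_vertical, 60, tolerance = 1)
  # invariance to projection radius beyond 50 x eye radius
  vf2 <- world_project(rec, c(0, 0, 0), projection_radius = 6e4)
  expect_lt(abs(vf2$fov_horizontal - vf$fov_horizontal), 1)
  expect_lt(abs(vf2$fov_vertical - vf$fov_vertical), 1)
})

test_that("degenerate world projections behave: single axis and antiparallel axes", {
  one <- data.frame(id = 1, x = 100, y = 0, z = 0,
                    anat_x = 1, anat_y = 0, anat_z = 0)
  vf1 <- world_project(one)
  expect_equal(vf1$fov_horizontal, 0)
  expect_equal(vf1$fov_vertical, 0)
  two <- data.frame(id = 1:2, x = c(100, -100), y = 0, z = 0,
                    anat_x = c(1, -1), anat_y = 0, anat_z = 0)
  vf2 <- world_project(two)
  expect_equal(vf2$fov_horizontal, 180, tolerance = 1e-6)
})
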