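# Ground-truth generator for volumetric tests: shells of elongated
# crystalline-cone point clusters on spherical or oval eye surfaces, with a
# controllable skew field.
#
# Geometry: the eye faces +x. Each cone has an ideal (surface-normal-like)
# viewing direction a(az, el); horizontal viewing directions converge on the
# vertical axis through the horizontal intersection point at distance R_h
# behind the surface, vertical ones at R_v. Lens positions are
#   p = (R_h - R_v) * (cos az, sin az, 0) + R_v * a
# which reduces to p = R * a for a spherical eye (R_h = R_v = R). A regular
# hexagonal lattice (physical spacing D) then requires azimuth steps D / R_h
# within a row and elevation steps (sqrt(3)/2) * D / R_v between rows.

#' Specification of a synthetic compound eye
#'
#' @param lens_diameter physical center-to-center lattice spacing D (um).
#' @param radius_h horizontal radius of curvature / intersection R_h (um).
#' @param radius_v vertical radius R_v (um); equal to `radius_h` for a
#'   spherical eye.
#' @param extent_deg angular extent (azimuth, elevation) of the eye patch in
#'   degrees.
#' @param cone_length length of each crystalline cone (um).
#' @param points_per_cone number of cloud points rendered along each cone.
#' @param skew tilt of the anatomical axis away from the ideal axis: a single
#'   angle in degrees, or a function `f(elevation_deg, azimuth_deg)` returning
#'   one. Tilt is applied toward `skew_target`.
#' @param skew_target 3D point the anatomical axes tilt toward (`NULL` means
#'   tilt toward the eye's central viewing direction, +x at infinity).
#' @param noise_sigma isotropic Gaussian positional noise s.d. (um).
#' @param seed integer seed for the positional noise.
#' @return object of class `synthetic_eye_spec`.
#' @export
synthetic_eye_spec <- function(lens_diameter = 20, radius_h = 1000,
                               radius_v = radius_h, extent_deg = c(60, 60),
                               cone_length = 2 * lens_diameter,
                               points_per_cone = 12, skew = 0,
                               skew_target = NULL, noise_sigma = 1, seed = 1L) {
  if (lens_diameter <= 0 || radius_h <= 0 || radius_v <= 0)
    config_error("lens_diameter and radii must be positive")
  if (any(extent_deg <= 0) || any(extent_deg >= 170))
    config_error("angular extent must lie in (0, 170) degrees per axis")
  structure(list(lens_diameter = lens_diameter, radius_h = radius_h,
                 radius_v = radius_v, extent_deg = extent_deg,
                 cone_length = cone_length, points_per_cone = points_per_cone,
                 skew = skew, skew_target = skew_target,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_eye_spec")
}

# rotate unit vector a by `tilt` radians within the plane spanned by a and d
tilt_toward <- function(a, d, tilt) {
  perp <- d - sum(d * a) * a
  np <- sqrt(sum(perp^2))
  if (np < 1e-12 || tilt == 0) return(a)
  unit3(cos(tilt) * a + sin(tilt) * perp / np)
}

#' Generate a synthetic 3D eye point cloud with ground truth
#'
#' Places crystalline cones at hexagonal angular spacing on a spherical or
#' oval eye surface patch; each cone is a line-segment cluster of points along
#' its (possibly skewed) anatomical axis, pointing inward from the lens, with
#' isotropic Gaussian positional noise. Bit-reproducible for a fixed seed.
#'
#' @param spec a [synthetic_eye_spec()].
#' @return list with `points` (N x 3 matrix, um), `labels` (cone id per
#'   point), `density` (per-point scalar, constant 200), and `truth`, a
#'   data.frame with one row per cone: lens position `x,y,z`, centroid
#'   `cx,cy,cz`, ideal axis `ix,iy,iz`, anatomical axis `ax,ay,az_`,
#'   `skew_deg`, `elevation`, `azimuth`.
#' @export
make_synthetic_eye3d <- function(spec) {
  stopifnot(inherits(spec, "synthetic_eye_spec"))
  D <- spec$lens_diameter; Rh <- spec$radius_h; Rv <- spec$radius_v
  d_az <- D / Rh                    # radians, within-row step
  d_el <- (sqrt(3) / 2) * D / Rv    # radians, row step
  half_az <- spec$extent_deg[1] / 2 * pi / 180
  half_el <- spec$extent_deg[2] / 2 * pi / 180
  rows <- seq(-floor(half_el / d_el), floor(half_el / d_el))
  if (length(rows) < 2 || floor(half_az / d_az) < 1)
    config_error("angular extent too small for the lattice spacing")
  skew_fun <- if (is.function(spec$skew)) spec$skew else function(el, az) spec$skew
  lens <- list(); axes <- list(); ideal <- list(); els <- c(); azs <- c()
  for (i in rows) {
    el <- i * d_el
    off <- (abs(i) %% 2) * d_az / 2
    cols <- seq(-floor((half_az - off) / d_az), floor((half_az - off) / d_az))
    for (j in cols) {
      az <- j * d_az + off
      a <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
      p <- c((Rh - Rv) * cos(az), (Rh - Rv) * sin(az), 0) + Rv * a
      t_deg <- skew_fun(el * 180 / pi, az * 180 / pi)
      d_t <- if (is.null(spec$skew_target)) c(1, 0, 0)
             else unit3(spec$skew_target - p)
      ac <- tilt_toward(a, d_t, t_deg * pi / 180)
      lens[[length(lens) + 1L]] <- p
      axes[[length(axes) + 1L]] <- ac
      ideal[[length(ideal) + 1L]] <- a
      els <- c(els, el * 180 / pi); azs <- c(azs, az * 180 / pi)
    }
  }
  n <- length(lens)
  L <- do.call(rbind, lens); A <- do.call(rbind, axes); I3 <- do.call(rbind, ideal)
  m <- spec$points_per_cone
  depth <- seq(0, spec$cone_length, length.out = m)
  pts <- matrix(0, n * m, 3)
  labels <- rep(seq_len(n), each = m)
  for (k in seq_len(n))
    pts[((k - 1) * m + 1):(k * m), ] <-
      matrix(L[k, ], m, 3, byrow = TRUE) - outer(depth, A[k, ])
  set.seed(spec$seed)
  if (spec$noise_sigma > 0)
    pts <- pts + matrix(rnorm(length(pts), 0, spec$noise_sigma), nrow(pts), 3)
  cen <- L - (spec$cone_length / 2) * A
  truth <- data.frame(id = seq_len(n),
                      x = L[, 1], y = L[, 2], z = L[, 3],
                      cx = cen[, 1], cy = cen[, 2], cz = cen[, 3],
                      ix = I3[, 1], iy = I3[, 2], iz = I3[, 3],
                      ax = A[, 1], ay = A[, 2], az_ = A[, 3],
                      skew_deg = vapply(seq_len(n), function(k)
                        acos(pmin(1, sum(A[k, ] * I3[k, ]))) * 180 / pi,
                        numeric(1)),
                      elevation = els, azimuth = azs)
  list(points = pts, labels = labels,
       density = rep(200, nrow(pts)), truth = truth, spec = spec)
}

#' Voxelize a synthetic eye into an 8-bit image stack
#'
#' Bins the cloud points of [make_synthetic_eye3d()] into a voxel grid
#' (slices along z) with cone voxels at density 200 on a background of 10,
#' for end-to-end tests of stack loading.
#'
#' @param eye result of [make_synthetic_eye3d()].
#' @param voxel_size voxel edge length (um).
#' @param pad number of empty voxels added around the cloud (default 2).
#' @return list with `stack` (3D integer array, slices along the third
#'   dimension), `origin` (um coordinates of voxel (1,1,1) center) and
#'   `voxel_size`.
#' @export
voxelize_eye3d <- function(eye, voxel_size, pad = 2L) {
  p <- eye$points
  lo <- apply(p, 2, min) - pad * voxel_size
  idx <- floor(sweep(p, 2, lo) / voxel_size) + 1L
  dims <- apply(idx, 2, max) + pad
  stack <- array(10L, dim = dims)
  stack[idx] <- 200L
  list(stack = stack, origin = lo + voxel_size / 2, voxel_size = voxel_size)
}
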