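# Closed-form optical geometry shared by both pipelines: the small-angle
# relation between lens diameter, radius of curvature and interommatidial
# angle; skew adjustment of the effective aperture; oval-eye lattice
# analysis; world-referenced field-of-view projection.

#' Spherical interommatidial angle and its inverse
#'
#' For a spherical eye whose ommatidial axes converge at the center of
#' curvature, the interommatidial angle is `D / R` radians, where `D` is the
#' lens diameter and `R` the radius of curvature; equivalently
#' `R = D / angle`.
#'
#' @param D lens diameter (um).
#' @param R radius of curvature or intersection (um).
#' @return angle in degrees.
#' @export
spherical_io_angle <- function(D, R) {
  if (any(D < 0)) config_error("D must be non-negative")
  if (any(R <= 0)) config_error("R must be positive")
  D / R * 180 / pi
}

#' @rdname spherical_io_angle
#' @param io_angle_deg interommatidial angle in degrees.
#' @return `radius_from_io`: radius in micrometers.
#' @export
radius_from_io <- function(D, io_angle_deg) {
  if (any(D < 0)) config_error("D must be non-negative")
  if (any(io_angle_deg <= 0)) config_error("io_angle_deg must be positive")
  D / (io_angle_deg * pi / 180)
}

#' Skew-adjusted effective lens diameter
#'
#' An ommatidium whose anatomical axis is skewed by `theta_s` from the local
#' surface normal presents a foreshortened aperture `D * cos(theta_s)` (a
#' lower bound: refraction reduces it further).
#'
#' @param D lens diameter (um).
#' @param skew_deg skew angle in degrees, within `[0, 90]`.
#' @return effective diameter (um).
#' @export
adjusted_diameter <- function(D, skew_deg) {
  if (any(skew_deg < 0 | skew_deg > 90))
    config_error("skew angle must lie in [0, 90] degrees")
  D * cos(skew_deg * pi / 180)
}

#' Total interommatidial angle from its components
#'
#' The total anatomical interommatidial angle is the hypotenuse of its
#' horizontal and vertical components.
#'
#' @param h,v horizontal and vertical angle components (degrees, >= 0).
#' @return total angle (degrees).
#' @export
total_io_angle <- function(h, v) {
  if (any(h < 0 | v < 0)) config_error("components must be non-negative")
  sqrt(h^2 + v^2)
}

#' Eye parameter
#'
#' The product of lens diameter and interommatidial angle (in radians),
#' `p = D * dphi`, in micrometer-radians. Provided as a convenience only.
#'
#' @param D lens diameter (um).
#' @param io_angle_deg interommatidial angle (degrees).
#' @return eye parameter (um rad).
#' @export
eye_parameter <- function(D, io_angle_deg) D * io_angle_deg * pi / 180

# kernel-smoothed mode finding on orientation angles with period 180 degrees
orientation_modes <- function(theta, n_modes = 3, bw = 5, min_sep = 30) {
  grid <- seq(-90, 90, by = 0.5)
  dens <- vapply(grid, function(g) {
    d <- (theta - g + 90) %% 180 - 90
    sum(exp(-0.5 * (d / bw)^2))
  }, numeric(1))
  n <- length(grid)
  is_max <- dens >= c(dens[n], dens[-n]) & dens >= c(dens[-1], dens[1])
  cand <- grid[is_max][order(-dens[is_max])]
  modes <- numeric(0)
  for (m in cand) {
    if (length(modes) >= n_modes) break
    if (!length(modes) ||
        all(abs((modes - m + 90) %% 180 - 90) >= min_sep)) modes <- c(modes, m)
  }
  sort(modes)
}

#' Oval-eye lattice analysis of adjacent-pair angles
#'
#' Finds the (up to) three orientation modes of the adjacent-pair
#' distribution (0 degrees = horizontal pairs, +/-60 = diagonal pairs for a
#' regular hexagonal lattice), selects pairs within `mode_halfwidth` of each
#' mode, and summarizes per-mode horizontal/vertical angle components. The
#' horizontal interommatidial component combines the diagonal pairs'
#' horizontal angle with *half* the horizontal pairs' horizontal angle (which
#' spans two lattice columns); the vertical component is the diagonal pairs'
#' vertical angle. Radii of intersection follow `R = D / angle`: per mode
#' from the total pair angle, and per axis from the component spacing
#' (columns are `D` apart horizontally, rows `sqrt(3)/2 * D` vertically).
#'
#' @param pairs a `pair_records` data.frame (or any data.frame with columns
#'   `orientation_deg`, `io_h_deg`, `io_v_deg`, `io_total_deg`).
#' @param mean_diameter_um mean lens diameter of the eye (um).
#' @param mode_halfwidth half-width of the selection window around each mode
#'   (degrees, default 15).
#' @return object of class `oval_eye_summary`: `modes` (orientations, deg),
#'   `per_mode` data.frame (n, mean h, v, total, radius), `dphi_h`, `dphi_v`,
#'   `radius_horizontal_pairs` (R_h), `radius_diagonal_pairs` (R_d),
#'   `R_h_axis`, `R_v_axis`, and the ratios `R_d / R_h`,
#'   `R_v_axis / R_h_axis` and `dphi_v / dphi_h`. Modes that cannot be
#'   detected leave their fields `NA` and set `complete = FALSE`.
#' @export
oval_eye_analysis <- function(pairs, mean_diameter_um, mode_halfwidth = 15) {
  th <- pairs$orientation_deg
  keep <- !is.na(th) & !is.na(pairs$io_h_deg) & !is.na(pairs$io_v_deg)
  pairs <- pairs[keep, , drop = FALSE]
  th <- th[keep]
  modes <- orientation_modes(th)
  per_mode <- do.call(rbind, lapply(modes, function(m) {
    d <- abs((th - m + 90) %% 180 - 90)
    sel <- d <= mode_halfwidth
    data.frame(mode_deg = m, n = sum(sel),
               io_h_deg = mean(pairs$io_h_deg[sel]),
               io_v_deg = mean(pairs$io_v_deg[sel]),
               io_total_deg = mean(pairs$io_total_deg[sel]),
               radius_um = radius_from_io(mean_diameter_um,
                                          mean(pairs$io_total_deg[sel])))
  }))
  complete <- length(modes) == 3L
  horiz_i <- if (length(modes)) which.min(abs(modes)) else integer(0)
  diag_i <- setdiff(seq_along(modes), horiz_i)
  dphi_h <- dphi_v <- R_h <- R_d <- NA_real_
  if (length(horiz_i) && length(diag_i)) {
    dphi_h <- mean(c(mean(per_mode$io_h_deg[diag_i]),
                     per_mode$io_h_deg[horiz_i] / 2))
    dphi_v <- mean(per_mode$io_v_deg[diag_i])
    R_h <- per_mode$radius_um[horiz_i]
    R_d <- mean(per_mode$radius_um[diag_i])
  }
  R_h_axis <- if (is.na(dphi_h)) NA_real_
              else radius_from_io(mean_diameter_um, 2 * dphi_h)
  R_v_axis <- if (is.na(dphi_v)) NA_real_
              else radius_from_io(sqrt(3) / 2 * mean_diameter_um, dphi_v)
  structure(list(modes = modes, per_mode = per_mode,
                 dphi_h = dphi_h, dphi_v = dphi_v,
                 radius_horizontal_pairs = R_h,
                 radius_diagonal_pairs = R_d,
                 R_h_axis = R_h_axis, R_v_axis = R_v_axis,
                 ratio_Rd_Rh = R_d / R_h,
                 ratio_Rv_Rh_axis = R_v_axis / R_h_axis,
                 ratio_dphi = dphi_v / dphi_h,
                 complete = complete),
            class = "oval_eye_summary")
}

#' @export
print.oval_eye_summary <- function(x, ...) {
  cat("<oval_eye_summary>\n  modes (deg):", sprintf("%.1f", x$modes), "\n")
  print(x$per_mode, digits = 4)
  cat(sprintf("  dphi_h %.3f deg, dphi_v %.3f deg (ratio %.2f)\n",
              x$dphi_h, x$dphi_v, x$ratio_dphi))
  cat(sprintf("  R_h %.0f um, R_d %.0f um (R_d/R_h %.2f); axis radii %.0f / %.0f um\n",
              x$radius_horizontal_pairs, x$radius_diagonal_pairs,
              x$ratio_Rd_Rh, x$R_h_axis, x$R_v_axis))
  invisible(x)
}

#' World-referenced projection of ommatidial axes
#'
#' Intersects each ommatidium's raw anatomical axis ray with a sphere of
#' `projection_radius` about `eye_center` and reports the angular extent of
#' the intersection directions: the world-referenced field of view. Rays that
#' miss the sphere (anti-directed) are excluded and counted.
#'
#' @param records an `ommatidium_records` data.frame (raw anatomical axes are
#'   used, not the neighborhood-averaged ones).
#' @param eye_center 3D reference point (eye-frame um; default the origin,
#'   i.e. the fitted sphere center).
#' @param projection_radius projection sphere radius in um (default 1e5, i.e.
#'   10 cm).
#' @return object of class `visual_field`: per-ommatidium world `elevation` /
#'   `azimuth` (deg), `fov_horizontal`, `fov_vertical` (deg), the projection
#'   radius and the number of excluded rays.
#' @export
world_project <- function(records, eye_center = c(0, 0, 0),
                          projection_radius = 1e5) {
  p <- cbind(records$x, records$y, records$z)
  a <- cbind(records$anat_x, records$anat_y, records$anat_z)
  ok <- !is.na(a[, 1])
  p <- sweep(p[ok, , drop = FALSE], 2, eye_center)
  a <- a[ok, , drop = FALSE]
  b <- rowSums(p * a)
  cc <- rowSums(p^2) - projection_radius^2
  disc <- b^2 - cc
  t1 <- -b + sqrt(pmax(disc, 0))
  hit <- disc >= 0 & t1 > 0
  d <- (p[hit, , drop = FALSE] + t1[hit] * a[hit, , drop = FALSE]) / projection_radius
  sph <- to_spherical(d)
  structure(list(directions = data.frame(id = records$id[ok][hit],
                                         elevation = sph[, 1],
                                         azimuth = sph[, 2]),
                 fov_horizontal = if (nrow(sph) > 1) diff(range(sph[, 2])) else 0,
                 fov_vertical = if (nrow(sph) > 1) diff(range(sph[, 1])) else 0,
                 projection_radius = projection_radius,
                 n_excluded = sum(!hit)),
            class = "visual_field")
}

#' @export
print.visual_field <- function(x, ...) {
  cat(sprintf("<visual_field> %.1f x %.1f deg (h x v), %d axes projected, %d excluded\n",
              x$fov_horizontal, x$fov_vertical, nrow(x$directions), x$n_excluded))
  invisible(x)
}
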