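# Sphere fitting and spherical-coordinate machinery for the volumetric
# pipeline. Convention: elevation in [-90, 90] degrees from the equatorial
# (xy) plane, azimuth in (-180, 180] degrees about z; before any angular work
# the cloud is rotated so its centroid direction (from the sphere center)
# points along +x, i.e. (elevation 0, azimuth 0), keeping the eye surface far
# from the poles.

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(c(1, 0, 0))
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation matrix taking unit vector u to +x while keeping horizontal
# directions horizontal (rotate about z, then about y)
rotation_to_x <- function(u) {
  u <- unit3(u)
  az <- atan2(u[2], u[1])
  el <- asin(max(-1, min(1, u[3])))
  Rz <- matrix(c(cos(-az), -sin(-az), 0,
                 sin(-az),  cos(-az), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(el), 0, sin(el),
                 0, 1, 0,
                 -sin(el), 0, cos(el)), 3, 3, byrow = TRUE)
  Ry %*% Rz
}

# coords: N x 3 matrix about the origin -> elevation/azimuth (deg), radius
to_spherical <- function(coords) {
  r <- sqrt(rowSums(coords^2))
  el <- asin(pmax(-1, pmin(1, coords[, 3] / r))) * 180 / pi
  az <- atan2(coords[, 2], coords[, 1]) * 180 / pi
  cbind(elevation = el, azimuth = az, radius = r)
}

from_spherical <- function(el_deg, az_deg, r) {
  el <- el_deg * pi / 180; az <- az_deg * pi / 180
  cbind(r * cos(el) * cos(az), r * cos(el) * sin(az), r * sin(el))
}

#' Least-squares sphere fit to a point cloud
#'
#' Linearized algebraic fit (Kasa method) followed by one Gauss-Newton
#' geometric refinement pass on the radial residuals.
#'
#' @param coords N x 3 numeric matrix of point positions (micrometers).
#' @return object of class `sphere_fit`: `center` (length 3), `radius`,
#'   and per-point signed radial `residuals` (`|p - center| - radius`).
#' @export
fit_sphere <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4L)
    ill_conditioned_error("sphere fit needs at least 4 points")
  ctr <- colMeans(coords)
  sv <- svd(sweep(coords, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    ill_conditioned_error("points are (near-)coplanar; sphere fit is degenerate")
  A <- cbind(2 * coords, 1)
  b <- rowSums(coords^2)
  beta <- qr.coef(qr(A), b)
  center <- beta[1:3]
  radius <- sqrt(beta[4] + sum(center^2))
  # one geometric Gauss-Newton pass
  d <- sweep(coords, 2, center)
  dist <- sqrt(rowSums(d^2))
  J <- cbind(-d / dist, -1)
  f <- dist - radius
  step <- tryCatch(qr.coef(qr(J), -f), error = function(e) rep(0, 4))
  if (all(is.finite(step))) {
    center <- center + step[1:3]
    radius <- radius + step[4]
    d <- sweep(coords, 2, center)
    dist <- sqrt(rowSums(d^2))
  }
  structure(list(center = unname(center), radius = unname(radius),
                 residuals = unname(dist - radius)),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> center (%.2f, %.2f, %.2f), radius %.2f, residual sd %.3f\n",
              x$center[1], x$center[2], x$center[3], x$radius, stats::sd(x$residuals)))
  invisible(x)
}

# --- radius-surface fit over (elevation, azimuth) -------------------------

# Binned-grid surface: per-cell mean radius, smoothed, NA cells filled by
# neighbor diffusion, evaluated by bilinear interpolation.
fit_radius_surface <- function(el, az, r, step_deg) {
  el_rng <- range(el); az_rng <- range(az)
  ne <- max(2L, ceiling(diff(el_rng) / step_deg))
  na_ <- max(2L, ceiling(diff(az_rng) / step_deg))
  ei <- pmin(ne, pmax(1L, 1L + floor((el - el_rng[1]) / diff(el_rng) * ne)))
  ai <- pmin(na_, pmax(1L, 1L + floor((az - az_rng[1]) / diff(az_rng) * na_)))
  idx <- (ai - 1L) * ne + ei
  cnt <- tabulate(idx, nbins = ne * na_)
  sm <- rep(0, ne * na_)
  agg <- rowsum(r, idx)
  sm[as.integer(rownames(agg))] <- agg[, 1]
  grid <- matrix(ifelse(cnt > 0, sm / pmax(cnt, 1), NA_real_), ne, na_)
  # fill empty cells from neighbors, then smooth
  fill_pass <- function(g) {
    nas <- which(is.na(g), arr.ind = TRUE)
    if (!nrow(nas)) return(g)
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1]; j <- nas[k, 2]
      nb <- g[max(1, i - 1):min(ne, i + 1), max(1, j - 1):min(na_, j + 1)]
      if (any(!is.na(nb))) g[i, j] <- mean(nb, na.rm = TRUE)
    }
    g
  }
  it <- 0L
  while (anyNA(grid) && it < ne + na_) { grid <- fill_pass(grid); it <- it + 1L }
  if (anyNA(grid)) grid[is.na(grid)] <- mean(r)
  smooth_pass <- function(g) {
    gp <- g
    gp[2:(ne - 1), ] <- (g[1:(ne - 2), ] + g[2:(ne - 1), ] + g[3:ne, ]) / 3
    g2 <- gp
    g2[, 2:(na_ - 1)] <- (gp[, 1:(na_ - 2)] + gp[, 2:(na_ - 1)] + gp[, 3:na_]) / 3
    g2
  }
  grid <- smooth_pass(smooth_pass(grid))
  structure(list(grid = grid, el_rng = el_rng, az_rng = az_rng,
                 ne = ne, na_ = na_),
            class = "radius_surface")
}

# bilinear evaluation (constant extrapolation at the border)
eval_radius_surface <- function(surf, el, az) {
  ne <- surf$ne; na_ <- surf$na_
  # continuous grid coordinates at cell centers
  ge <- (el - surf$el_rng[1]) / diff(surf$el_rng) * ne + 0.5
  ga <- (az - surf$az_rng[1]) / diff(surf$az_rng) * na_ + 0.5
  ge <- pmin(ne, pmax(1, ge)); ga <- pmin(na_, pmax(1, ga))
  i0 <- pmin(ne - 1L, floor(ge)); j0 <- pmin(na_ - 1L, floor(ga))
  ti <- ge - i0; tj <- ga - j0
  g <- surf$grid
  g[cbind(i0, j0)] * (1 - ti) * (1 - tj) +
    g[cbind(i0 + 1, j0)] * ti * (1 - tj) +
    g[cbind(i0, j0 + 1)] * (1 - ti) * tj +
    g[cbind(i0 + 1, j0 + 1)] * ti * tj
}
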