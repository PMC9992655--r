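# Per-cone and per-pair measurements: lens diameter from adjacent centroids,
# ideal axis from triplet planes, anatomical axis from the cluster ellipsoid,
# skewness as their angular difference, and anatomical interommatidial angles
# from projected components of neighborhood-averaged axes.

angle_between_deg <- function(a, b) {
  acos(pmax(-1, pmin(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

#' Measure per-ommatidium parameters from segmented clusters
#'
#' For each cluster: lens diameter `D` = mean 3D distance to adjacent
#' centroids (adjacency = centroid separation below 1.5x the median
#' nearest-centroid distance); ideal axis = outward-oriented average of the
#' unit normals of all triplet planes among the cluster and its adjacent
#' neighbors; anatomical axis = the principal semi-axis of the cluster's
#' point ellipsoid (SVD) closest in angle to the ideal axis; skewness =
#' the angle between the two; adjusted diameter = `D * cos(skew)`. A
#' neighborhood-averaged anatomical axis (mean over clusters within
#' `neighborhood_radius` lens diameters) is also stored: it feeds the
#' interommatidial angles, while the raw axes feed the field-of-view
#' projection.
#'
#' @param clusters a `cluster_set`.
#' @param sphere the `sphere_fit` (for the eye frame; kept for provenance).
#' @param neighborhood_radius axis-averaging radius in lens diameters
#'   (default 5).
#' @return data.frame of class `ommatidium_records`, one row per cluster:
#'   centroid `x,y,z` (eye frame), `elevation`, `azimuth`, `radius`,
#'   `n_points`, `diameter_um`, `adjusted_diameter_um`, ideal axis
#'   `ideal_x/y/z`, anatomical axis `anat_x/y/z`, averaged axis
#'   `avg_x/y/z`, `skew_deg`, `flagged`. Attribute `adjacency` holds the
#'   adjacent-pair index matrix.
#' @export
measure_ommatidia <- function(clusters, sphere, neighborhood_radius = 5) {
  stopifnot(inherits(clusters, "cluster_set"))
  cen <- clusters$centroids
  K <- nrow(cen)
  if (K < 7L) undefined_error("need at least 7 clusters for neighborhood measures")
  ok <- !is.na(cen[, 1])
  P <- clusters$section$coords_eye
  lab <- clusters$labels
  # pairwise centroid distances
  dmat <- as.matrix(stats::dist(cen))
  dmat[!ok, ] <- NA; dmat[, !ok] <- NA
  diag(dmat) <- NA
  nn <- apply(dmat, 1, function(r) if (all(is.na(r))) NA else min(r, na.rm = TRUE))
  med_nn <- stats::median(nn, na.rm = TRUE)
  adj_lim <- 1.5 * med_nn
  adj <- which(dmat <= adj_lim, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  adj_list <- lapply(seq_len(K), function(k)
    sort(c(adj[adj[, 1] == k, 2], adj[adj[, 2] == k, 1])))
  diam <- vapply(seq_len(K), function(k) {
    nb <- adj_list[[k]]
    if (!length(nb)) return(NA_real_)
    mean(dmat[k, nb])
  }, numeric(1))
  ideal <- matrix(NA_real_, K, 3)
  anat <- matrix(NA_real_, K, 3)
  skew <- rep(NA_real_, K)
  flagged <- rep(FALSE, K)
  for (k in which(ok)) {
    S <- c(k, adj_list[[k]])
    outward <- unit3(cen[k, ])
    if (length(S) >= 3L) {
      tri <- utils::combn(S, 3L)
      nsum <- c(0, 0, 0)
      for (t in seq_len(ncol(tri))) {
        a <- cen[tri[1, t], ]; b <- cen[tri[2, t], ]; c3 <- cen[tri[3, t], ]
        if (anyNA(c(a, b, c3))) next
        nv <- cross3(b - a, c3 - a)  # magnitude = 2x triangle area:
        if (sum(nv^2) < 1e-24) next  # area weighting damps thin triplets
        if (sum(nv * outward) < 0) nv <- -nv
        nsum <- nsum + nv
      }
      ideal[k, ] <- if (sum(nsum^2) > 0) unit3(nsum) else outward
    } else {
      ideal[k, ] <- outward
    }
    m <- lab == k
    if (sum(m) < 4L) { flagged[k] <- TRUE; next }
    pts <- P[m, , drop = FALSE]
    sv <- svd(scale(pts, scale = FALSE), nu = 0)
    axes3 <- sv$v
    ang <- apply(axes3, 2, function(v)
      min(angle_between_deg(v, ideal[k, ]), angle_between_deg(-v, ideal[k, ])))
    v <- axes3[, which.min(ang)]
    if (sum(v * ideal[k, ]) < 0) v <- -v
    anat[k, ] <- v
    skew[k] <- angle_between_deg(v, ideal[k, ])
  }
  # neighborhood-averaged anatomical axes
  avg <- matrix(NA_real_, K, 3)
  med_d <- stats::median(diam, na.rm = TRUE)
  lim <- neighborhood_radius * med_d
  for (k in which(ok)) {
    nb <- which(ok & (dmat[k, ] <= lim | seq_len(K) == k))
    nb <- nb[!is.na(anat[nb, 1])]
    if (!length(nb)) next
    avg[k, ] <- unit3(colSums(anat[nb, , drop = FALSE]))
  }
  sphc <- to_spherical(cen)
  rec <- data.frame(id = seq_len(K),
                    x = cen[, 1], y = cen[, 2], z = cen[, 3],
                    elevation = sphc[, 1], azimuth = sphc[, 2],
                    radius = sphc[, 3],
                    n_points = tabulate(lab, nbins = K),
                    diameter_um = diam,
                    adjusted_diameter_um = diam * cos(pmin(90, skew) * pi / 180),
                    ideal_x = ideal[, 1], ideal_y = ideal[, 2], ideal_z = ideal[, 3],
                    anat_x = anat[, 1], anat_y = anat[, 2], anat_z = anat[, 3],
                    avg_x = avg[, 1], avg_y = avg[, 2], avg_z = avg[, 3],
                    skew_deg = skew,
                    flagged = flagged)
  attr(rec, "adjacency") <- adj
  attr(rec, "median_diameter") <- med_d
  class(rec) <- c("ommatidium_records", "data.frame")
  rec
}

# unsigned 2D angle between the projections of two 3D vectors onto the plane
# spanned by coordinate axes i and j
projected_angle_deg <- function(a, b, i, j) {
  a2 <- c(a[i], a[j]); b2 <- c(b[i], b[j])
  na_ <- sqrt(sum(a2^2)); nb <- sqrt(sum(b2^2))
  if (na_ < 1e-12 || nb < 1e-12) return(NA_real_)
  acos(pmax(-1, pmin(1, sum(a2 * b2) / (na_ * nb)))) * 180 / pi
}

#' Measure anatomical interommatidial angles for adjacent cluster pairs
#'
#' For every adjacent pair of ommatidia: the pair's orientation on the eye
#' surface (0 degrees = horizontal), the horizontal angle component (angle
#' between the neighborhood-averaged axes projected onto the horizontal
#' plane, computed within the pair's horizontal section), the vertical
#' component (projection onto the vertical plane, within the vertical
#' section), and the total anatomical interommatidial angle as their
#' hypotenuse. Sections are half-overlapping slabs of width `section_width`
#' lens diameters; a pair whose midpoint misses all section midlines is
#' served by the nearest section and flagged.
#'
#' @param records an `ommatidium_records` data.frame.
#' @param section_width slab width in lens diameters (default 1).
#' @return data.frame of class `pair_records`: `cone_i`, `cone_j`,
#'   `orientation_deg`, `io_h_deg`, `io_v_deg`, `io_total_deg`, the section
#'   indices, and `flagged`.
#' @export
measure_io_pairs <- function(records, section_width = 1) {
  stopifnot(inherits(records, "ommatidium_records"))
  adj <- attr(records, "adjacency")
  if (is.null(adj) || nrow(adj) == 0L)
    undefined_error("records carry no adjacent pairs")
  med_d <- attr(records, "median_diameter")
  w <- section_width * med_d
  half <- w / 2
  n <- nrow(adj)
  ori <- io_h <- io_v <- io_t <- rep(NA_real_, n)
  sec_h <- sec_v <- rep(NA_integer_, n)
  flag <- rep(FALSE, n)
  for (p in seq_len(n)) {
    i <- adj[p, 1]; j <- adj[p, 2]
    ai <- c(records$avg_x[i], records$avg_y[i], records$avg_z[i])
    aj <- c(records$avg_x[j], records$avg_y[j], records$avg_z[j])
    if (anyNA(ai) || anyNA(aj)) { flag[p] <- TRUE; next }
    el_m <- (records$elevation[i] + records$elevation[j]) / 2 * pi / 180
    r_m <- (records$radius[i] + records$radius[j]) / 2
    dy <- (records$azimuth[j] - records$azimuth[i]) * pi / 180 * cos(el_m) * r_m
    dz <- (records$elevation[j] - records$elevation[i]) * pi / 180 * r_m
    a <- atan2(dz, dy) * 180 / pi
    if (a <= -90) a <- a + 180
    if (a > 90) a <- a - 180
    ori[p] <- a
    # horizontal sections: slabs along z; vertical sections: slabs along y
    z_m <- (records$z[i] + records$z[j]) / 2
    y_m <- (records$y[i] + records$y[j]) / 2
    sec_h[p] <- round(z_m / half)
    sec_v[p] <- round(y_m / half)
    io_h[p] <- projected_angle_deg(ai, aj, 1L, 2L)  # onto x-y plane
    io_v[p] <- projected_angle_deg(ai, aj, 1L, 3L)  # onto x-z plane
    io_t[p] <- sqrt(io_h[p]^2 + io_v[p]^2)
  }
  out <- data.frame(cone_i = adj[, 1], cone_j = adj[, 2],
                    orientation_deg = ori,
                    io_h_deg = io_h, io_v_deg = io_v, io_total_deg = io_t,
                    section_h = sec_h, section_v = sec_v,
                    flagged = flag)
  class(out) <- c("pair_records", "data.frame")
  out
}

#' Export the two measurement spreadsheets
#'
#' Writes `<out_prefix>_ommatidia.csv` (one row per crystalline-cone cluster)
#' and `<out_prefix>_pairs.csv` (one row per adjacent pair), comma-separated,
#' '.' decimal, UTF-8, with a header row.
#'
#' @param records an `ommatidium_records` data.frame.
#' @param pairs a `pair_records` data.frame.
#' @param out_prefix path prefix for the two files.
#' @return invisibly, the two file paths.
#' @export
export_spreadsheets <- function(records, pairs, out_prefix) {
  f1 <- paste0(out_prefix, "_ommatidia.csv")
  f2 <- paste0(out_prefix, "_pairs.csv")
  cone_cols <- c("id", "x", "y", "z", "elevation", "azimuth", "radius",
                 "n_points", "diameter_um", "adjusted_diameter_um",
                 "ideal_x", "ideal_y", "ideal_z",
                 "anat_x", "anat_y", "anat_z", "skew_deg")
  utils::write.csv(as.data.frame(records)[, cone_cols], f1, row.names = FALSE)
  pr <- as.data.frame(pairs)
  ci <- pairs$cone_i; cj <- pairs$cone_j
  pr$centroid_i_x <- records$x[ci]; pr$centroid_i_y <- records$y[ci]
  pr$centroid_i_z <- records$z[ci]
  pr$centroid_j_x <- records$x[cj]; pr$centroid_j_y <- records$y[cj]
  pr$centroid_j_z <- records$z[cj]
  pair_cols <- c("cone_i", "cone_j",
                 "centroid_i_x", "centroid_i_y", "centroid_i_z",
                 "centroid_j_x", "centroid_j_y", "centroid_j_z",
                 "orientation_deg", "io_h_deg", "io_v_deg", "io_total_deg")
  utils::write.csv(pr[, pair_cols], f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Run the full volumetric pipeline
#'
#' Composes [fit_sphere()], [make_cross_section()], [rasterize_and_detect()],
#' [assign_clusters()], optionally [correct_problem_clusters()],
#' [measure_ommatidia()], [measure_io_pairs()] and [world_project()], and
#' assembles a summary.
#'
#' @param cloud an `eye_point_cloud` (at least 100 points).
#' @param config a [run_config()] list (or arguments overriding its
#'   defaults).
#' @return list of class `oda3d_result` with each stage's output and a
#'   `summary` list (count, diameter mean/sd, skewness and interommatidial
#'   angle medians with IQR, field of view). Pairs with a total angle above
#'   5x the median are excluded from the summary statistics but retained in
#'   the tables.
#' @export
run_oda3d <- function(cloud, config = run_config()) {
  stopifnot(inherits(cloud, "eye_point_cloud"))
  if (nrow(cloud$coords) < 100L)
    io_error("pipeline entry needs at least 100 points")
  cfg <- config
  sphere <- fit_sphere(cloud$coords)
  section <- make_cross_section(
    cloud, sphere,
    expected_angular_diameter_deg =
      if (!is.null(cfg$lens_diameter_guess_um))
        cfg$lens_diameter_guess_um / sphere$radius * 180 / pi else NULL)
  centers <- rasterize_and_detect(section, window_deg = cfg$window_deg,
                                  expected_diameter_um = cfg$lens_diameter_guess_um,
                                  n_fundamentals = cfg$n_fundamentals)
  if (nrow(centers) == 0L)
    lattice_not_found_error("no ommatidial lattice detected in any segment")
  clusters <- assign_clusters(section, centers)
  if (isTRUE(cfg$correct_clusters))
    clusters <- correct_problem_clusters(clusters, seed = cfg$seed,
                                         de_iter = cfg$de_iter, de_pop = cfg$de_pop)
  records <- measure_ommatidia(clusters, sphere,
                               neighborhood_radius = cfg$neighborhood_radius)
  pairs <- measure_io_pairs(records, section_width = cfg$section_width)
  fov <- tryCatch(world_project(records, eye_center = c(0, 0, 0),
                                projection_radius = cfg$projection_radius_um),
                  error = function(e) NULL)
  io_ok <- pairs$io_total_deg[!is.na(pairs$io_total_deg)]
  med_io <- stats::median(io_ok)
  io_keep <- io_ok[io_ok <= 5 * med_io]
  sk <- records$skew_deg[!is.na(records$skew_deg)]
  summary <- list(
    count = nrow(records),
    diameter_mean_um = mean(records$diameter_um, na.rm = TRUE),
    diameter_sd_um = stats::sd(records$diameter_um, na.rm = TRUE),
    adjusted_diameter_mean_um = mean(records$adjusted_diameter_um, na.rm = TRUE),
    skew_median_deg = stats::median(sk),
    skew_iqr_deg = stats::IQR(sk),
    io_median_deg = stats::median(io_keep),
    io_iqr_deg = stats::IQR(io_keep),
    n_pairs = nrow(pairs),
    n_pairs_outlier = sum(io_ok > 5 * med_io),
    fov_horizontal_deg = if (is.null(fov)) NA_real_ else fov$fov_horizontal,
    fov_vertical_deg = if (is.null(fov)) NA_real_ else fov$fov_vertical)
  structure(list(sphere = sphere, section = section, centers = centers,
                 clusters = clusters, records = records, pairs = pairs,
                 fov = fov, summary = summary, config = cfg),
            class = "oda3d_result")
}

#' @export
print.oda3d_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<oda3d_result>\n  ommatidia: %d\n  lens diameter: %.2f +/- %.2f um",
    " (adjusted %.2f)\n  skewness: %.2f (IQR %.2f) deg\n",
    "  anatomical IO angle: %.3f (IQR %.3f) deg over %d pairs\n",
    "  field of view: %.1f x %.1f deg\n"),
    s$count, s$diameter_mean_um, s$diameter_sd_um,
    s$adjusted_diameter_mean_um, s$skew_median_deg, s$skew_iqr_deg,
    s$io_median_deg, s$io_iqr_deg, s$n_pairs,
    s$fov_horizontal_deg, s$fov_vertical_deg))
  invisible(x)
}
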