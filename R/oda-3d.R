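# Volumetric (micro-CT) pipeline, stage by stage:
#   density-filtered voxel cloud -> sphere fit -> radius surface and 50%
#   cross-section -> spherically projected raster images -> 2D detector ->
#   nearest-center clusters -> per-cone and per-pair measurements.

#' Eye point cloud
#'
#' @param coords N x 3 matrix of positions (um).
#' @param density per-point density scalar from the scan.
#' @param provenance slice index (or other origin tag) per point.
#' @return object of class `eye_point_cloud`.
#' @export
eye_point_cloud <- function(coords, density = rep(NA_real_, nrow(coords)),
                            provenance = rep(NA_integer_, nrow(coords))) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || !all(is.finite(coords)))
    io_error("coords must be a finite N x 3 matrix")
  structure(list(coords = coords, density = density, provenance = provenance),
            class = "eye_point_cloud")
}

#' @export
print.eye_point_cloud <- function(x, ...) {
  cat(sprintf("<eye_point_cloud> %d points\n", nrow(x$coords)))
  invisible(x)
}

#' Load a micro-CT slice stack into a density-filtered point cloud
#'
#' Reads a directory of TIFF slices (sorted by file name, slice index = z),
#' keeps the voxels whose density lies within `density_range` (inclusive;
#' this replaces interactive density picking), and scales voxel indices to
#' micrometers.
#'
#' @param directory path containing TIFF slices, or a 3D array (slices along
#'   the third dimension) for pre-loaded data.
#' @param voxel_size voxel edge length in micrometers.
#' @param density_range length-2 inclusive density window on the stored pixel
#'   scale (e.g. 0..255 for 8-bit).
#' @return an `eye_point_cloud`; coordinates are `index * voxel_size` with
#'   x = column, y = row, z = slice.
#' @export
load_stack <- function(directory, voxel_size, density_range) {
  if (voxel_size <= 0) config_error("voxel_size must be positive")
  if (length(density_range) != 2L || density_range[1] > density_range[2])
    config_error("density_range must be c(low, high)")
  stack <- if (is.array(directory) && length(dim(directory)) == 3L) {
    directory
  } else {
    read_stack(directory)
  }
  sel <- which(stack >= density_range[1] & stack <= density_range[2],
               arr.ind = TRUE)
  if (nrow(sel) == 0L)
    io_error(sprintf("no voxels with density in [%g, %g]",
                     density_range[1], density_range[2]))
  coords <- cbind(x = sel[, 2], y = sel[, 1], z = sel[, 3]) * voxel_size
  eye_point_cloud(coords, density = stack[sel], provenance = sel[, 3])
}

#' Select the 50%-residual cross-section of an eye point cloud
#'
#' Rotates the cloud into the eye frame (sphere center at the origin, cloud
#' centroid facing +x), models point radius as a smoothed function of
#' elevation and azimuth on a regular angular grid, and keeps the points
#' whose residual from that surface lies in the central 50% band (25th-75th
#' percentile, ties broken by point index).
#'
#' @param cloud an `eye_point_cloud` (or N x 3 matrix).
#' @param sphere a `sphere_fit` for the cloud.
#' @param angular_step_deg grid step of the radius surface; default half the
#'   expected angular lens diameter when given, otherwise chosen so cells
#'   average about 20 points.
#' @param expected_angular_diameter_deg optional prior on the angular lens
#'   diameter (`D / R`, in degrees).
#' @return object of class `cross_section` with member indices, eye-frame
#'   coordinates and spherical coordinates of the members, the fitted
#'   surface, and the eye-frame rotation.
#' @export
make_cross_section <- function(cloud, sphere, angular_step_deg = NULL,
                               expected_angular_diameter_deg = NULL) {
  coords <- if (inherits(cloud, "eye_point_cloud")) cloud$coords else as.matrix(cloud)
  stopifnot(inherits(sphere, "sphere_fit"))
  Rm <- rotation_to_x(colMeans(coords) - sphere$center)
  coords_eye <- sweep(coords, 2, sphere$center) %*% t(Rm)
  sph <- to_spherical(coords_eye)
  n <- nrow(coords)
  if (is.null(angular_step_deg)) {
    angular_step_deg <- if (!is.null(expected_angular_diameter_deg)) {
      expected_angular_diameter_deg / 2
    } else {
      area <- diff(range(sph[, 1])) * diff(range(sph[, 2]))
      max(0.25, sqrt(area * 20 / n))
    }
  }
  surf <- tryCatch(
    fit_radius_surface(sph[, 1], sph[, 2], sph[, 3], angular_step_deg),
    error = function(e) {
      warning("radius-surface fit failed; falling back to constant sphere radius")
      NULL
    })
  resid <- if (is.null(surf)) sph[, 3] - sphere$radius
           else sph[, 3] - eval_radius_surface(surf, sph[, 1], sph[, 2])
  ord <- order(resid)  # stable: ties broken by index
  members <- sort(ord[(floor(n / 4) + 1):floor(3 * n / 4)])
  structure(list(indices = members,
                 coords_eye = coords_eye,
                 spherical = sph,
                 residuals = resid,
                 surface = surf,
                 rotation = Rm,
                 sphere = sphere),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %d member points (central 50%% of residuals)\n",
              length(x$indices)))
  invisible(x)
}

# 2D histogram of (elevation, azimuth) into a count image
angular_histogram <- function(el, az, bin_deg) {
  el_rng <- range(el); az_rng <- range(az)
  ne <- max(8L, ceiling(diff(el_rng) / bin_deg))
  na_ <- max(8L, ceiling(diff(az_rng) / bin_deg))
  ei <- pmin(ne, pmax(1L, 1L + floor((el - el_rng[1]) / diff(el_rng) * ne)))
  ai <- pmin(na_, pmax(1L, 1L + floor((az - az_rng[1]) / diff(az_rng) * na_)))
  counts <- matrix(tabulate((ai - 1L) * ne + ei, nbins = ne * na_), ne, na_)
  list(counts = counts,
       el_centers = el_rng[1] + (seq_len(ne) - 0.5) / ne * diff(el_rng),
       az_centers = az_rng[1] + (seq_len(na_) - 0.5) / na_ * diff(az_rng))
}

#' Detect approximate lens centers on rasterized cross-section images
#'
#' Splits the cross-section into angular segments (default 90 x 90 degrees),
#' recenters each segment toward the projection pole to limit spherical
#' warping, rasterizes a 2D (elevation, azimuth) count histogram, runs the 2D
#' detector [run_oda()] on it, and maps detected maxima back to 3D via the
#' nearest cross-section point. Centers from different segments closer than
#' half the expected lens diameter are merged.
#'
#' @param section a `cross_section`.
#' @param window_deg angular segment size in degrees (default 90).
#' @param expected_diameter_um optional prior lens diameter, used for the
#'   histogram bin size (angular diameter / 4); otherwise the bin size is
#'   chosen to give a 256-bin segment image.
#' @param n_fundamentals passed to [run_oda()].
#' @param min_points segments with fewer member points are skipped (with a
#'   warning).
#' @return matrix with one row per detected center: eye-frame `x`, `y`, `z`,
#'   `elevation`, `azimuth`, and `point` (index of the supporting
#'   cross-section member).
#' @export
rasterize_and_detect <- function(section, window_deg = 90,
                                 expected_diameter_um = NULL,
                                 n_fundamentals = 3, min_points = 50) {
  stopifnot(inherits(section, "cross_section"))
  memb <- section$indices
  sph <- section$spherical[memb, , drop = FALSE]
  coords_m <- section$coords_eye[memb, , drop = FALSE]
  empty <- matrix(numeric(0), 0, 6,
                  dimnames = list(NULL, c("x", "y", "z", "elevation", "azimuth", "point")))
  if (nrow(sph) == 0L) return(empty)
  med_r <- stats::median(sph[, 3])
  el_rng <- range(sph[, 1]); az_rng <- range(sph[, 2])
  n_el <- max(1L, ceiling(diff(el_rng) / window_deg))
  n_az <- max(1L, ceiling(diff(az_rng) / window_deg))
  el_edges <- seq(el_rng[1], el_rng[2], length.out = n_el + 1)
  az_edges <- seq(az_rng[1], az_rng[2], length.out = n_az + 1)
  # segments are rasterized with a margin so the lattice continues past each
  # segment's core; a detection is owned by the segment whose core contains
  # it, which keeps segment joins free of duplicated or clipped centers
  margin <- if (!is.null(expected_diameter_um)) {
    2 * (expected_diameter_um / med_r) * (180 / pi)
  } else {
    0.05 * window_deg
  }
  cand <- list()
  est_diam <- c()
  for (i in seq_len(n_el)) for (j in seq_len(n_az)) {
    in_seg <- sph[, 1] >= el_edges[i] - margin & sph[, 1] <= el_edges[i + 1] + margin &
              sph[, 2] >= az_edges[j] - margin & sph[, 2] <= az_edges[j + 1] + margin
    if (sum(in_seg) < min_points) {
      if (any(in_seg)) warning(sprintf("segment (%d, %d): too few points, skipped", i, j))
      next
    }
    pts_seg <- coords_m[in_seg, , drop = FALSE]
    # recenter: rotate segment centroid direction onto +x
    R2 <- rotation_to_x(colMeans(pts_seg))
    sph2 <- to_spherical(pts_seg %*% t(R2))
    bin_deg <- if (!is.null(expected_diameter_um)) {
      (expected_diameter_um / med_r) * (180 / pi) / 4
    } else {
      max(diff(range(sph2[, 1])), diff(range(sph2[, 2]))) / 256
    }
    h <- angular_histogram(sph2[, 1], sph2[, 2], bin_deg)
    res <- tryCatch(run_oda(h$counts, n_fundamentals = n_fundamentals),
                    error = function(e) NULL)
    if (is.null(res) || res$count == 0L) {
      warning(sprintf("segment (%d, %d): no lattice detected, skipped", i, j))
      next
    }
    est_diam <- c(est_diam,
                  res$fft_diameter_px * bin_deg * pi / 180 * med_r / (sqrt(3) / 2))
    ctr_el <- h$el_centers[pmin(length(h$el_centers), pmax(1, round(res$centers[, "row"])))]
    ctr_az <- h$az_centers[pmin(length(h$az_centers), pmax(1, round(res$centers[, "col"])))]
    # nearest member point in the segment frame
    seg_idx <- which(in_seg)
    near <- vapply(seq_along(ctr_el), function(k) {
      d2 <- (sph2[, 1] - ctr_el[k])^2 + (sph2[, 2] - ctr_az[k])^2
      seg_idx[which.min(d2)]
    }, integer(1))
    # core ownership (half-open; outermost tiles closed at the global edge)
    el_hi <- if (i == n_el) Inf else el_edges[i + 1]
    az_hi <- if (j == n_az) Inf else az_edges[j + 1]
    in_core <- sph[near, 1] >= el_edges[i] - (i == 1) & sph[near, 1] < el_hi &
               sph[near, 2] >= az_edges[j] - (j == 1) & sph[near, 2] < az_hi
    cand[[length(cand) + 1L]] <- near[in_core]
  }
  if (!length(cand)) return(empty)
  near_all <- memb[unlist(cand)]
  diam <- if (!is.null(expected_diameter_um)) expected_diameter_um else stats::median(est_diam)
  # duplicate suppression across segment boundaries
  acc <- integer(0)
  P <- section$coords_eye
  for (k in near_all) {
    if (!length(acc)) { acc <- k; next }
    d2 <- (P[acc, 1] - P[k, 1])^2 + (P[acc, 2] - P[k, 2])^2 + (P[acc, 3] - P[k, 3])^2
    if (min(d2) >= (0.5 * diam)^2) acc <- c(acc, k)
  }
  out <- cbind(P[acc, 1], P[acc, 2], P[acc, 3],
               section$spherical[acc, 1], section$spherical[acc, 2], acc)
  colnames(out) <- c("x", "y", "z", "elevation", "azimuth", "point")
  out
}

#' Partition the point cloud into per-ommatidium clusters
#'
#' Labels every cloud point (both residual halves, so clusters are whole
#' crystalline cones) with its nearest approximate center in the projected
#' (elevation, azimuth) plane, then recomputes cluster centroids in 3D.
#'
#' @param section a `cross_section`.
#' @param centers matrix from [rasterize_and_detect()] (or any matrix with
#'   `elevation` and `azimuth` columns).
#' @return object of class `cluster_set`: per-point `labels`, per-cluster 3D
#'   `centroids` (eye frame), angular centroid positions, and `problematic`
#'   flags (filled by [correct_problem_clusters()]).
#' @export
assign_clusters <- function(section, centers) {
  stopifnot(inherits(section, "cross_section"))
  if (is.null(nrow(centers)) || nrow(centers) < 1L)
    config_error("need at least one center")
  sph <- section$spherical
  K <- nrow(centers)
  n <- nrow(sph)
  labels <- integer(n)
  chunk <- max(1L, floor(2e6 / K))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(sph[s:e, 1], centers[, "elevation"], "-")^2 +
          outer(sph[s:e, 2], centers[, "azimuth"], "-")^2
    labels[s:e] <- max.col(-d2, ties.method = "first")
  }
  centroids <- t(vapply(seq_len(K), function(k) {
    m <- labels == k
    if (any(m)) colMeans(section$coords_eye[m, , drop = FALSE]) else rep(NA_real_, 3)
  }, numeric(3)))
  structure(list(labels = labels, centroids = centroids,
                 centers_angular = centers[, c("elevation", "azimuth"), drop = FALSE],
                 problematic = rep(FALSE, K), section = section),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d points (%d flagged problematic)\n",
              nrow(x$centroids), length(x$labels), sum(x$problematic)))
  invisible(x)
}

# per-point misneighbor indicator for a subset of points: TRUE when a point's
# nearest other point (within the subset) carries a different label
misneighbored <- function(P, lab) {
  n <- nrow(P)
  bad <- logical(n)
  for (m in seq_len(n)) {
    d2 <- (P[, 1] - P[m, 1])^2 + (P[, 2] - P[m, 2])^2 + (P[, 3] - P[m, 3])^2
    d2[m] <- Inf
    bad[m] <- lab[which.min(d2)] != lab[m]
  }
  bad
}

# fraction of a cluster's points whose nearest other point (within the local
# neighborhood of clusters) belongs to a different cluster
misneighbor_fractions <- function(clusters, k_neighbors = 6L) {
  P <- clusters$section$coords_eye
  lab <- clusters$labels
  cen <- clusters$centroids
  K <- nrow(cen)
  frac <- rep(0, K)
  cen_ok <- which(!is.na(cen[, 1]))
  for (k in cen_ok) {
    d2c <- (cen[cen_ok, 1] - cen[k, 1])^2 + (cen[cen_ok, 2] - cen[k, 2])^2 +
           (cen[cen_ok, 3] - cen[k, 3])^2
    nb <- cen_ok[order(d2c)][seq_len(min(k_neighbors + 1L, length(cen_ok)))]
    sel <- which(lab %in% nb)
    if (length(sel) < 2L) next
    sub <- P[sel, , drop = FALSE]
    sl <- lab[sel]
    mine <- which(sl == k)
    if (!length(mine)) next
    bad <- 0L
    for (m in mine) {
      d2 <- (sub[, 1] - sub[m, 1])^2 + (sub[, 2] - sub[m, 2])^2 +
            (sub[, 3] - sub[m, 3])^2
      d2[m] <- Inf
      if (sl[which.min(d2)] != k) bad <- bad + 1L
    }
    frac[k] <- bad / length(mine)
  }
  frac
}

# objective for cluster-correction: given a projection direction (two angles),
# re-partition the neighborhood's points by nearest centroid in the projected
# plane; score = mean projected point-to-center distance (um) + mean aspect
# ratio (longest/shortest extent) of the projected clusters. Cones are
# elongated along their longitudinal axes, so projecting along that axis
# makes the footprints round (aspect ~ 1) and tight: the minimum sits at the
# plane orthogonal to the local ommatidial axes.
correction_objective <- function(angles, pts, cen_sub) {
  a <- angles[1]; b <- angles[2]
  nvec <- c(cos(b) * cos(a), cos(b) * sin(a), sin(b))
  # orthonormal basis of the projection plane
  e1 <- unit3(cross3(nvec, if (abs(nvec[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)))
  e2 <- cross3(nvec, e1)
  B <- cbind(e1, e2)
  p2 <- pts %*% B
  c2 <- cen_sub %*% B
  d2 <- outer(p2[, 1], c2[, 1], "-")^2 + outer(p2[, 2], c2[, 2], "-")^2
  newlab <- max.col(-d2, ties.method = "first")
  mean_dist <- mean(sqrt(d2[cbind(seq_len(nrow(p2)), newlab)]))
  aspects <- vapply(seq_len(nrow(c2)), function(j) {
    m <- newlab == j
    if (sum(m) < 3L) return(1)
    sv <- svd(scale(p2[m, , drop = FALSE], scale = FALSE), nu = 0, nv = 0)$d
    sv[1] / max(sv[2], 1e-9)
  }, numeric(1))
  list(value = mean_dist + mean(aspects), labels = newlab)
}

#' Identify and correct problematic clusters
#'
#' A cluster is problematic when at least 10% of its points have their
#' nearest neighboring point in a different cluster (a symptom of skewed,
#' overlapping projections). For each such cluster, the neighborhood of its 6
#' nearest clusters is re-partitioned by searching over projection-plane
#' orientations with a seeded differential-evolution optimizer, minimizing
#' the mean projected point-to-center distance plus the clusters' 3D aspect
#' ratio. A correction is kept only if it drops the cluster's misassigned
#' fraction below 5%.
#'
#' @param clusters a `cluster_set`.
#' @param flag_threshold fraction of misneighbored points that flags a
#'   cluster (default 0.10).
#' @param accept_threshold maximum misneighbored fraction after correction
#'   for it to be accepted (default 0.05).
#' @param seed integer seed for the optimizer.
#' @param de_iter,de_pop optimizer budget (generations, population size).
#' @return updated `cluster_set`; `problematic` marks clusters still flagged
#'   after correction, and attribute `n_flagged_before` records the initial
#'   flag count.
#' @export
correct_problem_clusters <- function(clusters, flag_threshold = 0.10,
                                     accept_threshold = 0.05, seed = 1L,
                                     de_iter = 20L, de_pop = 15L) {
  stopifnot(inherits(clusters, "cluster_set"))
  frac <- misneighbor_fractions(clusters)
  flagged <- which(frac >= flag_threshold)
  attr(clusters, "n_flagged_before") <- length(flagged)
  clusters$problematic <- frac >= flag_threshold
  if (!length(flagged)) return(clusters)
  P <- clusters$section$coords_eye
  for (k in flagged) {
    cen <- clusters$centroids
    cen_ok <- which(!is.na(cen[, 1]))
    d2c <- (cen[cen_ok, 1] - cen[k, 1])^2 + (cen[cen_ok, 2] - cen[k, 2])^2 +
           (cen[cen_ok, 3] - cen[k, 3])^2
    nb <- cen_ok[order(d2c)][seq_len(min(7L, length(cen_ok)))]
    sel <- which(clusters$labels %in% nb)
    pts <- P[sel, , drop = FALSE]
    cen_sub <- cen[nb, , drop = FALSE]
    obj <- function(x) correction_objective(x, pts, cen_sub)$value
    fit <- tryCatch(
      de_optimize(obj, lower = c(-pi, -pi / 2), upper = c(pi, pi / 2),
                  seed = seed + k, n_pop = de_pop, n_iter = de_iter),
      error = function(e) NULL)
    if (is.null(fit)) { warning("optimizer failed; keeping original labels"); next }
    res <- correction_objective(fit$par, pts, cen_sub)
    # accept only if the neighborhood's misassigned-element fraction becomes
    # small; judged locally over the re-partitioned points
    new_frac <- mean(misneighbored(pts, nb[res$labels]))
    if (new_frac < accept_threshold) {
      clusters$labels[sel] <- nb[res$labels]
      for (j in nb) {
        m <- clusters$labels == j
        clusters$centroids[j, ] <-
          if (any(m)) colMeans(P[m, , drop = FALSE]) else rep(NA_real_, 3)
      }
    }
  }
  clusters$problematic <- misneighbor_fractions(clusters) >= flag_threshold
  clusters
}
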