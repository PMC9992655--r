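# Local-maximum detection with minimum-distance suppression.
#
# The 2D detector and the reciprocal-space peak finder both reduce to the same
# primitive: find pixels that are maximal over a square neighborhood, merge
# equal-valued plateaus into their centroids, then greedily suppress maxima
# closer together than a minimum distance, keeping the brighter one (ties:
# smaller row, then smaller column — a fixed, deterministic order).

# Running maximum filter with a (2r+1) square footprint, via shifted pmax.
max_filter <- function(m, r) {
  if (r < 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (k in seq_len(r)) {           # rows
    out <- pmax(out,
                rbind(m[-seq_len(k), , drop = FALSE],
                      matrix(-Inf, k, nc)),
                rbind(matrix(-Inf, k, nc),
                      m[seq_len(nr - k), , drop = FALSE]))
  }
  # column pass on the row-filtered image (separable decomposition)
  res <- out
  for (k in seq_len(r)) {
    res <- pmax(res,
                cbind(out[, -seq_len(k), drop = FALSE],
                      matrix(-Inf, nr, k)),
                cbind(matrix(-Inf, nr, k),
                      out[, seq_len(nc - k), drop = FALSE]))
  }
  res
}

# Group candidate peak pixels that are 8-connected and equal-valued into
# plateau centroids. cand: matrix with columns row, col, value.
merge_plateaus <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  o <- order(cand[, "value"], cand[, "row"], cand[, "col"])
  cand <- cand[o, , drop = FALSE]
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  # candidates sharing a value are contiguous after sorting; check adjacency
  # only within equal-value runs (plateaus)
  runs <- split(seq_len(n), cand[, "value"])
  for (idx in runs) {
    if (length(idx) < 2L) next
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      i <- idx[a]; j <- idx[b]
      if (abs(cand[i, "row"] - cand[j, "row"]) <= 1 &&
          abs(cand[i, "col"] - cand[j, "col"]) <= 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(root), function(r) {
    g <- cand[root == r, , drop = FALSE]
    c(row = mean(g[, "row"]), col = mean(g[, "col"]),
      value = unname(g[1, "value"]))
  }))
  out
}

# Quadratic 1D sub-pixel offset from three samples around a maximum.
quad_offset <- function(vm, v0, vp) {
  den <- vm - 2 * v0 + vp
  if (den >= 0) return(0)   # not a proper maximum of the parabola
  off <- 0.5 * (vm - vp) / den
  max(-0.5, min(0.5, off))
}

#' Find local maxima with minimum-distance suppression
#'
#' Detects all local maxima of a matrix (pixels equal to the maximum of their
#' square neighborhood of radius `ceiling(min_distance)`), merges equal-valued
#' plateaus into centroids, and greedily suppresses maxima closer than
#' `min_distance`, keeping the brighter (ties broken top-left-most).
#'
#' @param m numeric matrix.
#' @param min_distance minimum allowed separation between accepted maxima, px.
#' @param threshold only pixels strictly above this value are candidates
#'   (default `-Inf`).
#' @param subpixel if `TRUE`, refine each accepted maximum by separable
#'   quadratic interpolation (off by default).
#' @param mask optional logical matrix: candidate maxima outside it are
#'   discarded *before* suppression, so masked-out background cannot shadow
#'   foreground maxima.
#' @return matrix with columns `row`, `col`, `value`, ordered by decreasing
#'   value (then row, then column).
#' @export
find_local_maxima <- function(m, min_distance = 1, threshold = -Inf,
                              subpixel = FALSE, mask = NULL) {
  r <- max(1L, min(ceiling(min_distance), nrow(m) - 1L, ncol(m) - 1L))
  mf <- max_filter(m, r)
  is_peak <- (m == mf) & (m > threshold)
  if (!is.null(mask)) is_peak <- is_peak & mask
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("row", "col", "value"))))
  cand <- cbind(row = idx[, 1], col = idx[, 2], value = m[idx])
  cand <- merge_plateaus(cand)
  # deterministic order: brightness desc, then row, then col
  o <- order(-cand[, "value"], cand[, "row"], cand[, "col"])
  cand <- cand[o, , drop = FALSE]
  acc <- matrix(numeric(0), 0, 3)
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, ]
    if (nrow(acc) == 0L ||
        all((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2 >= min_distance^2)) {
      acc <- rbind(acc, p)
    }
  }
  colnames(acc) <- c("row", "col", "value")
  rownames(acc) <- NULL
  if (subpixel && nrow(acc) > 0L) {
    for (k in seq_len(nrow(acc))) {
      i <- round(acc[k, 1]); j <- round(acc[k, 2])
      if (i > 1 && i < nrow(m) && j > 1 && j < ncol(m)) {
        acc[k, 1] <- i + quad_offset(m[i - 1, j], m[i, j], m[i + 1, j])
        acc[k, 2] <- j + quad_offset(m[i, j - 1], m[i, j], m[i, j + 1])
      }
    }
  }
  acc
}
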