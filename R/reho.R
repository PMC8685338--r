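# Regional homogeneity on a surface: Kendall's coefficient of concordance
# (KCC, Kendall's W) over each vertex and its k-ring neighborhood. With
# the default two-ring neighborhood a regular degree-6 vertex contributes
# K = 19 series (seed + 18 neighbors) of length n timepoints.

rank_rows <- function(x) t(apply(x, 1, rank))  # midranks for ties

tie_term <- function(r) {
  # sum over tie groups of (t^3 - t) for one ranked series
  tb <- tabulate(match(r, unique(r)))
  sum(tb^3 - tb)
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement of K rankings of n timepoints. Each series is ranked over
#' time (midranks for ties); with rank sums R_i per timepoint and
#' S = sum over i of (R_i - mean(R))^2,
#' W = 12 S / (K^2 (n^3 - n) - K sum_j T_j), where T_j is series j's tie
#' correction sum over tie groups of (t^3 - t) (dropped when
#' `tie_correction = FALSE`). The result is clamped to [0, 1] against
#' rounding. A zero or negative denominator (all series constant with the
#' correction on, or constant series with it off) returns 0 with a
#' warning — the degenerate-synchrony policy.
#'
#' @param series K x n numeric matrix: K time series of n timepoints.
#' @param tie_correction apply the tie term (default TRUE).
#' @return W in [0, 1].
#' @export
kendalls_w <- function(series, tie_correction = TRUE) {
  series <- as.matrix(series)
  k <- nrow(series); n <- ncol(series)
  if (k < 2L) stop("need at least K = 2 series")
  if (n < 2L) stop("need at least n = 2 timepoints")
  r <- rank_rows(series)
  ri <- colSums(r)
  s <- sum((ri - mean(ri))^2)
  denom <- k^2 * (n^3 - n)
  if (tie_correction) denom <- denom - k * sum(apply(r, 1, tie_term))
  if (denom <= 0) {
    warning("degenerate input: zero concordance denominator; returning W = 0")
    return(0)
  }
  min(max(12 * s / denom, 0), 1)
}

#' Whole-surface 2dReHo map
#'
#' For every masked-in vertex, Kendall's W over the time series of the
#' vertex and its ring-k neighbors (restricted to masked-in vertices;
#' K = 19 at a regular vertex with the default `ring = 2`). Zero-variance
#' series are excluded from their neighborhoods rather than failing; a
#' vertex whose neighborhood retains fewer than 2 usable series is masked
#' out (with a message).
#'
#' The map is computed by a vectorized sparse rank-sum accumulation; it is
#' exactly equal to calling [kendalls_w()] vertex by vertex, which the
#' test suite verifies by brute force.
#'
#' @param ts a `surface_timeseries` bound to `mesh`.
#' @param mesh the `triangle_mesh` (defaults to the mesh bound to `ts`).
#' @param mask a `cortex_mask`; default full mask.
#' @param ring neighborhood ring radius (>= 1; default 2).
#' @param tie_correction passed to the W computation.
#' @param incidence optional precomputed [kring_incidence()] matrix
#'   (reused across the subjects of a cohort).
#' @return a `surface_map` of W values.
#' @export
reho_map <- function(ts, mesh = ts$mesh, mask = full_mask(mesh), ring = 2L,
                     tie_correction = TRUE, incidence = NULL) {
  v <- n_vertices(mesh)
  if (nrow(ts$data) != v) stop("time series not bound to this mesh")
  if (ring < 1L) stop("ring must be >= 1")
  n <- ncol(ts$data)
  if (is.null(incidence)) incidence <- kring_incidence(mesh, ring)

  variances <- apply(ts$data, 1, stats::var)
  usable <- mask$keep & variances > 0
  if (any(mask$keep & !usable))
    message(sum(mask$keep & !usable), " zero-variance series excluded from neighborhoods")

  r <- matrix(0, v, n)
  t_j <- numeric(v)
  if (any(usable)) {
    r[usable, ] <- rank_rows(ts$data[usable, , drop = FALSE])
    t_j[usable] <- apply(r[usable, , drop = FALSE], 1, tie_term)
  }
  inc <- incidence
  if (any(!usable)) {
    inc[, which(!usable)] <- 0
    inc <- Matrix::drop0(inc)
  }
  k_v <- as.numeric(Matrix::rowSums(inc))

  rs <- as.matrix(inc %*% r)               # V x n rank sums
  s_v <- rowSums((rs - rowMeans(rs))^2)
  denom <- k_v^2 * (n^3 - n)
  if (tie_correction) denom <- denom - k_v * as.numeric(inc %*% t_j)

  w <- rep(NA_real_, v)
  ok <- mask$keep & k_v >= 2 & denom > 0
  w[ok] <- pmin(pmax(12 * s_v[ok] / denom[ok], 0), 1)
  dropped <- mask$keep & !ok
  if (any(dropped))
    message(sum(dropped), " vertex/vertices masked out (fewer than 2 usable series ",
            "or degenerate denominator)")
  surface_map(w, mesh, cortex_mask(mask$keep & ok, mesh))
}

#' Geodesic Gaussian smoothing of a surface map
#'
#' Per-vertex weighted average with weights exp(-d^2 / (2 sigma^2)),
#' sigma = fwhm / 2.3548, where d is the geodesic (edge-graph Dijkstra)
#' distance truncated at 3 sigma. Rows are renormalized over masked-in
#' vertices, so constants are preserved exactly and the output range is
#' bounded by the input range.
#'
#' @param map a `surface_map`.
#' @param mesh mesh (defaults to the map's mesh).
#' @param fwhm kernel full width at half maximum in mm (default 10, the
#'   conventional surface smoothing scale for group ReHo maps).
#' @param weights optional precomputed weight matrix from
#'   [smoothing_weights()], reused across the maps of a cohort.
#' @return smoothed `surface_map` (same mask) with `smoothed_fwhm` set.
#' @export
surface_smooth <- function(map, mesh = map$mesh, fwhm = 10, weights = NULL) {
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (is.null(weights)) weights <- smoothing_weights(mesh, fwhm)
  keep <- map$mask$keep
  w <- weights
  if (any(!keep)) {
    w[, which(!keep)] <- 0
    w <- Matrix::drop0(w)
  }
  vals <- ifelse(keep, map$values, 0)
  num <- as.numeric(w %*% vals)
  den <- as.numeric(Matrix::rowSums(w))
  out <- rep(NA_real_, length(vals))
  out[keep] <- num[keep] / den[keep]
  surface_map(out, mesh, map$mask, smoothed_fwhm = fwhm)
}

#' Gaussian geodesic smoothing weight matrix
#'
#' @param mesh a `triangle_mesh`.
#' @param fwhm kernel FWHM in mm.
#' @return sparse V x V matrix of unnormalized kernel weights (diagonal
#'   included); rows are normalized at smoothing time against the map mask.
#' @export
smoothing_weights <- function(mesh, fwhm) {
  sigma <- fwhm / 2.3548
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean_edge <- mean(sqrt(rowSums(d^2)))
  if (fwhm < mean_edge)
    warning(sprintf("fwhm (%g mm) below mean edge length (%.2f mm): kernel under-resolved",
                    fwhm, mean_edge))
  dists <- geodesic_neighbor_distances(mesh, cutoff = 3 * sigma)
  w <- dists
  w@x <- exp(-dists@x^2 / (2 * sigma^2))
  Matrix::Diagonal(n_vertices(mesh)) + w
}

#' Global mean of a surface map
#'
#' Mean (or vertex-area-weighted mean) of the masked-in values: the
#' "global 2dReHo" summary compared between groups.
#'
#' @param map a `surface_map`.
#' @param areas vertex areas (required for `weighting = "area"`).
#' @param weighting `"uniform"` or `"area"`.
#' @return scalar.
#' @export
global_reho <- function(map, areas = NULL, weighting = c("uniform", "area")) {
  weighting <- match.arg(weighting)
  keep <- map$mask$keep & !is.na(map$values)
  if (!any(keep)) stop("empty mask: no vertices to average")
  if (weighting == "uniform") return(mean(map$values[keep]))
  if (is.null(areas)) stop("area weighting requires vertex areas")
  stats::weighted.mean(map$values[keep], areas[keep])
}
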