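# Functional preprocessing: mid-thickness construction, volume-to-surface
# trilinear sampling, Friston-24 motion expansion, nuisance regression
# (white-matter/CSF means + motion; the global signal is deliberately NOT
# a regressor by default), band-pass filtering, initial-volume removal.

#' Mid-thickness surface from white and pial surfaces
#'
#' Vertex i of the result is the midpoint of white vertex i and pial
#' vertex i; topology is carried over unchanged. The mid-thickness is the
#' sampling locus for volume-to-surface projection.
#'
#' @param white,pial `triangle_mesh` objects with identical topology.
#' @return a `triangle_mesh`.
#' @export
midthickness <- function(white, pial) {
  if (n_vertices(white) != n_vertices(pial))
    stop("white and pial vertex counts differ")
  if (!identical(white$triangles, pial$triangles))
    stop("white and pial triangle lists differ (topology mismatch)")
  triangle_mesh((white$vertices + pial$vertices) / 2, white$triangles,
                hemisphere = white$hemisphere)
}

#' Sample a volumetric time series onto a surface
#'
#' Maps each vertex's world coordinate through `affine_world_to_voxel` to
#' a continuous 0-based voxel index and samples the volume there by
#' trilinear interpolation, at every timepoint. Trilinear interpolation
#' reproduces affine intensity fields exactly, which is this module's
#' sharpest correctness oracle.
#'
#' @param volume a `volume_timeseries`.
#' @param surface the `triangle_mesh` to sample at (typically the
#'   mid-thickness surface).
#' @param affine_world_to_voxel 4x4 matrix mapping world mm to 0-based
#'   continuous voxel index; defaults to the inverse of the volume's
#'   voxel-to-world affine.
#' @param out_of_view `"exclude"` (default: masked out with a warning) or
#'   `"fail"` for vertices mapping outside the voxel grid.
#' @return list with `ts` (a `surface_timeseries`; out-of-view rows 0) and
#'   `mask` (a `cortex_mask` with out-of-view vertices dropped).
#' @export
vol_to_surf <- function(volume, surface,
                        affine_world_to_voxel = solve(volume$affine),
                        out_of_view = c("exclude", "fail")) {
  out_of_view <- match.arg(out_of_view)
  v <- n_vertices(surface)
  xyz1 <- cbind(surface$vertices, 1)
  ijk <- xyz1 %*% t(affine_world_to_voxel)
  vals <- trilinear_sample(volume$data, ijk[, 1:3, drop = FALSE])
  keep <- !is.na(vals[, 1])
  if (!all(keep)) {
    msg <- sprintf("%d of %d vertices map outside the volume field of view",
                   sum(!keep), v)
    if (out_of_view == "fail") stop(msg)
    warning(msg, "; excluded from the cortex mask")
    vals[!keep, ] <- 0
  }
  list(ts = surface_timeseries(vals, surface, tr = volume$tr),
       mask = cortex_mask(keep, surface))
}

#' Friston-24 motion regressor expansion
#'
#' Expands 6 rigid-body motion parameters into the 24-regressor set:
#' the parameters R(t), their squares R(t)^2, the one-frame lags R(t-1)
#' and squared lags R(t-1)^2. Lagged rows are zero-filled at the first
#' frame (the common convention).
#'
#' @param motion 6 x T matrix (3 translations mm, 3 rotations).
#' @return 24 x T numeric matrix.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (nrow(motion) != 6L) stop("motion must be a 6 x T matrix, got ", nrow(motion), " rows")
  tlen <- ncol(motion)
  if (tlen < 2L) stop("need at least 2 timepoints")
  lag1 <- cbind(0, motion[, -tlen, drop = FALSE])
  rbind(motion, motion^2, lag1, lag1^2)
}

#' Build a nuisance regressor set
#'
#' @param motion 6 x T motion parameters.
#' @param wm_mean,csf_mean length-T mean white-matter and CSF series.
#' @return object of class `nuisance_set`.
#' @export
nuisance_set <- function(motion, wm_mean, csf_mean) {
  motion <- as.matrix(motion)
  tlen <- ncol(motion)
  if (nrow(motion) != 6L) stop("motion must be 6 x T")
  if (length(wm_mean) != tlen || length(csf_mean) != tlen)
    stop("wm_mean and csf_mean must have length T = ", tlen)
  structure(list(motion = motion, wm_mean = as.numeric(wm_mean),
                 csf_mean = as.numeric(csf_mean)),
            class = "nuisance_set")
}

#' Regress nuisance signals out of a surface time series
#'
#' Ordinary least squares of every vertex series on an intercept, the
#' Friston-24 motion expansion and the white-matter and CSF mean series
#' (26 regressors + intercept). Residuals are returned; they are
#' orthogonal to every retained regressor. Columns that are identically
#' zero (e.g. zero motion) are dropped before fitting; remaining rank
#' deficiency is an error naming the collinear columns.
#'
#' @param ts a `surface_timeseries`.
#' @param nuisance a `nuisance_set`; NULL fits intercept only (demeaning).
#' @return a `surface_timeseries` of residuals.
#' @export
nuisance_regress <- function(ts, nuisance = NULL) {
  tlen <- ncol(ts$data)
  if (is.null(nuisance)) {
    x <- matrix(1, tlen, 1, dimnames = list(NULL, "intercept"))
  } else {
    if (ncol(nuisance$motion) != tlen)
      stop("nuisance length (", ncol(nuisance$motion), ") != time series length (", tlen, ")")
    fr <- t(friston24(nuisance$motion))
    colnames(fr) <- paste0("friston", seq_len(24L))
    x <- cbind(intercept = 1, fr, wm_mean = nuisance$wm_mean,
               csf_mean = nuisance$csf_mean)
  }
  zero <- apply(x, 2, function(col) all(col == 0))
  x <- x[, !zero, drop = FALSE]
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  resid <- t(qr.resid(qrx, t(ts$data)))
  surface_timeseries(resid, ts$mesh, ts$tr)
}

#' Band-pass filter a surface time series
#'
#' Frequency-domain filter on the discrete Fourier transform of each
#' vertex series. The default dialect is an ideal mask: bins with
#' low <= f <= high are kept, all others (including DC) zeroed, giving
#' deterministic, oracle-checkable gains. A Butterworth-gain variant is
#' available.
#'
#' @param ts a `surface_timeseries` (TR supplies the sampling rate).
#' @param low,high band edges in Hz; 0 <= low < high < Nyquist = 1/(2 TR).
#' @param dialect `"ideal"` or `"butterworth"`.
#' @param order Butterworth order (ignored for the ideal mask).
#' @return filtered `surface_timeseries`.
#' @export
bandpass <- function(ts, low = 0.01, high = 0.1,
                     dialect = c("ideal", "butterworth"), order = 4L) {
  dialect <- match.arg(dialect)
  nyq <- 1 / (2 * ts$tr)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high >= nyq) stop("high (", high, " Hz) must be below Nyquist (", nyq, " Hz)")
  tlen <- ncol(ts$data)
  f <- pmin(0:(tlen - 1), tlen - (0:(tlen - 1))) / (tlen * ts$tr)
  gain <- switch(dialect,
    ideal = as.numeric(f >= low & f <= high),
    butterworth = {
      g_hi <- 1 / sqrt(1 + (f / high)^(2 * order))
      g_lo <- ifelse(f > 0, 1 / sqrt(1 + (low / f)^(2 * order)), 0)
      g_hi * g_lo
    })
  spec <- stats::mvfft(t(ts$data)) * gain
  filtered <- t(Re(stats::mvfft(spec, inverse = TRUE)) / tlen)
  surface_timeseries(filtered, ts$mesh, ts$tr)
}

#' Drop initial volumes
#'
#' Removes the first `n_drop` frames of a surface or volumetric time
#' series (scanner equilibration discard; the emulated acquisition drops
#' 10 of 255 volumes).
#'
#' @param x `surface_timeseries` or `volume_timeseries`.
#' @param n_drop number of leading frames to discard (< T).
#' @return same class as `x` with T - n_drop frames.
#' @export
drop_initial_volumes <- function(x, n_drop = 10L) {
  n_drop <- as.integer(n_drop)
  if (n_drop < 0L) stop("n_drop must be >= 0")
  if (inherits(x, "surface_timeseries")) {
    if (n_drop >= ncol(x$data)) stop("n_drop (", n_drop, ") >= number of volumes (", ncol(x$data), ")")
    if (n_drop == 0L) return(x)
    surface_timeseries(x$data[, -seq_len(n_drop), drop = FALSE], x$mesh, x$tr)
  } else if (inherits(x, "volume_timeseries")) {
    if (n_drop >= dim(x$data)[4]) stop("n_drop (", n_drop, ") >= number of volumes (", dim(x$data)[4], ")")
    if (n_drop == 0L) return(x)
    volume_timeseries(x$data[, , , -seq_len(n_drop), drop = FALSE], x$affine, x$tr)
  } else stop("x must be a surface_timeseries or volume_timeseries")
}
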