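# Volumetric time-series container and a minimal uncompressed NIfTI-1
# reader/writer (float32/float64, sform affine). The affine maps 0-based
# voxel indices (voxel centers at integer indices) to world mm (RAS) —
# the NIfTI sform convention, declared here once to avoid half-voxel bugs.

#' Volumetric time series
#'
#' @param data 4D numeric array (nx, ny, nz, T); a 3D array is treated
#'   as a single volume.
#' @param affine 4x4 matrix mapping 0-based voxel index (i, j, k, 1) to
#'   world mm (x, y, z, 1).
#' @param tr repetition time in seconds.
#' @return object of class `volume_timeseries`.
#' @export
volume_timeseries <- function(data, affine, tr = 2) {
  data <- as.array(data)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must be a 3D or 4D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps * 100) stop("affine is singular")
  structure(list(data = data, affine = affine, tr = as.double(tr)),
            class = "volume_timeseries")
}

#' @export
print.volume_timeseries <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_timeseries: %d x %d x %d voxels, %d volumes, TR=%g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Write a volume as uncompressed NIfTI-1
#'
#' @param vol a `volume_timeseries`.
#' @param path destination `.nii` path.
#' @param datatype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dt_code <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L
  size <- bitpix / 8L
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                               # sizeof_hdr
  writeBin(raw(36), con)                    # data_type..dim_info
  wi(c(4L, d, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0))                            # intent_p1-3
  wi(0L, 2)                                 # intent_code
  wi(dt_code, 2); wi(bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  vox <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  wf(c(0, vox, vol$tr, 0, 0, 0))            # pixdim[8]
  wf(352)                                   # vox_offset
  wf(c(1, 0))                               # scl_slope, scl_inter
  writeBin(raw(4), con)                     # slice_end(2), slice_code, xyzt_units
  wf(c(0, 0, 0))                            # cal_max, cal_min, slice_duration
  wf(0)                                     # toffset
  wi(c(0L, 0L), 4)                          # glmax, glmin
  writeBin(raw(80 + 24), con)               # descrip, aux_file
  wi(c(0L, 1L), 2)                          # qform_code=0, sform_code=1
  wf(rep(0, 6))                             # quaternions b,c,d + offsets
  wf(vol$affine[1, ]); wf(vol$affine[2, ]); wf(vol$affine[3, ])
  writeBin(raw(16), con)                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  writeBin(raw(4), con)                     # extension flag
  writeBin(as.numeric(vol$data), con, size = size, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 volume
#'
#' Supports float32/float64 single-file (.nii) images with an sform (or,
#' failing that, pixdim-scaled identity) affine. Sufficient for the
#' analytic fixtures this package trades in; not a general NIfTI reader.
#'
#' @param path `.nii` path.
#' @param tr repetition time override (seconds); default from pixdim[5].
#' @return a `volume_timeseries`.
#' @export
read_nifti <- function(path, tr = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path)
  ri <- function(off, size, n = 1, endian = "little")
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size, endian = endian)
  sz <- ri(0, 4)
  endian <- "little"
  if (sz != 348L) {
    endian <- "big"
    sz <- ri(0, 4, endian = "big")
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4, endian = endian)
  dim8 <- ri(40, 2, 8, endian)
  nd <- dim8[1]
  if (nd < 3 || nd > 4) stop("unsupported NIfTI dimensionality ", nd, ": ", path)
  d <- dim8[2:5]
  if (nd == 3) d[4] <- 1L
  dtype <- ri(70, 2, endian = endian)
  size <- switch(as.character(dtype), "16" = 4L, "64" = 8L,
                 stop("unsupported NIfTI datatype code ", dtype, " in ", path))
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  sform_code <- ri(254, 2, endian = endian)
  if (sform_code > 0) {
    affine <- rbind(rf(280, 4), rf(296, 4), rf(312, 4), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  seek(con, where = vox_offset, origin = "start")
  n <- prod(d)
  vals <- readBin(con, "numeric", n = n, size = size, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data block: ", path)
  volume_timeseries(array(vals, dim = d), affine,
                    tr = if (is.null(tr)) max(pixdim[5], .Machine$double.eps) else tr)
}

#' Trilinear sampling of a volume at continuous voxel coordinates
#'
#' @param data 4D array (nx, ny, nz, T).
#' @param ijk numeric N x 3 matrix of 0-based continuous voxel indices.
#' @return N x T matrix of interpolated values; rows outside the grid are NA.
#' @keywords internal
trilinear_sample <- function(data, ijk) {
  d <- dim(data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nt <- d[4]
  n <- nrow(ijk)
  inside <- ijk[, 1] >= 0 & ijk[, 1] <= nx - 1 &
            ijk[, 2] >= 0 & ijk[, 2] <= ny - 1 &
            ijk[, 3] >= 0 & ijk[, 3] <= nz - 1
  out <- matrix(NA_real_, n, nt)
  if (!any(inside)) return(out)
  p <- ijk[inside, , drop = FALSE]
  # clamp floor so that points exactly on the upper face use the last cell
  i0 <- pmin(floor(p[, 1]), nx - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(p[, 2]), ny - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(p[, 3]), nz - 2); k0 <- pmax(k0, 0)
  if (nx == 1) i0 <- rep(0, nrow(p))
  if (ny == 1) j0 <- rep(0, nrow(p))
  if (nz == 1) k0 <- rep(0, nrow(p))
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  dim(data) <- c(nx * ny * nz, nt)
  acc <- matrix(0, nrow(p), nt)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (nx > 1) abs(1 - dx - fx) else 1) *
         (if (ny > 1) abs(1 - dy - fy) else 1) *
         (if (nz > 1) abs(1 - dz - fz) else 1)
    idx <- (pmin(i0 + dx, nx - 1)) + nx * (pmin(j0 + dy, ny - 1)) +
      nx * ny * (pmin(k0 + dz, nz - 1)) + 1
    acc <- acc + w * data[idx, , drop = FALSE]
  }
  out[inside, ] <- acc
  out
}
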