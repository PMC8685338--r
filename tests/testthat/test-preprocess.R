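make_ts <- function(data, mesh = NULL, tr = 2) {
  v <- nrow(data)
  if (is.null(mesh)) {
    s <- ceiling(log((v - 2) / 10, 4))
    mesh <- icosphere(max(s, 0))
    stopifnot(n_vertices(mesh) == v)
  }
  surface_timeseries(data, mesh, tr)
}

test_that("midthickness is the vertexwise midpoint with preserved topology", {
  white <- icosphere(1, radius = 30)
  pial <- icosphere(1, radius = 34)
  mid <- midthickness(white, pial)
  expect_equal(sqrt(rowSums(mid$vertices^2)), rep(32, 42), tolerance = 1e-12)
  expect_identical(mid$triangles, white$triangles)
  expect_equal(midthickness(white, white)$vertices, white$vertices)
  perm <- white
  perm$triangles <- perm$triangles[, c(2, 1, 3)]
  expect_error(midthickness(white, perm), "topology")
})

test_that("vol_to_surf is exact on constant and affine fields", {
  aff <- rbind(c(2, 0, 0, -20), c(0, 2, 0, -20), c(0, 0, 2, -20), c(0, 0, 0, 1))
  surf <- icosphere(1, radius = 10)

  vc <- make_test_volume(c(25, 25, 25), aff, list(type = "constant", value = 7),
                         n_volumes = 3)
  pc <- vol_to_surf(vc, surf)
  expect_true(all(pc$mask$keep))
  expect_equal(max(abs(pc$ts$data - 7)), 0, tolerance = 1e-12)

  coef <- c(1, 0.5, -0.25, 2)
  vr <- make_test_volume(c(25, 25, 25), aff, list(type = "ramp", coef = coef),
                         n_volumes = 3)
  pr <- vol_to_surf(vr, surf)
  want <- as.numeric(coef[1] + surf$vertices %*% coef[2:4])
  expect_equal(max(abs(pr$ts$data - want)), 0, tolerance = 1e-10)
})

test_that("vol_to_surf at integer indices returns the exact voxel value", {
  set.seed(4)
  arr <- array(rnorm(5 * 5 * 5 * 2), c(5, 5, 5, 2))
  vol <- volume_timeseries(arr, diag(4), tr = 2)
  # 3 vertices at integer voxel coordinates under the identity affine
  surf <- triangle_mesh(rbind(c(1, 2, 3), c(2, 2, 2), c(0, 4, 1)),
                        rbind(c(1, 2, 3)))
  p <- vol_to_surf(vol, surf)
  expect_equal(p$ts$data[1, ], arr[2, 3, 4, ])
  expect_equal(p$ts$data[2, ], arr[3, 3, 3, ])
  expect_equal(p$ts$data[3, ], arr[1, 5, 2, ])
})

test_that("out-of-view vertices follow the stated policy", {
  vol <- make_test_volume(c(4, 4, 4), diag(4), list(type = "constant", value = 1),
                          n_volumes = 2)
  surf <- triangle_mesh(rbind(c(1, 1, 1), c(9, 9, 9), c(2, 1, 1)),
                        rbind(c(1, 2, 3)))
  expect_warning(p <- vol_to_surf(vol, surf), "outside")
  expect_identical(p$mask$keep, c(TRUE, FALSE, TRUE))
  expect_error(suppressWarnings(vol_to_surf(vol, surf, out_of_view = "fail")),
               "outside")
})

test_that("friston24 expands motion as [R, R^2, lag R, lag R^2]", {
  tlen <- 9L
  zero <- matrix(0, 6, tlen)
  expect_equal(friston24(zero), matrix(0, 24, tlen))
  expect_equal(nrow(friston24(matrix(rnorm(6 * tlen), 6))), 24L)
  ramp <- rbind(matrix(0, 5, tlen), t = seq_len(tlen))
  fr <- friston24(ramp)
  expect_equal(fr[6, ], as.numeric(seq_len(tlen)))
  expect_equal(fr[12, ], as.numeric(seq_len(tlen))^2)
  expect_equal(fr[18, ], c(0, seq_len(tlen - 1)))
  expect_equal(fr[24, ], c(0, seq_len(tlen - 1))^2)
  expect_error(friston24(matrix(0, 5, tlen)), "6 x T")
})

test_that("nuisance regression removes fitted signals and orthogonalizes", {
  mesh <- icosphere(0)
  tlen <- 50L
  set.seed(8)
  motion <- matrix(rnorm(6 * tlen, sd = 0.1), 6)
  wm <- rnorm(tlen); csf <- rnorm(tlen)
  nuis <- nuisance_set(motion, wm, csf)

  data <- matrix(rnorm(12 * tlen), 12)
  data[1, ] <- wm  # vertex identical to a regressor: residual ~ 0
  ts <- make_ts(data, mesh)
  res <- nuisance_regress(ts, nuis)
  expect_lt(sqrt(sum(res$data[1, ]^2)) / sqrt(sum(data[1, ]^2)), 1e-10)

  x <- cbind(1, t(friston24(motion)), wm, csf)
  orth <- abs(crossprod(x, t(res$data)))
  norms <- outer(sqrt(colSums(x^2)), sqrt(rowSums(res$data^2) + 1e-300))
  expect_lt(max(orth / norms), 1e-8)

  # all-zero nuisance collapses to intercept-only demeaning
  res0 <- nuisance_regress(ts, nuisance_set(matrix(0, 6, tlen),
                                            rep(0, tlen), rep(0, tlen)))
  expect_equal(res0$data, data - rowMeans(data), tolerance = 1e-12)

  # duplicated regressor is named in the rank-deficiency error
  expect_error(nuisance_regress(ts, nuisance_set(motion, wm, wm)),
               "rank deficient.*mean")
})

test_that("band-pass keeps in-band sinusoids and removes DC and out-of-band", {
  mesh <- icosphere(0)
  tlen <- 200L
  tt <- seq(0, by = 2, length.out = tlen)
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  data <- rbind(matrix(rep(inband, 4), 4, byrow = TRUE),
                matrix(rep(outband, 4), 4, byrow = TRUE),
                matrix(5, 4, tlen))
  ts <- make_ts(data, mesh)
  bp <- bandpass(ts, 0.01, 0.1)
  gain_in <- sd(bp$data[1, ]) / sd(inband)
  gain_out <- sd(bp$data[5, ]) / sd(outband)
  expect_gt(gain_in, 0.99); expect_lt(gain_in, 1.01)
  expect_lt(gain_out, 0.05)
  expect_equal(max(abs(bp$data[9, ])), 0, tolerance = 1e-10)  # constant -> 0

  # linearity
  x <- matrix(rnorm(12 * tlen), 12); y <- matrix(rnorm(12 * tlen), 12)
  bx <- bandpass(make_ts(x, mesh), 0.01, 0.1)$data
  by <- bandpass(make_ts(y, mesh), 0.01, 0.1)$data
  bxy <- bandpass(make_ts(2 * x - 3 * y, mesh), 0.01, 0.1)$data
  expect_equal(bxy, 2 * bx - 3 * by, tolerance = 1e-8)

  expect_error(bandpass(ts, 0.05, 0.3), "Nyquist")
  expect_error(bandpass(ts, 0.2, 0.1), "low")

  # butterworth dialect passes band centers and attenuates far out of band
  bw <- bandpass(ts, 0.01, 0.1, dialect = "butterworth")
  expect_gt(sd(bw$data[1, ]) / sd(inband), 0.9)
  expect_lt(sd(bw$data[5, ]) / sd(outband), 0.1)
})

test_that("drop_initial_volumes removes exactly the leading frames", {
  mesh <- icosphere(0)
  data <- matrix(seq_len(12 * 255), 12)
  ts <- make_ts(data, mesh)
  d10 <- drop_initial_volumes(ts, 10)
  expect_equal(ncol(d10$data), 245L)
  expect_equal(d10$data[, 1], data[, 11])
  expect_equal(drop_initial_volumes(ts, 0)$data, data)
  expect_error(drop_initial_volumes(ts, 255), "n_drop")

  vol <- make_test_volume(c(3, 3, 3), diag(4), list(type = "constant", value = 1),
                          n_volumes = 8)
  expect_equal(dim(drop_initial_volumes(vol, 3)$data)[4], 5L)
})

test_that("NIfTI volumes round-trip", {
  aff <- rbind(c(3, 0, 0, -10), c(0, 2, 0, -5), c(0, 0, 2, -8), c(0, 0, 0, 1))
  vol <- make_test_volume(c(6, 7, 8), aff, list(type = "ramp", coef = c(0, 1, 0, 0)),
                          n_volumes = 4)
  for (dt in c("float32", "float64")) {
    p <- withr::local_tempfile(fileext = ".nii")
    write_nifti(vol, p, datatype = dt)
    v2 <- read_nifti(p)
    tol <- if (dt == "float32") 1e-5 else 1e-12
    expect_equal(v2$data, vol$data, tolerance = tol)
    expect_equal(v2$affine, vol$affine, tolerance = 1e-6)
  }
})
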