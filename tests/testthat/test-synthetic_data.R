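test_that("cohort_config rejects infeasible worlds", {
  expect_error(cohort_config(n_sz = 1), "sample sizes")
  expect_error(cohort_config(n_volumes = 10), "20 volumes")
  expect_error(cohort_config(phi = 1), "phi")
  expect_error(cohort_config(rho0 = 0.9,
    clusters = list(list(seed = 1, ring = 2, delta_sz = 0.2, delta_hc = 0))),
    "outside")
  expect_error(cohort_config(covariate = list(variable = "duration",
                                              r_target = 0.99, cluster = 1)),
               "infeasible")
})

test_that("subject simulation is deterministic and respects the synchrony model", {
  mesh <- icosphere(1)
  cfg <- cohort_config(subdivisions = 1, n_volumes = 60,
                       clusters = list(), covariate = NULL)
  a <- simulate_subject_timeseries(mesh, cfg, seed = 99, rho_background = 0.5,
                                   rho_by_cluster = numeric(0), members = list())
  b <- simulate_subject_timeseries(mesh, cfg, seed = 99, rho_background = 0.5,
                                   rho_by_cluster = numeric(0), members = list())
  expect_identical(a$data, b$data)

  # rho = 1 everywhere: every vertex shares one series, downstream W = 1
  s1 <- simulate_subject_timeseries(mesh, cfg, seed = 7, rho_background = 1,
                                    rho_by_cluster = numeric(0), members = list())
  expect_equal(max(abs(sweep(s1$data, 2, s1$data[1, ]))), 0, tolerance = 1e-12)
  w <- reho_map(s1, mesh)
  expect_equal(unname(w$values), rep(1, 42))
})

test_that("independent noise gives mean W near 1/K (Monte-Carlo oracle)", {
  mesh <- icosphere(1)
  cfg <- cohort_config(subdivisions = 1, n_volumes = 120, phi = 0,
                       clusters = list(), covariate = NULL)
  adj <- mesh_adjacency(mesh)
  # on this small sphere two-rings wrap, so K varies by vertex: compare
  # the mean map against the per-vertex null expectation E[W] = 1/K
  k_v <- vapply(seq_len(n_vertices(mesh)), function(v)
    length(kring_neighbors(mesh, v, 2, adj = adj)) + 1L, 1L)
  ws <- matrix(NA_real_, 30, n_vertices(mesh))
  for (r in seq_len(30)) {
    s <- simulate_subject_timeseries(mesh, cfg, seed = 1000 + r,
                                     rho_background = 0, rho_by_cluster = numeric(0),
                                     members = list())
    ws[r, ] <- reho_map(s, mesh)$values
  }
  expect_lt(max(abs(colMeans(ws) - 1 / k_v)), 0.02)
  expect_lt(abs(mean(ws) - mean(1 / k_v)), 0.005)
})

test_that("generated series have lag-1 autocorrelation near phi", {
  mesh <- icosphere(0)
  for (phi in c(0.2, 0.5)) {
    cfg <- cohort_config(subdivisions = 0, n_volumes = 255, phi = phi,
                         clusters = list(), covariate = NULL)
    s <- simulate_subject_timeseries(mesh, cfg, seed = 3, rho_background = 0.3,
                                     rho_by_cluster = numeric(0), members = list())
    ac <- apply(s$data, 1, function(x) stats::acf(x, lag.max = 1, plot = FALSE)$acf[2])
    expect_lt(abs(mean(ac) - phi), 0.1)
  }
})

test_that("planted synchrony raises regional 2dReHo monotonically", {
  mesh <- icosphere(1)
  base <- cohort_config(subdivisions = 1, n_volumes = 100, rho0 = 0.2,
                        clusters = list(list(seed = 1, ring = 2,
                                             delta_sz = 0, delta_hc = 0)),
                        covariate = NULL)
  members <- planted_vertices(mesh, base)
  grid <- c(0, 0.15, 0.3, 0.45, 0.6, 0.75)
  means <- vapply(seq_along(grid), function(i) {
    vals <- vapply(1:8, function(r) {
      s <- simulate_subject_timeseries(mesh, base, seed = i * 100 + r,
                                       rho_background = 0.2,
                                       rho_by_cluster = 0.2 + grid[i],
                                       members = members)
      mean(reho_map(s, mesh)$values[members[[1]]])
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(means) > 0))
  expect_gt(suppressWarnings(cor(grid, means, method = "spearman")), 0.99)
})

test_that("cohort generation is reproducible and covariate-coupled", {
  cfg <- cohort_config(n_sz = 10, n_hc = 8, subdivisions = 1, n_volumes = 40)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$timeseries[[5]]$data, b$timeseries[[5]]$data)
  expect_equal(length(a$timeseries), 18L)
  expect_identical(unique(a$records$group), c("SZ", "HC"))
  # PANSS total is the sum of the subscales; duration non-negative; HC NA
  sz <- a$records[a$records$group == "SZ", ]
  expect_equal(sz$panss_total,
               sz$panss_positive + sz$panss_negative + sz$panss_general)
  expect_true(all(sz$duration >= 0))
  expect_true(all(is.na(a$records$duration[a$records$group == "HC"])))
})

test_that("analytic test volumes realize their fields", {
  aff <- rbind(c(2, 0, 0, -5), c(0, 2, 0, -5), c(0, 0, 2, -5), c(0, 0, 0, 1))
  vc <- make_test_volume(c(4, 4, 4), aff, list(type = "constant", value = 3.5),
                         n_volumes = 2)
  expect_true(all(vc$data == 3.5))
  # field f(x,y,z) = x reproduces the world x-coordinate at voxel centers
  vx <- make_test_volume(c(4, 4, 4), aff, list(type = "ramp", coef = c(0, 1, 0, 0)))
  expect_equal(vx$data[, 1, 1, 1], 2 * (0:3) - 5)
  expect_error(make_test_volume(c(4, 4, 4), matrix(0, 4, 4),
                                list(type = "constant", value = 1)), "invertible")
})

test_that("recruitment roster and QC filter reproduce the stated exclusions", {
  roster <- participant_roster(seed = 5)
  expect_equal(nrow(roster), 223L)
  expect_equal(sum(roster$group == "SZ"), 97L)
  kept <- qc_filter(roster)
  expect_equal(sum(kept$group == "SZ"), 93L)
  expect_equal(sum(kept$group == "HC"), 125L)
  tab <- table(kept$group, kept$sex)
  expect_equal(unname(tab["SZ", c("M", "F")]), c(65L, 28L))
  expect_equal(unname(tab["HC", c("M", "F")]), c(84L, 41L))
  # every excluded subject violates a stated criterion
  dropped <- roster[!roster$id %in% kept$id, ]
  expect_true(all(!dropped$acquisition_complete |
                  dropped$max_translation_mm > 2 |
                  dropped$max_rotation_deg > 2))
})
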