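test_that("two-sample t matches hand computation and stats::t.test", {
  same <- c(1, 2, 3, 4)
  r <- two_sample_t(same, same)
  expect_equal(r$t, 0); expect_equal(r$p, 1)

  r2 <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$t, -3 / sqrt(2 / 3))  # s_p = 1, se = sqrt(2/3): t = -3.674
  expect_equal(round(r2$t, 3), -3.674)
  expect_equal(r2$df, 4)

  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), mean = 0.5)
    for (v in c("pooled", "welch")) {
      mine <- two_sample_t(a, b, variance = v)
      ref <- stats::t.test(a, b, var.equal = (v == "pooled"))
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
      flipped <- two_sample_t(b, a, variance = v)
      expect_equal(flipped$t, -mine$t)
      expect_equal(flipped$p, mine$p)
    }
  }
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "variance")
})

test_that("BH step-up matches the exhaustive-threshold oracle", {
  expect_identical(bh_fdr(numeric(0), 0.05), logical(0))
  expect_false(any(bh_fdr(rep(1, 10), 0.05)))
  expect_true(bh_fdr(0.04, 0.05))
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  set.seed(9)
  for (i in 1:200) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    expect_identical(bh_fdr(p, q), oracle_bh(p, q))
  }
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

make_maps <- function(mat, mesh, keep = rep(TRUE, nrow(mat))) {
  lapply(seq_len(ncol(mat)), function(j)
    surface_map(mat[, j], mesh, cortex_mask(keep, mesh)))
}

test_that("vertex-wise group test matches per-vertex t tests and FDR rules", {
  mesh <- icosphere(1)
  v <- n_vertices(mesh)
  set.seed(12)
  xa <- matrix(rnorm(v * 6), v); xb <- matrix(rnorm(v * 7), v)
  xa[1:5, ] <- xa[1:5, ] + 3
  keep <- rep(TRUE, v); keep[40] <- FALSE
  res <- vertexwise_group_test(make_maps(xa, mesh, keep), make_maps(xb, mesh, keep))
  for (vv in c(1, 6, 20)) {
    ref <- two_sample_t(xa[vv, ], xb[vv, ])
    expect_equal(res$t_map$values[vv], ref$t, tolerance = 1e-12)
    expect_equal(res$p_map$values[vv], ref$p, tolerance = 1e-12)
  }
  expect_true(is.na(res$t_map$values[40]))
  expect_false(res$sig[40])
  expect_identical(res$sig[keep], bh_fdr(res$p_map$values[keep], 0.05))
  # q -> 1 rejects everything with p < 1; q -> 0 rejects nothing
  r1 <- vertexwise_group_test(make_maps(xa, mesh, keep), make_maps(xb, mesh, keep),
                              q = 0.999999)
  expect_true(all(r1$sig[keep] == (r1$p_map$values[keep] < 1)))
  r0 <- vertexwise_group_test(make_maps(xa, mesh, keep), make_maps(xb, mesh, keep),
                              q = 1e-12)
  expect_false(any(r0$sig))
  # mask mismatch is an error
  keep2 <- keep; keep2[41] <- FALSE
  expect_error(vertexwise_group_test(make_maps(xa, mesh, keep),
                                     make_maps(xb, mesh, keep2)), "mask")
})

test_that("signed clusters are maximal components with conserved area", {
  mesh <- icosphere(2)
  v <- n_vertices(mesh)
  areas <- vertex_areas(mesh)
  adj <- mesh_adjacency(mesh)
  # two well-separated planted patches of opposite sign
  pos <- c(1, kring_neighbors(mesh, 1, 2, adj = adj))
  far <- which.max(rowSums(sweep(mesh$vertices, 2, mesh$vertices[1, ])^2))
  neg <- c(far, kring_neighbors(mesh, far, 2, adj = adj))
  tvals <- rnorm(v, 0, 0.1)
  tvals[pos] <- 5; tvals[pos[1]] <- 6.5
  tvals[neg] <- -4.5; tvals[far] <- -7
  sig <- rep(FALSE, v); sig[c(pos, neg)] <- TRUE
  fake <- structure(list(t_map = surface_map(tvals, mesh), sig = sig),
                    class = "group_comparison")
  tab <- extract_clusters(fake, mesh, areas, index_base = 1L)
  expect_equal(nrow(tab), 2L)
  expect_identical(sort(tab$sign), c("+", "-")[order(c("+", "-"))])
  prow <- tab[tab$sign == "+", ]; nrow_ <- tab[tab$sign == "-", ]
  expect_equal(prow$peak_vertex, 1L)
  expect_equal(prow$peak_t, 6.5)
  expect_equal(nrow_$peak_vertex, far)
  expect_equal(nrow_$peak_t, -7)
  expect_setequal(prow$members[[1]], pos)
  expect_equal(sum(tab$area_mm2), sum(areas[c(pos, neg)]))
  expect_equal(sum(tab$n_vertices), length(pos) + length(neg))

  # empty significance mask -> empty table
  fake0 <- structure(list(t_map = surface_map(tvals, mesh),
                          sig = rep(FALSE, v)), class = "group_comparison")
  expect_equal(nrow(extract_clusters(fake0, mesh, areas)), 0L)
})

test_that("cluster extraction is invariant under vertex relabeling", {
  mesh <- icosphere(1)
  v <- n_vertices(mesh)
  set.seed(77)
  tvals <- rnorm(v)
  sig <- abs(tvals) > 0.8
  if (!any(sig)) sig[1:3] <- TRUE
  base <- structure(list(t_map = surface_map(tvals, mesh), sig = sig),
                    class = "group_comparison")
  tab <- extract_clusters(base, mesh, index_base = 1L)
  perm <- sample(v)                     # new label for each old vertex
  inv <- order(perm)
  mesh2 <- triangle_mesh(mesh$vertices[inv, ],
                         matrix(perm[mesh$triangles], ncol = 3),
                         hemisphere = mesh$hemisphere)
  t2 <- tvals[inv]; s2 <- sig[inv]
  tab2 <- extract_clusters(structure(list(t_map = surface_map(t2, mesh2),
                                          sig = s2),
                                     class = "group_comparison"),
                           mesh2, index_base = 1L)
  expect_equal(nrow(tab2), nrow(tab))
  # partitions agree after mapping new labels back to old
  back <- lapply(tab2$members, function(mm) sort(inv[mm]))
  orig <- lapply(tab$members, sort)
  expect_setequal(vapply(back, paste, "", collapse = ","),
                  vapply(orig, paste, "", collapse = ","))
  expect_equal(sort(perm[tab$peak_vertex]), sort(tab2$peak_vertex))
})

test_that("partial Spearman recovers monotone links and ignores covariate artifacts", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- x^3 + 2
  expect_equal(partial_spearman(x, y)$r, 1)

  set.seed(13)
  n <- 100
  z <- rnorm(n)
  x2 <- rnorm(n)
  y2 <- 2 * z + 0.5           # exactly a function of the covariate
  r2 <- partial_spearman(x2, y2, covariates = cbind(z))
  expect_true(!r2$ok || abs(r2$r) < 0.2)

  # constant residuals are flagged, not an error
  r3 <- partial_spearman(rep(1, 10), rnorm(10))
  expect_false(r3$ok); expect_true(is.na(r3$r))

  # with no covariates matches cor.test's estimate
  a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(partial_spearman(a, b)$r,
               unname(stats::cor.test(a, b, method = "spearman")$estimate),
               tolerance = 1e-12)
})

test_that("clinical correlation table covers the full family with FDR", {
  set.seed(14)
  n <- 40
  records <- data.frame(group = rep("SZ", n), age = rnorm(n, 40, 10),
                        sex = sample(c("M", "F"), n, TRUE),
                        duration = rgamma(n, 2, 0.2),
                        panss_total = rnorm(n, 60, 10),
                        flat = 1)
  rm_ <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("r1", "r2", "r3")))
  rm_[, 1] <- rank(records$duration) + rnorm(n, 0, 5)
  out <- correlate_clusters(rm_, records, c("duration", "panss_total"), q = 0.05)
  expect_equal(nrow(out), 6L)  # 3 regions x 2 variables
  top <- out[which.max(abs(out$r)), ]
  expect_identical(top$region, "r1")
  expect_identical(top$variable, "duration")
  # constant variable: flagged NA, never significant
  out2 <- correlate_clusters(rm_, records, "flat")
  expect_true(all(is.na(out2$r)))
  expect_false(any(out2$significant_fdr))
})

test_that("demographics table reproduces published-style group tests", {
  # post-exclusion sex counts 65M/28F vs 84M/41F give chi-square p ~ 0.67
  rec <- data.frame(
    group = rep(c("SZ", "HC"), c(93, 125)),
    sex = c(rep(c("M", "F"), c(65, 28)), rep(c("M", "F"), c(84, 41))),
    age = c(rnorm(93, 41, 11.5), rnorm(125, 38, 14.9)))
  tab <- demographics_table(rec, continuous = "age")
  sexrow <- tab[tab$variable == "sex", ]
  expect_equal(sexrow$p, 0.67, tolerance = 0.01)
  ref <- stats::chisq.test(table(rec$group, rec$sex), correct = FALSE)
  expect_equal(sexrow$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(sexrow$p, ref$p.value, tolerance = 1e-12)

  # chi-square equals the direct formula sum (O-E)^2 / E on any 2x2 table
  set.seed(15)
  for (i in 1:10) {
    m <- matrix(sample(5:60, 4), 2)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(chisq_2x2(m)$statistic, sum((m - e)^2 / e), tolerance = 1e-12)
  }

  # identical groups: t-test p = 1
  rec2 <- data.frame(group = rep(c("A", "B"), each = 4),
                     sex = rep("M", 8), age = rep(c(30, 40, 50, 60), 2))
  tab2 <- demographics_table(rec2, continuous = "age")
  expect_equal(tab2[tab2$variable == "age", "p"], 1)
})

test_that("global group test is two_sample_t on the global values", {
  set.seed(16)
  a <- runif(10, 0.2, 0.3); b <- runif(12, 0.25, 0.35)
  expect_identical(global_group_test(a, b), two_sample_t(a, b))
  same <- runif(5)
  expect_equal(global_group_test(same, same)$t, 0)
})
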