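# Group-level statistics: vertex-wise two-sample t tests with
# Benjamini-Hochberg FDR control, signed edge-connected cluster
# extraction, global-mean comparison, covariate-adjusted Spearman
# correlations with clinical variables, and a demographics table.
# Sign convention throughout: group A minus group B (patients minus
# controls), so negative t means lower in patients.

#' Two-sample t test
#'
#' Pooled-variance Student's t by default (the standard vertex-wise
#' neuroimaging GLM contrast); Welch's unequal-variance form as an option.
#' Two-sided p from the t distribution.
#'
#' @param a,b numeric samples (group A, group B).
#' @param variance `"pooled"` or `"welch"`.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(a, b, variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (variance == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    if (va <= 0 && vb <= 0) stop("zero variance in both groups")
    se2 <- va / na + vb / nb
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df)
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Rejects all hypotheses with p <= p_(k*), k* = max{k : p_(k) <= k q / m}.
#' Ties are handled by a stable sort (tied p-values share a fate).
#'
#' @param pvals numeric p-values in [0, 1].
#' @param q FDR level.
#' @return logical rejection flags, same length/order as `pvals`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  m <- length(pvals)
  if (m == 0L) return(logical(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be in [0, 1] with no NA")
  o <- order(pvals)
  ps <- pvals[o]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0L) return(rep(FALSE, m))
  pvals <= ps[max(ok)]
}

#' Vertex-wise two-sample comparison with FDR control
#'
#' Per-vertex two-sample t test (A minus B) on the masked-in vertices of
#' a stack of subject maps, with Benjamini-Hochberg correction applied
#' jointly over all masked-in vertices (both hemispheres together when
#' the maps cover both).
#'
#' @param maps_a,maps_b lists of `surface_map` (one per subject), all on
#'   the same mesh with identical masks.
#' @param q FDR level (default 0.05).
#' @param variance t-test variant, see [two_sample_t()].
#' @return object of class `group_comparison`: `t_map`, `p_map`
#'   (`surface_map`s), `sig` (logical vector, the FDR-significant
#'   vertices), `df`, `q`, `n_a`, `n_b`.
#' @export
vertexwise_group_test <- function(maps_a, maps_b, q = 0.05,
                                  variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    stop("need >= 2 subject maps per group")
  all_maps <- c(maps_a, maps_b)
  mesh <- all_maps[[1]]$mesh
  keep <- all_maps[[1]]$mask$keep
  for (m in all_maps) {
    if (length(m$values) != length(all_maps[[1]]$values)) stop("map lengths differ")
    if (!identical(m$mask$keep, keep))
      stop("cortex masks differ across subjects; intersect them first")
  }
  xa <- do.call(cbind, lapply(maps_a, function(m) m$values))
  xb <- do.call(cbind, lapply(maps_b, function(m) m$values))
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (variance == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(tt))
  } else {
    se2 <- va / na + vb / nb
    tt <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  pv <- 2 * stats::pt(-abs(tt), df)
  sig <- rep(FALSE, length(tt))
  sig[keep] <- bh_fdr(pv[keep], q)
  mask <- cortex_mask(keep, mesh)
  structure(list(t_map = surface_map(tt, mesh, mask),
                 p_map = surface_map(pv, mesh, mask),
                 sig = sig, df = df, q = q, n_a = na, n_b = nb),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: n = %d vs %d, q = %g, %d significant vertices\n",
              x$n_a, x$n_b, x$q, sum(x$sig)))
  invisible(x)
}

#' Signed cluster extraction
#'
#' Maximal edge-connected components of same-sign FDR-significant
#' vertices, reported with peak vertex (argmax |t|), peak t, cluster area
#' in mm^2 (sum of member vertex areas) and member count. The two size
#' measures are both reported because conventions differ on whether
#' "cluster size" means area or vertex count.
#'
#' @param result a `group_comparison`.
#' @param mesh the `triangle_mesh`.
#' @param areas vertex areas from [vertex_areas()] (computed if NULL).
#' @param index_base base for the reported peak vertex index (0 or 1).
#' @return data.frame of class `cluster_table` with columns `sign`
#'   ("+"/"-"), `peak_vertex`, `peak_t`, `area_mm2`, `n_vertices`,
#'   `members` (list column of 1-based member indices), ordered by
#'   decreasing |peak t|. Empty significance mask gives zero rows.
#' @export
extract_clusters <- function(result, mesh, areas = NULL, index_base = 0L) {
  stopifnot(index_base %in% c(0L, 1L))
  if (is.null(areas)) areas <- vertex_areas(mesh)
  tvals <- result$t_map$values
  empty <- data.frame(sign = character(0), peak_vertex = integer(0),
                      peak_t = numeric(0), area_mm2 = numeric(0),
                      n_vertices = integer(0))
  empty$members <- list()
  class(empty) <- c("cluster_table", "data.frame")
  sig <- which(result$sig)
  if (length(sig) == 0L) return(empty)
  adj <- mesh_adjacency(mesh)
  rows <- list()
  for (sgn in c(1, -1)) {
    verts <- sig[sign(tvals[sig]) == sgn]
    if (length(verts) == 0L) next
    inset <- logical(n_vertices(mesh))
    inset[verts] <- TRUE
    visited <- logical(n_vertices(mesh))
    for (s in verts) {
      if (visited[s]) next
      comp <- integer(0)
      frontier <- s
      visited[s] <- TRUE
      while (length(frontier)) {
        comp <- c(comp, frontier)
        nxt <- unique(unlist(adj[frontier], use.names = FALSE))
        nxt <- nxt[inset[nxt] & !visited[nxt]]
        visited[nxt] <- TRUE
        frontier <- nxt
      }
      comp <- sort(comp)
      peak <- comp[which.max(abs(tvals[comp]))]
      rows[[length(rows) + 1L]] <- list(
        sign = if (sgn > 0) "+" else "-",
        peak_vertex = peak - 1L + as.integer(index_base),
        peak_t = tvals[peak],
        area_mm2 = sum(areas[comp]),
        n_vertices = length(comp),
        members = list(comp))
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(sign = r$sign, peak_vertex = r$peak_vertex, peak_t = r$peak_t,
               area_mm2 = r$area_mm2, n_vertices = r$n_vertices)))
  tab$members <- lapply(rows, function(r) r$members[[1]])
  tab <- tab[order(-abs(tab$peak_t)), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("cluster_table", "data.frame")
  tab
}

#' Global-level group comparison
#'
#' Two-sample t test on per-subject global map means (see
#' [global_reho()]): the "global 2dReHo" contrast.
#'
#' @param global_a,global_b numeric vectors of per-subject global values.
#' @param variance see [two_sample_t()].
#' @return list with `t`, `p`, `df`.
#' @export
global_group_test <- function(global_a, global_b, variance = "pooled") {
  two_sample_t(global_a, global_b, variance = variance)
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Residualizes both variables on an intercept plus the covariates by
#' ordinary least squares, then Spearman-correlates the residual ranks.
#' Two-sided p via the t approximation with n - 2 - k degrees of freedom
#' (k = number of covariates).
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (e.g. age and sex); NULL for a plain Spearman correlation.
#' @return list with `r`, `p`, `n`, `ok` (FALSE when residuals are
#'   constant and r is undefined — flagged, not an error).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  cc <- stats::complete.cases(x, y, if (is.null(covariates)) rep(TRUE, length(x)) else covariates)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  k <- 0L
  if (!is.null(covariates)) {
    z <- as.matrix(as.data.frame(covariates))[cc, , drop = FALSE]
    storage.mode(z) <- "double"
    k <- ncol(z)
    if (n < k + 3L) stop("need n >= number of covariates + 3")
    qx <- qr(cbind(1, z))
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
  } else if (n < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, ok = FALSE))
  r <- stats::cor(rank(x), rank(y))
  df <- n - 2L - k
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df), n = n, ok = TRUE)
}

#' Region-by-variable clinical correlation table
#'
#' For each significant region (its per-subject mean map value) and each
#' clinical variable, the Spearman correlation after regressing out age
#' and sex, computed in patients only, with Benjamini-Hochberg adjustment
#' across the whole region x variable family. Both the raw and the
#' FDR-adjusted significance are reported.
#'
#' @param region_means numeric n_subject x n_region matrix of per-subject
#'   regional map means (column names = region ids).
#' @param records subject table with `group`, `age`, `sex` and the
#'   clinical variables.
#' @param variables character vector of clinical variable column names.
#' @param q FDR level for the family.
#' @param group_label which group to correlate in (default "SZ").
#' @return data.frame: region, variable, r, p, n, significant_raw
#'   (p < 0.05), significant_fdr.
#' @export
correlate_clusters <- function(region_means, records, variables, q = 0.05,
                               group_label = "SZ") {
  region_means <- as.matrix(region_means)
  if (nrow(region_means) != nrow(records))
    stop("region_means rows must match records rows")
  sel <- records$group == group_label
  if (sum(sel) < 5L) stop("too few subjects in group ", group_label)
  rm_ <- region_means[sel, , drop = FALSE]
  rec <- records[sel, , drop = FALSE]
  covs <- data.frame(age = rec$age,
                     sex = as.integer(factor(rec$sex)))
  regions <- colnames(rm_)
  if (is.null(regions)) regions <- paste0("region", seq_len(ncol(rm_)))
  grid <- expand.grid(region = regions, variable = variables,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    xv <- rm_[, match(grid$region[i], regions)]
    yv <- rec[[grid$variable[i]]]
    if (is.null(yv)) stop("variable not in records: ", grid$variable[i])
    if (length(unique(yv[!is.na(yv)])) < 2L)
      return(list(r = NA_real_, p = NA_real_, n = sum(!is.na(yv)), ok = FALSE))
    na_count <- sum(is.na(yv))
    if (na_count > 0)
      message(na_count, " missing '", grid$variable[i],
              "' values handled pairwise-complete")
    partial_spearman(xv, yv, covs)
  })
  out <- data.frame(grid,
                    r = vapply(res, `[[`, 0, "r"),
                    p = vapply(res, `[[`, 0, "p"),
                    n = vapply(res, function(z) as.numeric(z$n), 0))
  valid <- !is.na(out$p)
  out$significant_raw <- valid & out$p < 0.05
  out$significant_fdr <- FALSE
  if (any(valid)) out$significant_fdr[valid] <- bh_fdr(out$p[valid], q)
  out
}

#' Demographics table with group tests
#'
#' Per-group mean and SD for continuous variables with a two-sample
#' t-test p-value, and a 2x2 Pearson chi-square (no continuity
#' correction by default, the form that matches standard statistical
#' software output for case-control sex tables) for sex.
#'
#' @param records subject table with `group` (two levels) and `sex`.
#' @param continuous character vector of continuous variable names
#'   present in `records` (missing ones are skipped).
#' @param yates apply Yates continuity correction to the chi-square.
#' @return data.frame: variable, group levels' mean/sd (or counts for
#'   sex), test ("t" or "chisq"), statistic, p.
#' @export
demographics_table <- function(records, continuous = c("age", "education"),
                               yates = FALSE) {
  groups <- sort(unique(records$group))
  if (length(groups) != 2L) stop("records must contain exactly two groups")
  g1 <- records[records$group == groups[1], , drop = FALSE]
  g2 <- records[records$group == groups[2], , drop = FALSE]
  rows <- list()
  for (v in intersect(continuous, names(records))) {
    x1 <- g1[[v]]; x2 <- g2[[v]]
    enough <- sum(!is.na(x1)) >= 2 && sum(!is.na(x2)) >= 2
    tst <- if (enough) two_sample_t(x1, x2) else list(t = NA_real_, p = NA_real_)
    rows[[v]] <- data.frame(
      variable = v, test = "t",
      mean_1 = mean(x1, na.rm = TRUE), sd_1 = stats::sd(x1, na.rm = TRUE),
      mean_2 = mean(x2, na.rm = TRUE), sd_2 = stats::sd(x2, na.rm = TRUE),
      statistic = tst$t, p = tst$p)
  }
  if ("sex" %in% names(records) &&
      length(unique(records$sex[!is.na(records$sex)])) == 2L) {
    tab <- table(factor(records$group, levels = groups), records$sex)
    cs <- chisq_2x2(tab, yates = yates)
    rows[["sex"]] <- data.frame(
      variable = "sex", test = "chisq",
      mean_1 = tab[1, 1], sd_1 = tab[1, 2],
      mean_2 = tab[2, 1], sd_2 = tab[2, 2],
      statistic = cs$statistic, p = cs$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  out
}

#' Pearson chi-square test for a 2x2 table
#'
#' @param tab 2x2 contingency table/matrix of counts.
#' @param yates apply the continuity correction.
#' @return list with `statistic`, `p`, `df` (= 1).
#' @export
chisq_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Per-subject regional mean map values
#'
#' Helper mapping a list of subject maps and a set of regions (vertex
#' index vectors) to the n x R matrix consumed by
#' [correlate_clusters()].
#'
#' @param maps list of `surface_map`, one per subject.
#' @param regions named list of integer vertex-index vectors.
#' @return n x R numeric matrix with region names as columns.
#' @export
region_mean_matrix <- function(maps, regions) {
  if (is.null(names(regions)))
    names(regions) <- paste0("region", seq_along(regions))
  out <- vapply(regions, function(idx)
    vapply(maps, function(m) mean(m$values[idx], na.rm = TRUE), 0),
    numeric(length(maps)))
  out <- matrix(out, nrow = length(maps),
                dimnames = list(NULL, names(regions)))
  out
}
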