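# Synthetic cohorts with the statistical structure the analysis assumes:
# band-limited autocorrelated vertex time series with spatially structured
# local synchrony, planted group differences of both signs, and clinical
# covariates rank-coupled to regional synchrony. The generator is the
# package's test bed; its defaults emulate the target acquisition
# (TR = 2 s) and a schizophrenia-vs-control contrast with bidirectional
# regional effects.

derive_seed <- function(master, stage, i = 0L) {
  # deterministic fan-out of a master seed; stays below 2^31
  (as.numeric(master) * 7919 + stage * 104729 + i * 13) %% 2147483629
}

#' Cohort configuration
#'
#' The stated world of the generator. Per-vertex signals follow
#' `x_v(t) = sqrt(rho_v) s_region(t) + sqrt(1 - rho_v) eps_v(t)` with
#' independent AR(1) latent and noise processes (coefficient `phi`, unit
#' innovation variance): `rho_v` is the vertex's synchrony mixing weight,
#' mapping monotonically to the neighborhood concordance. Background
#' vertices share one latent per hemisphere-mesh at weight `rho0`;
#' vertices inside a planted cluster load on that cluster's own latent at
#' `rho0 + delta(group) + subject jitter`.
#'
#' @param n_sz,n_hc per-group sample sizes (>= 2).
#' @param subdivisions,radius icosphere mesh specification.
#' @param n_volumes number of acquired volumes T (>= 20).
#' @param tr repetition time, seconds.
#' @param phi temporal AR(1) coefficient in [0, 1).
#' @param rho0 baseline synchrony mixing weight in [0, 1].
#' @param clusters list of planted clusters, each a list with elements
#'   `seed` (vertex index), `ring` (neighborhood radius defining the
#'   member set), `delta_sz`, `delta_hc` (group synchrony offsets).
#' @param global_delta_sz,global_delta_hc group offsets applied to every
#'   vertex (models a global synchrony reduction).
#' @param subject_jitter_sd SD of the per-subject, per-cluster synchrony
#'   jitter (rho scale) that creates between-subject variance.
#' @param global_jitter_sd SD of the per-subject global synchrony jitter.
#' @param covariate list describing the clinical coupling: `variable`
#'   (one of "duration", "panss_positive", "panss_negative",
#'   "panss_general", "panss_total"), `r_target` (target Spearman
#'   correlation with the linked cluster's mean 2dReHo, |r| <= 0.95) and
#'   `cluster` (index into `clusters`); NULL for no coupling.
#' @param seed master seed; all randomness fans out from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_sz = 45L, n_hc = 45L,
                          subdivisions = 3L, radius = 50,
                          n_volumes = 150L, tr = 2,
                          phi = 0.3, rho0 = 0.3,
                          clusters = list(
                            list(seed = 1L, ring = 4L, delta_sz = 0.15, delta_hc = 0),
                            list(seed = 4L, ring = 4L, delta_sz = -0.15, delta_hc = 0)),
                          global_delta_sz = 0, global_delta_hc = 0,
                          subject_jitter_sd = 0.08, global_jitter_sd = 0.02,
                          covariate = list(variable = "duration",
                                           r_target = 0.5, cluster = 1L),
                          seed = 20210001L) {
  cfg <- list(n_sz = as.integer(n_sz), n_hc = as.integer(n_hc),
              subdivisions = as.integer(subdivisions), radius = radius,
              n_volumes = as.integer(n_volumes), tr = tr, phi = phi,
              rho0 = rho0, clusters = clusters,
              global_delta_sz = global_delta_sz,
              global_delta_hc = global_delta_hc,
              subject_jitter_sd = subject_jitter_sd,
              global_jitter_sd = global_jitter_sd,
              covariate = covariate, seed = as.integer(seed))
  if (cfg$n_sz < 2L || cfg$n_hc < 2L) stop("per-group sample sizes must be >= 2")
  if (cfg$n_volumes < 20L) stop("need at least 20 volumes")
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  if (rho0 < 0 || rho0 > 1) stop("rho0 must be in [0, 1]")
  for (cl in cfg$clusters) {
    for (d in c(cl$delta_sz, cl$delta_hc))
      if (rho0 + d < 0 || rho0 + d > 1)
        stop("rho0 + delta = ", rho0 + d, " outside [0, 1]")
  }
  if (!is.null(cfg$covariate)) {
    if (abs(cfg$covariate$r_target) > 0.95)
      stop("infeasible r_target (|r| > 0.95)")
    if (cfg$covariate$cluster > length(cfg$clusters))
      stop("covariate$cluster index out of range")
  }
  structure(cfg, class = "cohort_config")
}

ar1_series <- function(n, phi) {
  innov <- stats::rnorm(n)
  if (phi == 0) return(innov)
  x0 <- stats::rnorm(1, sd = 1 / sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
}

#' Planted cluster membership sets for a config
#'
#' @param mesh the cohort mesh.
#' @param config a `cohort_config`.
#' @return list of integer vertex-index vectors (seed + ring-k neighbors),
#'   one per planted cluster.
#' @export
planted_vertices <- function(mesh, config) {
  adj <- mesh_adjacency(mesh)
  lapply(config$clusters, function(cl)
    sort(c(cl$seed, kring_neighbors(mesh, cl$seed, cl$ring, adj = adj))))
}

#' Simulate one subject's surface time series
#'
#' Generates the mixing-weight model described in [cohort_config()]:
#' deterministic given `seed`. `rho_by_cluster` supplies the subject's
#' realized synchrony weight inside each planted cluster and
#' `rho_background` the weight elsewhere; [simulate_cohort()] derives
#' these from the config, but they can be passed directly for controlled
#' experiments (e.g. rho = 1 everywhere gives W = 1 downstream, rho = 0
#' with phi = 0 gives i.i.d. noise with E[W] = 1/K).
#'
#' @param mesh a `triangle_mesh`.
#' @param config a `cohort_config`.
#' @param seed integer RNG seed for this subject.
#' @param rho_background background mixing weight (default from config).
#' @param rho_by_cluster numeric vector, one weight per planted cluster
#'   (default rho0 + delta_sz, i.e. a patient with no jitter).
#' @param members precomputed [planted_vertices()] list (optional).
#' @return a `surface_timeseries`.
#' @export
simulate_subject_timeseries <- function(mesh, config, seed,
                                        rho_background = config$rho0,
                                        rho_by_cluster = vapply(config$clusters,
                                          function(cl) config$rho0 + cl$delta_sz, 0),
                                        members = planted_vertices(mesh, config)) {
  v <- n_vertices(mesh)
  tn <- config$n_volumes
  rho <- rep(rho_background, v)
  region <- rep(0L, v)  # 0 = background latent
  for (j in seq_along(members)) {
    rho[members[[j]]] <- rho_by_cluster[j]
    region[members[[j]]] <- j
  }
  if (any(rho < 0 | rho > 1))
    stop("realized rho outside [0, 1]; adjust rho0/delta/jitter")
  set.seed(as.integer(seed))
  latents <- vapply(0:length(members), function(j) ar1_series(tn, config$phi),
                    numeric(tn))
  noise <- matrix(stats::rnorm(v * tn), v, tn)
  if (config$phi > 0) {
    x0 <- stats::rnorm(v, sd = 1 / sqrt(1 - config$phi^2))
    # recursive AR(1) across columns, vectorized over vertices
    for (t in seq_len(tn))
      noise[, t] <- noise[, t] + config$phi * (if (t == 1) x0 else noise[, t - 1])
  }
  sig <- sqrt(rho) * t(latents)[region + 1L, , drop = FALSE] +
    sqrt(1 - rho) * noise
  surface_timeseries(sig, mesh, config$tr)
}

gaussian_copula_pair <- function(z, r_spearman) {
  # second coordinate of a bivariate normal whose Spearman correlation
  # with z is r_spearman (Pearson r = 2 sin(pi r_s / 6))
  r <- 2 * sin(pi * r_spearman / 6)
  r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
}

qgamma_match <- function(p, mean, sd) {
  shape <- (mean / sd)^2
  stats::qgamma(p, shape = shape, rate = shape / mean)
}

#' Simulate a full cohort
#'
#' Draws per-subject synchrony weights (group offset + jitter, clamped to
#' [0.02, 0.98]), generates every subject's surface time series, and
#' builds the subject table. PANSS subscales are drawn around published
#' schizophrenia means (positive 13.3 +/- 5.9, negative 20.7 +/- 6.1,
#' general 28.2 +/- 5.9; total = their sum); illness duration follows a
#' gamma with mean 16.3 y, SD 10.9 y. When a covariate coupling is
#' configured, the named variable is generated by a Gaussian copula on
#' the linked cluster's subject jitter so that its Spearman correlation
#' with the realized regional 2dReHo approximates `r_target` (patients
#' only; controls carry NA for clinical fields).
#'
#' @param config a `cohort_config`.
#' @param mesh optional mesh (built from the config's icosphere spec by
#'   default).
#' @return list with `timeseries` (list of `surface_timeseries`),
#'   `records` (data.frame: id, group, age, sex, duration,
#'   panss_positive/negative/general/total), `mesh`, `planted` (cluster
#'   vertex sets), and `rho` (n x n_clusters matrix of realized weights).
#' @export
simulate_cohort <- function(config, mesh = icosphere(config$subdivisions, config$radius)) {
  n <- config$n_sz + config$n_hc
  group <- rep(c("SZ", "HC"), c(config$n_sz, config$n_hc))
  members <- planted_vertices(mesh, config)
  ncl <- length(config$clusters)

  set.seed(derive_seed(config$seed, stage = 1L))
  zmat <- matrix(stats::rnorm(n * max(ncl, 1L)), n, max(ncl, 1L))
  zglob <- stats::rnorm(n)
  rho <- matrix(config$rho0, n, max(ncl, 1L))
  gdelta <- ifelse(group == "SZ", config$global_delta_sz, config$global_delta_hc)
  gjit <- gdelta + config$global_jitter_sd * zglob
  for (j in seq_len(ncl)) {
    d <- ifelse(group == "SZ", config$clusters[[j]]$delta_sz,
                config$clusters[[j]]$delta_hc)
    rho[, j] <- config$rho0 + d + config$subject_jitter_sd * zmat[, j] + gjit
  }
  rho_bg <- config$rho0 + gjit
  rho <- pmin(pmax(rho, 0.02), 0.98)
  rho_bg <- pmin(pmax(rho_bg, 0.02), 0.98)

  # demographics: age/sex mirror a typical adult case-control cohort
  age <- round(ifelse(group == "SZ", stats::rnorm(n, 41, 11.5), stats::rnorm(n, 38, 14.9)))
  age <- pmin(pmax(age, 18), 70)
  sex <- ifelse(stats::runif(n) < ifelse(group == "SZ", 0.70, 0.67), "M", "F")

  duration <- rep(NA_real_, n)
  pp <- pn <- pg <- rep(NA_real_, n)
  is_sz <- group == "SZ"
  nsz <- sum(is_sz)
  pp[is_sz] <- pmax(round(stats::rnorm(nsz, 13.32, 5.89)), 7)
  pn[is_sz] <- pmax(round(stats::rnorm(nsz, 20.70, 6.06)), 7)
  pg[is_sz] <- pmax(round(stats::rnorm(nsz, 28.19, 5.86)), 16)
  duration[is_sz] <- qgamma_match(stats::runif(nsz), 16.3, 10.9)

  cov <- config$covariate
  if (!is.null(cov) && ncl > 0) {
    zc <- gaussian_copula_pair(zmat[is_sz, cov$cluster], cov$r_target)
    u <- stats::pnorm(zc)
    val <- switch(cov$variable,
      duration = qgamma_match(u, 16.3, 10.9),
      panss_positive = 7 + stats::qgamma(u, shape = 2, rate = 2 / 6.3),
      panss_negative = 7 + stats::qgamma(u, shape = 4, rate = 4 / 13.7),
      panss_general = 16 + stats::qgamma(u, shape = 4, rate = 4 / 12.2),
      panss_total = 30 + stats::qgamma(u, shape = 6, rate = 6 / 32.2),
      stop("unknown covariate variable: ", cov$variable))
    switch(cov$variable,
      duration = { duration[is_sz] <- val },
      panss_positive = { pp[is_sz] <- val },
      panss_negative = { pn[is_sz] <- val },
      panss_general = { pg[is_sz] <- val },
      panss_total = NULL)
    if (cov$variable == "panss_total") {
      # rescale subscales to match the coupled total
      tot0 <- pp[is_sz] + pn[is_sz] + pg[is_sz]
      f <- val / tot0
      pp[is_sz] <- pp[is_sz] * f; pn[is_sz] <- pn[is_sz] * f; pg[is_sz] <- pg[is_sz] * f
    }
  }
  records <- data.frame(
    id = sprintf("sub-%03d", seq_len(n)),
    group = group, age = age, sex = sex,
    duration = duration,
    panss_positive = pp, panss_negative = pn, panss_general = pg,
    panss_total = pp + pn + pg,
    stringsAsFactors = FALSE)

  ts <- vector("list", n)
  for (i in seq_len(n)) {
    ts[[i]] <- simulate_subject_timeseries(
      mesh, config, seed = derive_seed(config$seed, stage = 2L, i = i),
      rho_background = rho_bg[i],
      rho_by_cluster = rho[i, seq_len(max(ncl, 1L))],
      members = members)
  }
  list(timeseries = ts, records = records, mesh = mesh,
       planted = members, rho = rho)
}

#' Analytic volumetric test fixture
#'
#' Builds a volume whose intensity follows a named analytic field of the
#' world coordinate at every timepoint: `constant` (value c) or `ramp`
#' (a0 + ax x + ay y + az z, world mm). Because trilinear interpolation is
#' exact for affine functions, the ramp fixture makes volume-to-surface
#' sampling testable to machine precision.
#'
#' @param shape integer length-3 voxel grid extent.
#' @param affine 4x4 voxel(0-based)-to-world matrix.
#' @param field list: `type = "constant"` with `value`, or `type = "ramp"`
#'   with `coef = c(a0, ax, ay, az)`.
#' @param n_volumes number of timepoints.
#' @param tr repetition time (s).
#' @return a `volume_timeseries`.
#' @export
make_test_volume <- function(shape, affine, field, n_volumes = 1L, tr = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  affine <- as.matrix(affine)
  if (abs(det(affine)) < .Machine$double.eps * 100) stop("affine must be invertible")
  g <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                             k = 0:(shape[3] - 1)))
  world <- cbind(g, 1) %*% t(affine)
  vals <- switch(field$type,
    constant = rep(field$value, nrow(g)),
    ramp = field$coef[1] + world[, 1:3, drop = FALSE] %*% field$coef[2:4],
    stop("field$type must be 'constant' or 'ramp'"))
  arr <- array(rep(as.numeric(vals), n_volumes),
               dim = c(shape, n_volumes))
  volume_timeseries(arr, affine, tr = tr)
}

# ---- recruitment roster and quality control ---------------------------------

#' Synthetic recruitment roster
#'
#' Builds the recruited (pre-exclusion) roster of a case-control study:
#' 97 patients (29 women) and 126 controls (42 women) by default, with
#' per-subject acquisition-completeness flags and maximum head-motion
#' summaries. Exactly 4 patients (3 men, 1 woman) and 1 control (a woman)
#' carry a disqualifying record — incomplete acquisition or motion beyond
#' 2 mm / 2 degrees — so that quality control retains 93 patients and 125
#' controls with post-exclusion sex counts 65M/28F vs 84M/41F.
#'
#' @param n_sz,n_sz_female,n_hc,n_hc_female recruitment counts.
#' @param seed RNG seed.
#' @return data.frame with id, group, sex, acquisition_complete,
#'   max_translation_mm, max_rotation_deg.
#' @export
participant_roster <- function(n_sz = 97L, n_sz_female = 29L,
                               n_hc = 126L, n_hc_female = 42L, seed = 1L) {
  set.seed(derive_seed(seed, stage = 7L))
  n <- n_sz + n_hc
  group <- rep(c("SZ", "HC"), c(n_sz, n_hc))
  sex <- c(rep(c("F", "M"), c(n_sz_female, n_sz - n_sz_female)),
           rep(c("F", "M"), c(n_hc_female, n_hc - n_hc_female)))
  # clean motion: sub-threshold by construction
  trans <- stats::runif(n, 0.05, 1.8)
  rot <- stats::runif(n, 0.05, 1.8)
  complete <- rep(TRUE, n)
  fail_sz <- c(which(group == "SZ" & sex == "M")[1:3],
               which(group == "SZ" & sex == "F")[1])
  fail_hc <- which(group == "HC" & sex == "F")[1]
  trans[fail_sz[1]] <- 3.1           # gross motion
  rot[fail_sz[2]] <- 2.7
  complete[fail_sz[3]] <- FALSE      # incomplete acquisition
  trans[fail_sz[4]] <- 2.4
  complete[fail_hc] <- FALSE
  ord <- sample.int(n)
  data.frame(id = sprintf("rec-%03d", seq_len(n)),
             group = group[ord], sex = sex[ord],
             acquisition_complete = complete[ord],
             max_translation_mm = round(trans[ord], 2),
             max_rotation_deg = round(rot[ord], 2),
             stringsAsFactors = FALSE)
}

#' Quality-control filter
#'
#' Retains subjects with complete T1 + resting-state acquisitions and
#' maximum head motion within the stated limits (2 mm translation,
#' 2 degrees rotation by default).
#'
#' @param roster data.frame from [participant_roster()] (or any table with
#'   the same QC columns).
#' @param max_translation_mm,max_rotation_deg exclusion thresholds.
#' @return the retained subset of `roster`.
#' @export
qc_filter <- function(roster, max_translation_mm = 2, max_rotation_deg = 2) {
  need <- c("acquisition_complete", "max_translation_mm", "max_rotation_deg")
  if (!all(need %in% names(roster)))
    stop("roster lacks QC columns: ", paste(setdiff(need, names(roster)), collapse = ", "))
  keep <- roster$acquisition_complete &
    roster$max_translation_mm <= max_translation_mm &
    roster$max_rotation_deg <= max_rotation_deg
  roster[keep, , drop = FALSE]
}
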