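#' Simulation configuration for synthetic paired cohorts
#'
#' Collects the parameters of the synthetic aqueous-humor cohort generator.
#' Defaults emulate a paired anti-VEGF discovery cohort of 13 simpleVH and
#' 12 VH_TRD patients, each sampled at baseline and 7 days post-treatment,
#' profiled on a 1432-protein and a 1542-metabolite layer, plus an
#' independent validation cohort of 10 controls and 5 + 5 PDR patients.
#'
#' Abundances are log-normal: log2 intensities are Normal per feature, with
#' per-feature baseline means drawn uniformly over
#' `baseline_log2_mean_range`, an additive per-patient-per-feature random
#' intercept (`patient_sd`, the between-subject biological component that
#' gives paired tests their power), and technical noise whose log2 SD is
#' chosen so the linear-scale coefficient of variation equals `tech_cv`.
#' Planted features carry a signed group effect (`effect_log2_cross`, added
#' to every VH_TRD sample), a signed treatment effect (`effect_log2_long`,
#' added to every post-treatment sample), or both: `improvement` features
#' have opposite-signed cross and longitudinal effects (treatment reverses
#' the severe-phenotype deviation), `aggravation` features have same-signed
#' effects (treatment pushes further in the pathological direction).
#'
#' Missingness combines an intensity-dependent (MNAR) logistic mechanism —
#' a cell of log2 abundance `v` is masked with probability
#' `plogis((mnar_midpoint - v) * mnar_slope)` — with uniform MCAR dropout at
#' rate `mcar_rate`; the two mechanisms act as independent events.
#'
#' @param n_groupA Number of simpleVH patients (paired baseline/post).
#' @param n_groupB Number of VH_TRD patients (paired baseline/post).
#' @param n_controls Number of control patients in the validation cohort
#'   (one sample each).
#' @param n_validationA,n_validationB simpleVH / VH_TRD patients in the
#'   validation cohort (paired).
#' @param n_features Named count vector, features per layer.
#' @param baseline_log2_mean_range Interval for per-feature baseline log2
#'   means.
#' @param tech_cv Technical coefficient of variation on the linear scale.
#' @param patient_sd SD of the per-patient-per-feature log2 intercept.
#' @param effect_log2_cross,effect_log2_long,effect_log2_disease Magnitudes
#'   (log2) of the planted group, treatment and PDR-vs-control effects.
#' @param n_cross_only,n_long_only,n_improvement,n_aggravation Named count
#'   vectors per layer: how many features carry each planted label.
#' @param mnar_midpoint log2 abundance at which MNAR masking probability is
#'   50\%.
#' @param mnar_slope Slope of the MNAR logistic link (0 disables the
#'   intensity dependence at a constant 0.5 only at the midpoint).
#' @param mcar_rate Probability of masking completely at random.
#' @param seed Integer seed; one seed governs all draws.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_groupA = 13, n_groupB = 12,
                       n_controls = 10, n_validationA = 5, n_validationB = 5,
                       n_features = c(protein = 1432, metabolite = 1542),
                       baseline_log2_mean_range = c(14, 24),
                       tech_cv = 0.2, patient_sd = 0.3,
                       effect_log2_cross = 1, effect_log2_long = 1,
                       effect_log2_disease = 1,
                       n_cross_only = c(protein = 66, metabolite = 81),
                       n_long_only = c(protein = 49, metabolite = 187),
                       n_improvement = c(protein = 3, metabolite = 32),
                       n_aggravation = c(protein = 2, metabolite = 1),
                       mnar_midpoint = 12, mnar_slope = 0.8,
                       mcar_rate = 0.05, seed = 1L) {
  cfg <- list(n_groupA = n_groupA, n_groupB = n_groupB,
              n_controls = n_controls,
              n_validationA = n_validationA, n_validationB = n_validationB,
              n_features = n_features,
              baseline_log2_mean_range = baseline_log2_mean_range,
              tech_cv = tech_cv, patient_sd = patient_sd,
              effect_log2_cross = effect_log2_cross,
              effect_log2_long = effect_log2_long,
              effect_log2_disease = effect_log2_disease,
              n_cross_only = n_cross_only, n_long_only = n_long_only,
              n_improvement = n_improvement, n_aggravation = n_aggravation,
              mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
              mcar_rate = mcar_rate, seed = as.integer(seed))
  counts <- c(n_groupA, n_groupB, n_controls, n_validationA, n_validationB,
              n_features, n_cross_only, n_long_only, n_improvement,
              n_aggravation)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (tech_cv <= 0) stop("tech_cv must be > 0")
  if (mcar_rate < 0 || mcar_rate >= 1) stop("mcar_rate must be in [0, 1)")
  for (ly in names(n_features)) {
    planted <- .planted_count(cfg, ly)
    if (planted > n_features[[ly]])
      stop(sprintf("planted feature counts (%d) exceed layer size (%d) for '%s'",
                   planted, n_features[[ly]], ly))
  }
  class(cfg) <- "sim_config"
  cfg
}

.planted_count <- function(config, layer) {
  sum(config$n_cross_only[[layer]], config$n_long_only[[layer]],
      config$n_improvement[[layer]], config$n_aggravation[[layer]])
}

# log2 SD giving a linear-scale CV of cv for a log-normal variable
.log2_sd_for_cv <- function(cv) sqrt(log(1 + cv^2)) / log(2)

.draw_covariates <- function(group, n) {
  # clinical covariates loosely matched to a PDR surgical cohort
  pars <- switch(group,
    simpleVH = list(age = c(54.7, 6.8), dur = c(9.1, 4.2), hba1c = c(8.6, 2.0)),
    VH_TRD   = list(age = c(51.9, 7.0), dur = c(6.8, 5.8), hba1c = c(7.8, 1.9)),
    control  = list(age = c(51.1, 5.3), dur = c(0, 0),     hba1c = c(5.4, 0.3)))
  data.frame(
    age = round(stats::rnorm(n, pars$age[1], pars$age[2]), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    diabetes_duration = pmax(0, round(stats::rnorm(n, pars$dur[1], pars$dur[2]), 1)),
    hba1c = round(pmax(4.5, stats::rnorm(n, pars$hba1c[1], pars$hba1c[2])), 1))
}

# Assign planted labels and signed effects to a layer.
.plant_layer <- function(config, layer) {
  p <- config$n_features[[layer]]
  ids <- sprintf("%s_%04d", layer, seq_len(p))
  lab <- rep("null", p)
  n_co <- config$n_cross_only[[layer]]
  n_lo <- config$n_long_only[[layer]]
  n_im <- config$n_improvement[[layer]]
  n_ag <- config$n_aggravation[[layer]]
  pick <- sample.int(p, n_co + n_lo + n_im + n_ag)
  lab[pick] <- rep(c("cross_only", "long_only", "improvement", "aggravation"),
                   times = c(n_co, n_lo, n_im, n_ag))
  sign_cross <- sample(c(-1, 1), p, replace = TRUE)
  sign_long <- sample(c(-1, 1), p, replace = TRUE)
  eff_cross <- ifelse(lab %in% c("cross_only", "improvement", "aggravation"),
                      sign_cross * config$effect_log2_cross, 0)
  eff_long <- numeric(p)
  eff_long[lab == "long_only"] <- (sign_long * config$effect_log2_long)[lab == "long_only"]
  im <- lab == "improvement"; ag <- lab == "aggravation"
  eff_long[im] <- -sign_cross[im] * config$effect_log2_long
  eff_long[ag] <- sign_cross[ag] * config$effect_log2_long
  data.frame(feature_id = ids, layer = layer, label = lab,
             effect_log2_cross = eff_cross, effect_log2_long = eff_long,
             stringsAsFactors = FALSE)
}

# Simulate the complete (pre-missingness) log2 matrix for one layer.
.simulate_layer <- function(config, truth, design, disease_effect = FALSE) {
  p <- nrow(truth)
  n <- nrow(design)
  mu <- stats::runif(p, config$baseline_log2_mean_range[1],
                     config$baseline_log2_mean_range[2])
  sd2 <- .log2_sd_for_cv(config$tech_cv)
  patients <- unique(design$patient_id)
  pat_eff <- matrix(stats::rnorm(p * length(patients), 0, config$patient_sd),
                    nrow = p, dimnames = list(NULL, patients))
  log2x <- matrix(mu, nrow = p, ncol = n) +
    pat_eff[, design$patient_id, drop = FALSE] +
    matrix(stats::rnorm(p * n, 0, sd2), nrow = p)
  is_b <- design$group == "VH_TRD"
  is_post <- design$timepoint == "post"
  is_pdr <- design$group != "control"
  log2x[, is_b] <- log2x[, is_b] + truth$effect_log2_cross
  log2x[, is_post] <- log2x[, is_post] + truth$effect_log2_long
  if (disease_effect) {
    planted <- truth$label != "null"
    log2x[planted, is_pdr] <- log2x[planted, is_pdr] + config$effect_log2_disease
  }
  dimnames(log2x) <- list(truth$feature_id, design$sample_id)
  2^log2x
}

#' Generate a synthetic paired discovery cohort with known ground truth
#'
#' Simulates the two-layer discovery cohort: every patient contributes a
#' baseline and a post-treatment sample, VH_TRD samples carry the planted
#' cross-sectional effects, post samples the planted longitudinal effects,
#' and MNAR + MCAR missingness is applied per layer. Fully reproducible
#' from `config$seed`; draw order is fixed (design covariates, then per
#' layer in the order of `config$n_features`: planting, baseline means,
#' patient effects, noise, missingness).
#'
#' @param config A [sim_config()].
#' @return A list with elements `tables` (named list of [feature_table()]
#'   per layer, with missingness applied), `design` (a [study_design()])
#'   and `truth` (data frame: `feature_id`, `layer`, `label`,
#'   `effect_log2_cross`, `effect_log2_long`).
#' @export
generate_discovery_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nA <- config$n_groupA; nB <- config$n_groupB
  pat <- sprintf("P%02d", seq_len(nA + nB))
  grp <- rep(c("simpleVH", "VH_TRD"), c(nA, nB))
  covA <- .draw_covariates("simpleVH", nA)
  covB <- .draw_covariates("VH_TRD", nB)
  cov <- rbind(covA, covB)
  design <- data.frame(
    sample_id = paste0(rep(pat, each = 2), c("_baseline", "_post")),
    patient_id = rep(pat, each = 2),
    group = rep(grp, each = 2),
    timepoint = rep(c("baseline", "post"), nA + nB),
    cov[rep(seq_len(nA + nB), each = 2), ],
    row.names = NULL, stringsAsFactors = FALSE)
  design <- study_design(design)

  tables <- list(); truths <- list()
  for (ly in names(config$n_features)) {
    truth <- .plant_layer(config, ly)
    raw <- .simulate_layer(config, truth, design)
    tab <- feature_table(raw, layer = ly, scale_state = "raw")
    tab <- apply_missingness(tab, config)
    tables[[ly]] <- tab
    truths[[ly]] <- truth
  }
  list(tables = tables, design = design, truth = do.call(rbind, truths))
}

#' Generate a synthetic three-group validation cohort
#'
#' Simulates the validation design: `n_controls` control patients (one
#' sample each) plus paired baseline/post samples for `n_validationA`
#' simpleVH and `n_validationB` VH_TRD patients, for one layer. Controls
#' carry no planted disease effects; planted features additionally receive
#' a PDR-vs-control elevation of `effect_log2_disease` so biphasic patterns
#' (elevated in disease vs control, yet depleted in the severe phenotype)
#' are representable.
#'
#' @param config A [sim_config()] with `n_controls > 0`.
#' @param layer Which layer to simulate.
#' @return As [generate_discovery_cohort()], with a single `table` element.
#' @export
generate_validation_cohort <- function(config, layer = "protein") {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_controls <= 0) stop("n_controls must be > 0")
  set.seed(config$seed + 1L)
  nC <- config$n_controls; nA <- config$n_validationA; nB <- config$n_validationB
  ctrl <- sprintf("VC%02d", seq_len(nC))
  pdr <- sprintf("VP%02d", seq_len(nA + nB))
  grp_pdr <- rep(c("simpleVH", "VH_TRD"), c(nA, nB))
  cov <- rbind(.draw_covariates("control", nC),
               .draw_covariates("simpleVH", nA),
               .draw_covariates("VH_TRD", nB))
  design <- data.frame(
    sample_id = c(paste0(ctrl, "_baseline"),
                  paste0(rep(pdr, each = 2), c("_baseline", "_post"))),
    patient_id = c(ctrl, rep(pdr, each = 2)),
    group = c(rep("control", nC), rep(grp_pdr, each = 2)),
    timepoint = c(rep("baseline", nC),
                  rep(c("baseline", "post"), nA + nB)),
    cov[c(seq_len(nC), nC + rep(seq_len(nA + nB), each = 2)), ],
    row.names = NULL, stringsAsFactors = FALSE)
  design <- study_design(design)

  truth <- .plant_layer(config, layer)
  raw <- .simulate_layer(config, truth, design, disease_effect = TRUE)
  tab <- feature_table(raw, layer = layer, scale_state = "raw")
  tab <- apply_missingness(tab, config)
  list(table = tab, design = design, truth = truth)
}

#' Apply intensity-dependent and random missingness to a complete table
#'
#' Each observed cell of log2 abundance `v` is masked with probability
#' `1 - (1 - plogis((mnar_midpoint - v) * mnar_slope)) * (1 - mcar_rate)`,
#' i.e. the union of an independent MNAR event (logistic in log2 abundance,
#' 50\% at the midpoint) and an MCAR event.
#'
#' @param table A raw-scale [feature_table()].
#' @param config A [sim_config()] supplying `mnar_midpoint`, `mnar_slope`,
#'   `mcar_rate`.
#' @param seed Optional seed; by default masking consumes the current RNG
#'   stream (as used inside the cohort generators).
#' @return The table with masked cells set to `NA`.
#' @export
apply_missingness <- function(table, config, seed = NULL) {
  stopifnot(inherits(table, "FeatureTable"))
  if (!is.null(seed)) set.seed(seed)
  v <- table$values
  p_mnar <- stats::plogis((config$mnar_midpoint - log2(v)) * config$mnar_slope)
  p_miss <- 1 - (1 - p_mnar) * (1 - config$mcar_rate)
  mask <- matrix(stats::runif(length(v)) < p_miss, nrow = nrow(v))
  v[mask] <- NA_real_
  table$values <- v
  table
}
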