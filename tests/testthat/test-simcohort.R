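test_that("cohort generation is reproducible and bookkeeps planted labels", {
  cfg <- sim_config(n_features = c(protein = 60, metabolite = 80),
                    n_cross_only = c(protein = 5, metabolite = 6),
                    n_long_only = c(protein = 4, metabolite = 7),
                    n_improvement = c(protein = 3, metabolite = 8),
                    n_aggravation = c(protein = 2, metabolite = 1),
                    seed = 7)
  a <- generate_discovery_cohort(cfg)
  b <- generate_discovery_cohort(cfg)
  expect_identical(a$tables$protein$values, b$tables$protein$values)
  expect_identical(a$tables$metabolite$values, b$tables$metabolite$values)
  expect_identical(a$truth, b$truth)
  expect_identical(a$design, b$design)

  counts <- table(a$truth$label, a$truth$layer)
  expect_equal(counts["improvement", "protein"], 3)
  expect_equal(counts["improvement", "metabolite"], 8)
  expect_equal(counts["aggravation", "protein"], 2)
  expect_equal(counts["aggravation", "metabolite"], 1)
  expect_equal(counts["cross_only", "protein"], 5)
  expect_equal(counts["long_only", "metabolite"], 7)

  # design arithmetic: every patient paired baseline/post
  expect_equal(nrow(a$design), 2 * (13 + 12))
  expect_equal(sum(a$design$group == "VH_TRD"), 24)
  expect_true(all(table(a$design$patient_id) == 2))

  # improvement features have opposite-signed effects, aggravation same-signed
  tr <- a$truth
  im <- tr[tr$label == "improvement", ]
  ag <- tr[tr$label == "aggravation", ]
  expect_true(all(sign(im$effect_log2_cross) == -sign(im$effect_log2_long)))
  expect_true(all(sign(ag$effect_log2_cross) == sign(ag$effect_log2_long)))
})

test_that("planted counts exceeding the layer size are rejected", {
  expect_error(sim_config(n_features = c(protein = 10),
                          n_cross_only = c(protein = 6),
                          n_long_only = c(protein = 6),
                          n_improvement = c(protein = 0),
                          n_aggravation = c(protein = 0)),
               "exceed")
  expect_error(sim_config(tech_cv = 0), "tech_cv")
  expect_error(sim_config(mcar_rate = 1), "mcar_rate")
})

test_that("technical CV of generated abundances matches the configured CV", {
  cfg <- null_config(seed = 11, n_features = c(protein = 400),
                     tech_cv = 0.1, patient_sd = 0)
  coh <- generate_discovery_cohort(cfg)
  cv <- apply(coh$tables$protein$values, 1, function(x) sd(x) / mean(x))
  # oracle: direct per-feature CV of the draws at large feature count
  expect_equal(median(cv), 0.1, tolerance = 0.05)
  expect_lt(abs(mean(cv) - 0.1), 0.01)
})

test_that("group-mean log2 differences equal planted effects as noise vanishes", {
  cfg <- sim_config(n_features = c(protein = 40),
                    n_cross_only = c(protein = 5), n_long_only = c(protein = 5),
                    n_improvement = c(protein = 5), n_aggravation = c(protein = 5),
                    tech_cv = 1e-6, patient_sd = 0,
                    mnar_midpoint = -1e3, mcar_rate = 0, seed = 3)
  coh <- generate_discovery_cohort(cfg)
  lg <- log2(coh$tables$protein$values)
  d <- coh$design
  base <- d$timepoint == "baseline"
  cross_hat <- rowMeans(lg[, base & d$group == "VH_TRD"]) -
    rowMeans(lg[, base & d$group == "simpleVH"])
  long_hat <- rowMeans(lg[, d$timepoint == "post"]) - rowMeans(lg[, base])
  expect_equal(unname(cross_hat), coh$truth$effect_log2_cross, tolerance = 1e-4)
  expect_equal(unname(long_hat), coh$truth$effect_log2_long, tolerance = 1e-4)
})

test_that("validation cohort has the three-group paired design", {
  cfg <- sim_config(n_features = c(protein = 50),
                    n_cross_only = c(protein = 4), n_long_only = c(protein = 0),
                    n_improvement = c(protein = 0), n_aggravation = c(protein = 2),
                    seed = 5)
  val <- generate_validation_cohort(cfg, layer = "protein")
  expect_equal(ncol(val$table$values), 10 + 2 * 5 + 2 * 5)
  expect_equal(sum(val$design$group == "control"), 10)
  expect_true(all(table(val$design$patient_id[val$design$group != "control"]) == 2))
  val2 <- generate_validation_cohort(cfg, layer = "protein")
  expect_identical(val$table$values, val2$table$values)
})

test_that("planted biphasic features are recoverable from validation group means", {
  # elevated in PDR vs control, yet depleted in VH_TRD vs simpleVH
  cfg <- sim_config(n_features = c(protein = 200),
                    n_cross_only = c(protein = 30), n_long_only = c(protein = 0),
                    n_improvement = c(protein = 0), n_aggravation = c(protein = 0),
                    effect_log2_cross = 1.5, effect_log2_disease = 2,
                    tech_cv = 0.05, patient_sd = 0.05,
                    mnar_midpoint = -1e3, mcar_rate = 0, seed = 9)
  val <- generate_validation_cohort(cfg, layer = "protein")
  lg <- log2(val$table$values)
  d <- val$design
  base <- d$timepoint == "baseline"
  tr <- val$truth
  down_cross <- tr$label == "cross_only" & tr$effect_log2_cross < 0
  expect_gt(sum(down_cross), 0)
  m_ctrl <- rowMeans(lg[down_cross, d$group == "control", drop = FALSE])
  m_svh <- rowMeans(lg[down_cross, base & d$group == "simpleVH", drop = FALSE])
  m_trd <- rowMeans(lg[down_cross, base & d$group == "VH_TRD", drop = FALSE])
  # both signs recoverable: PDR above control, severe phenotype below simpleVH
  expect_true(all(m_svh > m_ctrl))
  expect_true(all(m_trd < m_svh))
})

test_that("missingness follows the MNAR logistic union MCAR model", {
  cfg0 <- sim_config(n_features = c(protein = 200), seed = 2,
                     n_cross_only = c(protein = 0), n_long_only = c(protein = 0),
                     n_improvement = c(protein = 0), n_aggravation = c(protein = 0),
                     mnar_midpoint = 18, mnar_slope = 0, mcar_rate = 0,
                     baseline_log2_mean_range = c(18, 18), tech_cv = 1e-6,
                     patient_sd = 0)
  coh <- generate_discovery_cohort(cfg0)
  # slope 0: constant masking probability 0.5 (logistic(0)); check empirically
  expect_equal(mean(is.na(coh$tables$protein$values)), 0.5, tolerance = 0.02)

  # very high abundances, mcar 0: masking probability -> 0
  cfg1 <- sim_config(n_features = c(protein = 100), seed = 2,
                     n_cross_only = c(protein = 0), n_long_only = c(protein = 0),
                     n_improvement = c(protein = 0), n_aggravation = c(protein = 0),
                     mnar_midpoint = 12, mnar_slope = 1, mcar_rate = 0,
                     baseline_log2_mean_range = c(40, 45))
  coh1 <- generate_discovery_cohort(cfg1)
  expect_equal(sum(is.na(coh1$tables$protein$values)), 0)

  # empirical missing rate is monotone non-increasing across abundance deciles
  cfg2 <- sim_config(n_features = c(protein = 2000), seed = 4,
                     n_cross_only = c(protein = 0), n_long_only = c(protein = 0),
                     n_improvement = c(protein = 0), n_aggravation = c(protein = 0),
                     mnar_midpoint = 16, mnar_slope = 1, mcar_rate = 0.02,
                     baseline_log2_mean_range = c(14, 22), tech_cv = 0.1,
                     patient_sd = 0)
  coh2 <- generate_discovery_cohort(cfg2)
  v <- coh2$tables$protein$values
  mu <- rowMeans(log2(v), na.rm = TRUE)
  dec <- cut(mu, quantile(mu, 0:10 / 10), include.lowest = TRUE)
  rate <- tapply(rowMeans(is.na(v)), dec, mean)
  expect_true(all(diff(rate) <= 0.02))  # monotone up to sampling jitter
})
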