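test_that("the assumption gate follows the decision table", {
  set.seed(16)
  a <- rnorm(60); b <- rnorm(60)
  expect_equal(assess_assumptions(a, b)$test, "t")

  bh <- rnorm(60, sd = 6)
  expect_equal(assess_assumptions(a, bh)$test, "welch_t")

  sk <- exp(2 * rnorm(60)); sk2 <- exp(2 * rnorm(60))
  expect_equal(assess_assumptions(sk, sk2)$test, "wilcoxon")

  d <- rnorm(30)
  expect_equal(assess_assumptions(d + 1 + rnorm(30, sd = 0.3), d,
                                  paired = TRUE)$test, "paired_t")
  expect_equal(assess_assumptions(exp(d) + 1, exp(d) * 0,
                                  paired = TRUE)$test, "signed_rank")

  # too few observations: nonparametric fallback
  expect_equal(assess_assumptions(c(1, 2), c(3, 4))$test, "wilcoxon")
})

test_that("gated p-values match closed-form and enumeration oracles", {
  # textbook pooled t on {1,2,3} vs {2,3,4}
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  gate <- list(test = "t")
  expect_equal(two_group_test(a, b, gate), oracle_t_p(a, b), tolerance = 1e-12)

  # signed-rank, 5 all-positive differences: exact two-sided p = 0.0625
  before <- c(1, 2, 3, 4, 5); after <- before + c(0.5, 1, 0.2, 0.8, 1.4)
  p <- two_group_test(after, before, list(test = "signed_rank"), paired = TRUE)
  expect_equal(p, 0.0625)
  expect_equal(p, oracle_signedrank_p(after - before))

  # identical arms: t statistic is 0 -> p = 1
  x <- c(1, 2, 3)
  expect_equal(two_group_test(x, x, list(test = "t")), 1)
  # zero variance in both arms: degenerate convention p = 1 with warning
  expect_warning(p1 <- two_group_test(c(1, 1, 1), c(2, 2, 2),
                                      list(test = "t")), "zero variance")
  expect_equal(p1, 1)
  expect_equal(suppressWarnings(
    two_group_test(c(1, 2, 3, 4), c(1, 2, 3, 4), list(test = "wilcoxon"))), 1)
})

test_that("fold change follows linear-scale means with direction by sign", {
  f <- fold_change(c(3, 3), c(2, 2))
  expect_equal(f$fc, 1.5)
  expect_equal(f$direction, "up")
  expect_equal(f$log2fc, log2(1.5))

  set.seed(11)
  a <- runif(10, 1, 5); b <- runif(10, 1, 5)
  expect_equal(fold_change(a, b)$fc * fold_change(b, a)$fc, 1)

  expect_equal(fold_change(c(2, 4), c(4, 2))$direction, "flat")
  expect_error(fold_change(1:3, c(0, 0, 0)), "zero reference")
})

test_that("NIPALS PLS-DA matches an independent implementation", {
  set.seed(12)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- rep(c(0, 1), each = 4)
  m <- fit_plsda(X, y, n_components = 3)
  o <- oracle_nipals(X, y - mean(y), 3)
  # weights match up to component-wise sign
  for (a in 1:3) {
    s <- sign(sum(m$weights[, a] * o$weights[, a]))
    expect_equal(unname(m$weights[, a]), s * o$weights[, a], tolerance = 1e-8)
    expect_equal(unname(m$scores[, a]), s * o$scores[, a], tolerance = 1e-8)
  }
  expect_equal(m$ssy, o$ssy, tolerance = 1e-8)
  expect_equal(unname(vip_scores(m)), oracle_vip(o$weights, o$ssy),
               tolerance = 1e-8)
})

test_that("PLS-DA handles the one-feature and orthogonal-noise cases", {
  y <- rep(c(0, 1), each = 10)
  X1 <- matrix(y + 0, ncol = 1)
  m1 <- fit_plsda(X1, y, n_components = 1)
  expect_equal(abs(unname(m1$weights[1, 1])), 1)
  # first component explains all of SSY
  expect_equal(m1$ssy[1], sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(unname(vip_scores(m1)), 1)

  set.seed(13)
  X <- cbind(signal = y + rnorm(20, sd = 0.05), noise = rnorm(20))
  m <- fit_plsda(X, y, n_components = 1)
  expect_gt(abs(m$weights["signal", 1]), 0.99)
  expect_lt(abs(m$weights["noise", 1]), 0.15)

  Xc <- cbind(X, flat = rep(1, 20))
  expect_warning(mc <- fit_plsda(Xc, y, n_components = 1), "constant")
  expect_equal(mc$dropped, "flat")
})

test_that("the VIP identity sum(vip^2) = p holds on random models", {
  set.seed(14)
  for (i in 1:5) {
    n <- sample(8:20, 1); p <- sample(3:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(0, 1), length.out = n)
    m <- fit_plsda(X, y, n_components = 2)
    v <- vip_scores(m)
    expect_equal(sum(v^2), length(v), tolerance = 1e-8)
  }
})

test_that("dual-threshold significance calling is layer specific", {
  prot <- data.frame(p_value = c(0.01, 0.01, 0.2, 0.04),
                     fc = c(0.5, 1.4, 3, 1.6))
  out <- call_significant(prot, "protein")
  # fc 0.5 -> 1/fc = 2 > 1.5 significant; fc 1.4 not; p 0.2 not; 1.6 yes
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE))

  met <- data.frame(p_value = c(0.03, 0.03, 0.2), fc = c(1, 1, 1),
                    vip = c(1.2, 0.8, 2))
  expect_equal(call_significant(met, "metabolite")$significant,
               c(TRUE, FALSE, FALSE))
  met$vip <- NULL
  met$fc <- 2
  expect_error(call_significant(met, "metabolite"), "VIP")
})

test_that("run_differential reports both axes with correct references", {
  cfg <- sim_config(n_features = c(protein = 120),
                    n_cross_only = c(protein = 10),
                    n_long_only = c(protein = 10),
                    n_improvement = c(protein = 5),
                    n_aggravation = c(protein = 5),
                    tech_cv = 0.05, patient_sd = 0.1,
                    mnar_midpoint = -1e3, mcar_rate = 0, seed = 15)
  coh <- generate_discovery_cohort(cfg)
  tab <- normalize_layer(coh$tables$protein)
  cross <- run_differential(tab, coh$design, "cross_sectional")
  long <- run_differential(tab, coh$design, "longitudinal")
  tr <- coh$truth
  # signs of estimated log2fc agree with planted effects where planted
  pl <- tr$effect_log2_cross != 0
  expect_true(all(sign(cross$log2fc[pl]) == sign(tr$effect_log2_cross[pl])))
  pl2 <- tr$effect_log2_long != 0
  expect_true(all(sign(long$log2fc[pl2]) == sign(tr$effect_log2_long[pl2])))
  # paired tests used on the longitudinal axis
  expect_true(all(long$test_used %in% c("paired_t", "signed_rank")))
  expect_true(all(cross$test_used %in% c("t", "welch_t", "wilcoxon")))
  # fc = 2^log2fc invariant
  expect_equal(cross$fc, 2^cross$log2fc, tolerance = 1e-12)
})
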