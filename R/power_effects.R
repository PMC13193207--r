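#' Cohen's d with a noncentral-t confidence interval
#'
#' Standardized mean difference using the pooled SD,
#' `d = (mean1 - mean2) / sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`.
#' The confidence interval inverts the noncentral-t distribution of the
#' two-sample t statistic (exact under normality), rather than using the
#' normal-approximation standard error.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (`n >= 2`, `sd > 0`).
#' @param conf Confidence level (default 0.95).
#' @return List of class `EffectSize`: `d`, `ci_low`, `ci_high`.
#' @export
cohens_d_ci <- function(mean1, sd1, n1, mean2, sd2, n2, conf = 0.95) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled SD")
  d <- (mean1 - mean2) / sqrt(sp2)
  mult <- sqrt(n1 * n2 / (n1 + n2))   # t = d * mult, ncp = delta * mult
  tobs <- d * mult
  df <- n1 + n2 - 2
  a <- (1 - conf) / 2
  ci <- .ncp_ci(tobs, df, a) / mult
  structure(list(d = d, ci_low = ci[1], ci_high = ci[2]),
            class = "EffectSize")
}

# invert the noncentral-t CDF in the noncentrality parameter
.ncp_ci <- function(tobs, df, a) {
  lim <- abs(tobs) + 20
  # pt() with ncp emits precision notes far below the tolerance that
  # matters here; silence them
  pnt <- function(q, df, ncp) suppressWarnings(stats::pt(q, df, ncp))
  lo <- tryCatch(
    stats::uniroot(function(ncp) pnt(tobs, df, ncp) - (1 - a),
                   c(-lim, lim), tol = 1e-9)$root,
    error = function(e) -lim)
  hi <- tryCatch(
    stats::uniroot(function(ncp) pnt(tobs, df, ncp) - a,
                   c(-lim, lim), tol = 1e-9)$root,
    error = function(e) lim)
  c(lo, hi)
}

#' Power of the two-sided two-sample t test
#'
#' Power at effect size `d` with group sizes `n1`, `n2`: the probability
#' that `|T|` exceeds the two-sided critical value under the noncentral-t
#' alternative with `ncp = d * sqrt(n1 n2 / (n1 + n2))`.
#'
#' @param d Cohen's d.
#' @param n1,n2 Group sizes (`>= 2`).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1).
#' @export
power_two_sample_t <- function(d, n1, n2 = n1, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  suppressWarnings(stats::pt(-tc, df, ncp) +
                     stats::pt(tc, df, ncp, lower.tail = FALSE))
}

#' Prospective sample size for the two-sample t test
#'
#' Smallest per-group `n` whose two-sided t-test power at effect size `d`
#' reaches the target (balanced design).
#'
#' @param d Cohen's d (non-zero).
#' @param power Target power (default 0.80).
#' @param alpha Two-sided significance level (default 0.05).
#' @param n_max Search cap; exceeding it aborts with a message that the
#'   effect is too small to resolve.
#' @return Integer n per group.
#' @export
sample_size_two_sample_t <- function(d, power = 0.80, alpha = 0.05,
                                     n_max = 1e5) {
  if (d == 0) stop("d must be non-zero")
  n <- 2
  while (power_two_sample_t(d, n, n, alpha) < power) {
    n <- n + 1
    if (n > n_max)
      stop("effect size too small to resolve within n_max per group")
  }
  n
}

#' Covariate-adjusted group comparison (ANCOVA sensitivity analysis)
#'
#' Linear model of one feature's log2 abundance on group plus baseline
#' covariates (age, sex, diabetes duration, HbA1c by default), fitted on
#' baseline cross-sectional samples; the reported p-value is the partial
#' F-test for the group term. Sex (and any other categorical covariate)
#' enters as an indicator via the usual treatment contrasts. Samples with
#' missing covariates are dropped listwise with a warning; covariates that
#' are constant or aliased in the fit are dropped with a warning.
#'
#' @param values Named numeric vector of log2 abundances (names = sample
#'   ids), or a vector aligned with `design` rows.
#' @param design A [study_design()] with the covariate columns.
#' @param covariates Covariate column names (default
#'   `age, sex, diabetes_duration, hba1c`).
#' @param groups The two groups compared (default simpleVH vs VH_TRD at
#'   baseline).
#' @return List: `p_value` (partial F for group), `n_used`,
#'   `dropped_covariates`, `fit`.
#' @export
ancova_adjust <- function(values, design,
                          covariates = c("age", "sex", "diabetes_duration",
                                         "hba1c"),
                          groups = c("simpleVH", "VH_TRD")) {
  d <- as.data.frame(design)
  if (!is.null(names(values))) {
    d <- d[d$sample_id %in% names(values), , drop = FALSE]
    values <- values[d$sample_id]
  } else if (length(values) != nrow(d)) {
    stop("'values' must be named by sample id or aligned with the design")
  }
  keep <- d$timepoint == "baseline" & d$group %in% groups
  d <- d[keep, , drop = FALSE]
  y <- values[keep]
  miss <- setdiff(covariates, names(d))
  if (length(miss)) stop("design lacks covariate(s): ",
                         paste(miss, collapse = ", "))
  cc <- stats::complete.cases(d[, covariates, drop = FALSE]) & !is.na(y)
  if (any(!cc)) {
    warning(sprintf("dropping %d sample(s) with missing covariates (listwise)",
                    sum(!cc)))
    d <- d[cc, , drop = FALSE]; y <- y[cc]
  }
  dat <- data.frame(y = y, group = factor(d$group),
                    d[, covariates, drop = FALSE])
  # drop constant covariates up front
  const <- vapply(covariates, function(v) length(unique(dat[[v]])) < 2, TRUE)
  dropped <- covariates[const]
  use <- covariates[!const]
  full_fml <- stats::reformulate(c("group", use), response = "y")
  fit <- stats::lm(full_fml, data = dat)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    al_cov <- use[vapply(use, function(v) any(startsWith(aliased, v)), TRUE)]
    dropped <- c(dropped, al_cov)
    use <- setdiff(use, al_cov)
    fit <- stats::lm(stats::reformulate(c("group", use), response = "y"),
                     data = dat)
  }
  if (length(dropped))
    warning("dropped constant/collinear covariate(s): ",
            paste(dropped, collapse = ", "))
  red <- stats::lm(stats::reformulate(if (length(use)) use else "1",
                                      response = "y"), data = dat)
  an <- stats::anova(red, fit)
  list(p_value = an[["Pr(>F)"]][2], n_used = nrow(dat),
       dropped_covariates = dropped, fit = fit)
}
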