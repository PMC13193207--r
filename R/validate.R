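#' Kruskal-Wallis test across groups
#'
#' Rank-based k-group test with average-rank tie correction; p-value from
#' the chi-square approximation with `g - 1` degrees of freedom. A fully
#' constant input returns `H = 0, p = 1`.
#'
#' @param groups List of numeric vectors (each non-empty; total n >= 3).
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (any(lengths(groups) == 0)) stop("each group needs >= 1 observation")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need >= 3 observations in total")
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1, p_value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pairwise Wilcoxon rank-sum tests
#'
#' Two-sided rank-sum p-value for every pair of groups: exact when both
#' arms are small and tie-free, normal approximation with continuity and
#' tie correction otherwise. Intended to follow a significant overall
#' [kruskal_wallis()] test. No multiplicity adjustment by default;
#' `adjust = "holm"` is available.
#'
#' @param groups Named list of numeric vectors.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Symmetric matrix of p-values (diagonal `NA`).
#' @export
pairwise_wilcoxon <- function(groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (any(lengths(groups) == 0)) stop("empty group")
  g <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(g))
  pm <- matrix(NA_real_, g, g, dimnames = list(nm, nm))
  ps <- c(); pi_ <- c(); pj <- c()
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    a <- groups[[i]]; b <- groups[[j]]
    p <- if (all(c(a, b) == c(a, b)[1])) 1 else suppressWarnings(
      stats::wilcox.test(a, b)$p.value)
    ps <- c(ps, p); pi_ <- c(pi_, i); pj <- c(pj, j)
  }
  if (adjust == "holm") ps <- stats::p.adjust(ps, "holm")
  for (k in seq_along(ps)) {
    pm[pi_[k], pj[k]] <- pm[pj[k], pi_[k]] <- ps[k]
  }
  pm
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired measurements; zero differences
#' are dropped (standard Wilcoxon convention), the exact distribution is
#' used for up to 25 non-zero tie-free differences, the normal
#' approximation otherwise. All-zero differences give `p = 1`.
#'
#' @param before,after Equal-length paired vectors.
#' @return Two-sided p-value.
#' @export
paired_signed_rank <- function(before, after) {
  if (length(before) != length(after)) stop("paired vectors differ in length")
  d <- after - before
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  suppressWarnings(
    stats::wilcox.test(d, exact = length(d) <= 25)$p.value)
}

#' Fit an internal-standard calibration curve
#'
#' Weighted least-squares line of response ratio (analyte signal over
#' isotope-labelled internal-standard signal) on nominal concentration.
#' The bioanalytical `1/x` weighting is the default, down-weighting high
#' calibrants so relative accuracy is even across the range.
#'
#' @param levels Data frame with columns `concentration` (nmol/L, > 0 for
#'   `1/x` weighting) and `ratio`; at least 3 levels.
#' @param weighting `"1/x"` (default) or `"none"`.
#' @return List of class `CalibrationCurve`: `slope`, `intercept`,
#'   `r_squared`, `weighting`, `levels`.
#' @export
fit_calibration <- function(levels, weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  if (!all(c("concentration", "ratio") %in% names(levels)))
    stop("'levels' needs columns 'concentration' and 'ratio'")
  if (nrow(levels) < 3) stop("at least 3 calibration levels are required")
  w <- if (weighting == "1/x") {
    if (any(levels$concentration <= 0))
      stop("1/x weighting requires positive concentrations")
    1 / levels$concentration
  } else rep(1, nrow(levels))
  fit <- stats::lm(ratio ~ concentration, data = levels, weights = w)
  co <- stats::coef(fit)
  if (co[["concentration"]] == 0) stop("degenerate calibration: zero slope")
  structure(list(slope = unname(co[["concentration"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 # noiseless calibrants trip summary.lm's perfect-fit note
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 weighting = weighting, levels = levels),
            class = "CalibrationCurve")
}

#' Absolute concentration from a calibration curve
#'
#' Inverts the fitted line: `(ratio - intercept) / slope`. Values outside
#' the calibrated concentration range are returned with an out-of-range
#' flag rather than censored.
#'
#' @param curve A [fit_calibration()] result.
#' @param response_ratio Numeric vector of observed response ratios.
#' @return Data frame with `concentration` (nmol/L) and `out_of_range`.
#' @export
quantify_absolute <- function(curve, response_ratio) {
  stopifnot(inherits(curve, "CalibrationCurve"))
  if (curve$slope == 0) stop("zero slope")
  conc <- (response_ratio - curve$intercept) / curve$slope
  rng <- range(curve$levels$concentration)
  data.frame(concentration = conc,
             out_of_range = conc < rng[1] | conc > rng[2])
}

#' QC coefficient of variation with pass/fail gating
#'
#' @param values Replicate measurements (>= 2, positive mean).
#' @param threshold CV acceptance threshold (default 0.20).
#' @return List with `cv` (sample SD / mean) and `pass`.
#' @export
qc_cv <- function(values, threshold = 0.20) {
  if (length(values) < 2) stop("need >= 2 replicates")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  cv <- stats::sd(values) / m
  list(cv = cv, pass = cv < threshold)
}

#' Wound-closure and gel-contraction quantification
#'
#' `wound_closure` returns `(area_0h - area_t) / area_0h * 100` (percent
#' of the initial wound closed at time t; negative with a warning if the
#' wound widened); `gel_area` returns the relative gel area
#' `area_t / area_0h * 100` (smaller = stronger contraction).
#'
#' @param area_0h,area_t Positive areas at time 0 and time t.
#' @param mode `"wound_closure"` or `"gel_area"`.
#' @return Percentage.
#' @export
assay_quant <- function(area_0h, area_t, mode = c("wound_closure", "gel_area")) {
  mode <- match.arg(mode)
  if (any(area_0h <= 0) || any(area_t <= 0)) stop("areas must be positive")
  if (mode == "wound_closure") {
    out <- (area_0h - area_t) / area_0h * 100
    if (any(out < 0)) warning("negative wound closure (wound widened)")
    out
  } else {
    area_t / area_0h * 100
  }
}
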