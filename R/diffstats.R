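#' Classic Levene test of variance homogeneity
#'
#' Centre-at-mean Levene test: one-way ANOVA on the absolute deviations
#' from the group means. Used by the assumption gate; exported because the
#' validation module reuses it.
#'
#' @param groups List of numeric vectors.
#' @return List with `statistic` (F), `df` and `p_value`.
#' @export
levene_test <- function(groups) {
  g <- length(groups)
  z <- lapply(groups, function(x) abs(x - mean(x)))
  ni <- lengths(z)
  N <- sum(ni)
  zbar_i <- vapply(z, mean, 0)
  zbar <- sum(ni * zbar_i) / N
  ssb <- sum(ni * (zbar_i - zbar)^2)
  ssw <- sum(vapply(z, function(zi) sum((zi - mean(zi))^2), 0))
  if (ssw == 0) {
    stat <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    stat <- (ssb / (g - 1)) / (ssw / (N - g))
    p <- stats::pf(stat, g - 1, N - g, lower.tail = FALSE)
  }
  list(statistic = stat, df = c(g - 1, N - g), p_value = p)
}

.shapiro_p <- function(x) {
  # non-testable vectors (too short, essentially constant) are treated as
  # non-Normal so the gate falls back to a rank test
  if (length(x) < 3 || length(x) > 5000) return(0)
  if (stats::sd(x) == 0) return(0)
  out <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  out
}

#' Choose the two-group test from normality and variance checks
#'
#' Implements the assumption gate used per feature: Shapiro-Wilk normality
#' on each arm (on the paired differences when `paired`), Levene variance
#' homogeneity for the unpaired case, all at `alpha`. Decision table:
#' both arms Normal and homoscedastic -> Student t; Normal but
#' heteroscedastic -> Welch t; otherwise Wilcoxon rank-sum. Paired: Normal
#' differences -> paired t, otherwise Wilcoxon signed-rank. Arms with
#' fewer than 3 usable observations route to the nonparametric fallback.
#'
#' @param valuesA,valuesB Numeric vectors (aligned pairs when `paired`).
#' @param paired Logical.
#' @param alpha Gate level (default 0.05).
#' @return A list of class `test_gate`: `test` (one of `t`, `welch_t`,
#'   `wilcoxon`, `paired_t`, `signed_rank`), plus the gate p-values.
#' @export
assess_assumptions <- function(valuesA, valuesB, paired = FALSE,
                               alpha = 0.05) {
  if (paired) {
    if (length(valuesA) != length(valuesB))
      stop("paired arms must have equal length")
    d <- valuesA - valuesB
    p_norm <- .shapiro_p(d)
    test <- if (length(d) >= 3 && p_norm >= alpha) "paired_t" else "signed_rank"
    gate <- list(test = test, p_normal_diff = p_norm)
  } else {
    pa <- .shapiro_p(valuesA)
    pb <- .shapiro_p(valuesB)
    if (length(valuesA) < 3 || length(valuesB) < 3) {
      gate <- list(test = "wilcoxon", p_normal_A = pa, p_normal_B = pb)
    } else if (pa >= alpha && pb >= alpha) {
      p_var <- levene_test(list(valuesA, valuesB))$p_value
      test <- if (p_var >= alpha) "t" else "welch_t"
      gate <- list(test = test, p_normal_A = pa, p_normal_B = pb,
                   p_levene = p_var)
    } else {
      gate <- list(test = "wilcoxon", p_normal_A = pa, p_normal_B = pb)
    }
  }
  class(gate) <- "test_gate"
  gate
}

#' Two-group test p-value under an assumption gate
#'
#' Runs the test selected by [assess_assumptions()] and returns the
#' two-sided p-value. Rank tests use exact small-sample distributions where
#' feasible (no ties/zeros). Two arms with zero variance yield `p = 1` with
#' a warning (degenerate-input convention).
#'
#' @param valuesA,valuesB Numeric vectors.
#' @param gate A `test_gate` from [assess_assumptions()] (computed if
#'   missing).
#' @param paired Logical; must match the gate.
#' @return Two-sided p-value.
#' @export
two_group_test <- function(valuesA, valuesB, gate = NULL, paired = FALSE) {
  if (is.null(gate)) gate <- assess_assumptions(valuesA, valuesB, paired)
  if (stats::var(valuesA) == 0 && stats::var(valuesB) == 0) {
    warning("zero variance in both arms; returning p = 1")
    return(1)
  }
  p <- switch(gate$test,
    t = stats::t.test(valuesA, valuesB, var.equal = TRUE)$p.value,
    welch_t = stats::t.test(valuesA, valuesB)$p.value,
    wilcoxon = suppressWarnings(
      stats::wilcox.test(valuesA, valuesB)$p.value),
    paired_t = {
      d <- valuesA - valuesB
      if (stats::sd(d) == 0) {
        warning("all paired differences equal; returning p = 1")
        1
      } else stats::t.test(valuesA, valuesB, paired = TRUE)$p.value
    },
    signed_rank = {
      d <- valuesA - valuesB
      if (all(d == 0)) 1 else suppressWarnings(
        stats::wilcox.test(valuesA, valuesB, paired = TRUE,
                           exact = sum(d != 0) <= 25)$p.value)
    },
    stop("unknown gated test: ", gate$test))
  min(p, 1)
}

#' Linear-scale fold change and direction
#'
#' Fold change is the ratio of linear-scale arithmetic group means,
#' group-of-interest over reference (back-transform log2 data before
#' calling). Direction follows the sign of the log2 fold change; `flat`
#' only at exactly zero.
#'
#' @param values_interest,values_reference Linear-scale vectors.
#' @return List with `fc`, `log2fc`, `direction` (`up`/`down`/`flat`).
#' @export
fold_change <- function(values_interest, values_reference) {
  m_ref <- mean(values_reference)
  if (m_ref == 0) stop("zero reference mean; fold change undefined")
  fc <- mean(values_interest) / m_ref
  l2 <- log2(fc)
  list(fc = fc, log2fc = l2,
       direction = if (l2 > 0) "up" else if (l2 < 0) "down" else "flat")
}

#' Fit a PLS-DA model by NIPALS (PLS1)
#'
#' Partial least squares discriminant analysis for a two-class response:
#' features are autoscaled (centred, unit variance; constant features are
#' dropped with a warning), the class indicator is centred, and components
#' are extracted sequentially by NIPALS with X- and y-deflation. The
#' explained response sum of squares per component (`ssy`) feeds the VIP
#' computation.
#'
#' @param X Samples x features numeric matrix.
#' @param y Two-level class labels (factor, character or binary numeric).
#' @param n_components Number of latent components (default 2; truncated
#'   at the effective rank).
#' @param scale Autoscale features (default TRUE).
#' @return List of class `PlsModel`: `weights` (p x A, unit-norm columns),
#'   `scores`, `loadings`, `q`, `ssy`, `n_components`, `features`,
#'   `dropped`.
#' @export
fit_plsda <- function(X, y, n_components = 2, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  yf <- if (is.numeric(y)) factor(y) else factor(as.character(y))
  if (nlevels(yf) != 2) stop("y must have exactly two classes")
  yv <- as.numeric(yf == levels(yf)[2])
  yv <- yv - mean(yv)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d constant feature(s) before PLS-DA",
                    length(dropped)))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Xs <- scale(X, center = TRUE, scale = if (scale) sds else FALSE)
  p <- ncol(Xs)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, nrow(Xs), 0)
  q <- ssy <- numeric(0)
  Xc <- Xs; yc <- yv
  for (a in seq_len(n_components)) {
    wv <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break
    wv <- wv / nw
    tv <- drop(Xc %*% wv)
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- drop(crossprod(Xc, tv)) / tt
    qa <- sum(yc * tv) / tt
    Xc <- Xc - tcrossprod(tv, pv)
    yc <- yc - qa * tv
    W <- cbind(W, wv); P <- cbind(P, pv); Tm <- cbind(Tm, tv)
    q <- c(q, qa); ssy <- c(ssy, qa^2 * tt)
  }
  if (ncol(W) == 0) stop("no PLS component could be extracted")
  rownames(W) <- rownames(P) <- colnames(Xs)
  structure(list(weights = W, scores = Tm, loadings = P, q = q, ssy = ssy,
                 n_components = ncol(W), features = colnames(Xs),
                 dropped = dropped),
            class = "PlsModel")
}

#' Variable importance in projection scores
#'
#' For a fitted PLS model with unit-norm weight vectors `w_a` and
#' explained response sum of squares `ssy_a`,
#' `vip_j = sqrt(p * sum_a ssy_a * w_ja^2 / sum_a ssy_a)` with `p` the
#' number of retained variables; the scores satisfy
#' `sum_j vip_j^2 = p` exactly.
#'
#' @param model A `PlsModel` from [fit_plsda()].
#' @return Named vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "PlsModel"))
  if (all(model$ssy == 0)) stop("model explains no response variance")
  p <- nrow(model$weights)
  w2 <- model$weights^2
  vip <- sqrt(p * drop(w2 %*% model$ssy) / sum(model$ssy))
  names(vip) <- model$features
  vip
}

#' Apply the layer-specific dual significance thresholds
#'
#' Protein features are significant when `p < p_threshold` and the
#' two-sided fold change `max(fc, 1/fc)` exceeds `fc_threshold`; metabolite
#' features when `p < p_threshold` and `vip > vip_threshold`. No
#' multiplicity correction is applied by default; `adjust = "BH"` switches
#' the p criterion to Benjamini-Hochberg adjusted p-values.
#'
#' @param results Data frame with columns `p_value`, `fc` and (for
#'   metabolites) `vip`.
#' @param layer `"protein"` or `"metabolite"`.
#' @param p_threshold,fc_threshold,vip_threshold Thresholds (defaults
#'   0.05, 1.5, 1).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `results` with a logical `significant` column (replaced if
#'   present).
#' @export
call_significant <- function(results, layer = c("protein", "metabolite"),
                             p_threshold = 0.05, fc_threshold = 1.5,
                             vip_threshold = 1, adjust = c("none", "BH")) {
  layer <- match.arg(layer)
  adjust <- match.arg(adjust)
  p <- results$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  if (layer == "protein") {
    sig <- p < p_threshold & pmax(results$fc, 1 / results$fc) > fc_threshold
  } else {
    if (is.null(results$vip) || anyNA(results$vip))
      stop("metabolite significance requires VIP scores for every feature")
    sig <- p < p_threshold & results$vip > vip_threshold
  }
  results$significant <- sig
  results
}

#' Per-feature differential statistics for one comparison axis
#'
#' Runs the full assumption-gated per-feature battery on a normalized
#' table. The cross-sectional axis compares VH_TRD against simpleVH using
#' baseline samples only (unpaired); the longitudinal axis compares
#' post-treatment against baseline across all paired PDR patients (paired
#' by patient). Fold changes are computed on back-transformed (linear
#' scale) group means, group-of-interest (VH_TRD, or post) over reference.
#' For metabolite tables a PLS-DA model is fitted per axis on all features
#' jointly (class = group for cross-sectional, timepoint for longitudinal)
#' and VIP scores attached; significance is then called with the layer's
#' dual thresholds.
#'
#' @param table A normalized [feature_table()] (log2 scale).
#' @param design A [study_design()].
#' @param axis `"cross_sectional"` or `"longitudinal"`.
#' @param n_components PLS-DA components for the metabolite VIP model.
#' @param gate_alpha Assumption-gate level.
#' @param ... Passed to [call_significant()].
#' @return Data frame with one row per feature: `feature_id`, `layer`,
#'   `axis`, `p_value`, `fc`, `log2fc`, `vip` (NA for proteins),
#'   `test_used`, `direction`, `significant`.
#' @export
run_differential <- function(table, design,
                             axis = c("cross_sectional", "longitudinal"),
                             n_components = 2, gate_alpha = 0.05, ...) {
  stopifnot(inherits(table, "FeatureTable"))
  axis <- match.arg(axis)
  if (table$scale_state == "raw")
    stop("run_differential expects a log2/normalized table")
  d <- .design_for(design, colnames(table$values))
  x <- table$values
  lin <- 2^x

  if (axis == "cross_sectional") {
    keep <- d$timepoint == "baseline" & d$group %in% c("simpleVH", "VH_TRD")
    db <- d[keep, ]
    xb <- x[, keep, drop = FALSE]
    linb <- lin[, keep, drop = FALSE]
    ia <- db$group == "simpleVH"; ib <- db$group == "VH_TRD"
    res <- .per_feature_battery(xb, linb, which(ib), which(ia),
                                paired = FALSE, gate_alpha = gate_alpha)
    if (table$layer == "metabolite") {
      mod <- fit_plsda(t(xb), db$group, n_components = n_components)
      res$vip <- vip_scores(mod)[res$feature_id]
    }
  } else {
    pdr <- d[d$group %in% c("simpleVH", "VH_TRD"), ]
    pats <- unique(pdr$patient_id)
    base_id <- pdr$sample_id[match(paste(pats, "baseline"),
                                   paste(pdr$patient_id, pdr$timepoint))]
    post_id <- pdr$sample_id[match(paste(pats, "post"),
                                   paste(pdr$patient_id, pdr$timepoint))]
    ok <- !is.na(base_id) & !is.na(post_id)
    base_i <- match(base_id[ok], colnames(x))
    post_i <- match(post_id[ok], colnames(x))
    res <- .per_feature_battery(x, lin, post_i, base_i, paired = TRUE,
                                gate_alpha = gate_alpha)
    if (table$layer == "metabolite") {
      use <- c(base_i, post_i)
      mod <- fit_plsda(t(x[, use, drop = FALSE]),
                       rep(c("baseline", "post"), each = length(base_i)),
                       n_components = n_components)
      res$vip <- vip_scores(mod)[res$feature_id]
    }
  }
  res$layer <- table$layer
  res$axis <- axis
  res <- res[, c("feature_id", "layer", "axis", "p_value", "fc", "log2fc",
                 "vip", "test_used", "direction")]
  call_significant(res, layer = table$layer, ...)
}

.per_feature_battery <- function(xlog, xlin, idx_interest, idx_ref, paired,
                                 gate_alpha = 0.05) {
  n <- nrow(xlog)
  p_value <- fc <- l2 <- numeric(n)
  test_used <- direction <- character(n)
  for (i in seq_len(n)) {
    a <- xlog[i, idx_interest]; b <- xlog[i, idx_ref]
    gate <- assess_assumptions(a, b, paired = paired, alpha = gate_alpha)
    p_value[i] <- suppressWarnings(two_group_test(a, b, gate, paired = paired))
    f <- fold_change(xlin[i, idx_interest], xlin[i, idx_ref])
    fc[i] <- f$fc; l2[i] <- f$log2fc; direction[i] <- f$direction
    test_used[i] <- gate$test
  }
  data.frame(feature_id = rownames(xlog), p_value = p_value, fc = fc,
             log2fc = l2, vip = NA_real_, test_used = test_used,
             direction = direction, stringsAsFactors = FALSE)
}
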