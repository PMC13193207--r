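#' Filter features by per-group presence
#'
#' Retains features whose fraction of observed (non-missing) values strictly
#' exceeds `min_frac` in at least one design group. "Over 50\%" is read as a
#' strict inequality, so a feature observed in exactly half the samples of
#' every group is removed. For the discovery design the filtering groups are
#' the group x timepoint cells, so a feature that is robustly observed in
#' any one cell survives.
#'
#' @param table A raw-scale [feature_table()].
#' @param design A [study_design()] covering the table's samples.
#' @param min_frac Presence threshold (default 0.5).
#' @param by Grouping used for the rule: `"group_timepoint"` (default) or
#'   `"group"`.
#' @return The filtered table, feature order preserved.
#' @export
filter_presence <- function(table, design, min_frac = 0.5,
                            by = c("group_timepoint", "group")) {
  stopifnot(inherits(table, "FeatureTable"))
  by <- match.arg(by)
  d <- .design_for(design, colnames(table$values))
  cell <- if (by == "group") d$group else paste(d$group, d$timepoint, sep = ".")
  cells <- unique(cell)
  if (any(tabulate(factor(cell, cells)) == 0L))
    stop("a filtering group has zero samples")
  obs <- !is.na(table$values)
  keep <- rep(FALSE, nrow(obs))
  for (cl in cells) {
    idx <- cell == cl
    keep <- keep | (rowMeans(obs[, idx, drop = FALSE]) > min_frac)
  }
  if (!any(keep)) warning("no features pass the presence filter")
  table$values <- table$values[keep, , drop = FALSE]
  table
}

#' Impute missing cells by K-nearest-neighbour features
#'
#' For each missing cell, the K nearest features (rows) by Euclidean
#' distance over co-observed samples — normalised to the root-mean-square
#' difference so features with different co-observation counts are
#' comparable — donate their observed values in that sample, combined as an
#' inverse-distance-weighted mean. Observed cells are never altered. A
#' feature with no co-observed partner observed in the needed sample falls
#' back to its own observed mean (logged via a message).
#'
#' @param table A [feature_table()] (conventionally raw scale, after
#'   [filter_presence()]).
#' @param k Number of neighbours (default 10).
#' @return The table with no remaining missing cells.
#' @export
knn_impute <- function(table, k = 10) {
  stopifnot(inherits(table, "FeatureTable"), k >= 1)
  x <- table$values
  if (!anyNA(x)) return(table)
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  o <- matrix(as.numeric(obs), nrow = nrow(x))
  # pairwise sum of squared differences over co-observed samples, via BLAS:
  # ssd_ij = sum_s o_i o_j (x_i - x_j)^2
  sq <- x0^2
  a <- sq %*% t(o)              # sum o_j * x_i^2 over co-observed
  cross <- x0 %*% t(x0)
  ssd <- a + t(a) - 2 * cross
  nco <- o %*% t(o)
  d2 <- ssd / nco               # mean squared difference; NaN where nco == 0
  diag(d2) <- Inf
  d2[nco == 0] <- Inf

  need <- which(rowSums(!obs) > 0L)
  n_fallback <- 0L
  for (i in need) {
    ord <- order(d2[i, ])       # nearest features first; Inf sorts last
    valid <- is.finite(d2[i, ord])
    ord <- ord[valid]
    miss_s <- which(!obs[i, ])
    fmean <- mean(x[i, obs[i, ]])
    for (s in miss_s) {
      donors <- ord[obs[ord, s]]
      if (length(donors) == 0L) {
        x[i, s] <- fmean
        n_fallback <- n_fallback + 1L
        next
      }
      donors <- donors[seq_len(min(k, length(donors)))]
      dd <- sqrt(d2[i, donors])
      if (any(dd == 0)) {
        x[i, s] <- mean(x[donors[dd == 0], s])
      } else {
        w <- 1 / dd
        x[i, s] <- sum(w * x[donors, s]) / sum(w)
      }
    }
  }
  if (n_fallback > 0L)
    message(sprintf("knn_impute: %d cell(s) imputed by feature-mean fallback",
                    n_fallback))
  table$values <- x
  table
}

#' Median normalization of a log2 matrix
#'
#' Shifts every sample column so its median equals the grand median of the
#' original column medians (a scale-stable common target).
#'
#' @param mat Numeric matrix on the log2 scale, samples in columns.
#' @return The shifted matrix.
#' @export
median_normalize <- function(mat) {
  meds <- apply(mat, 2, stats::median)
  sweep(mat, 2, meds - stats::median(meds))
}

#' Quantile normalization of a log2 matrix
#'
#' Each column's sorted values are replaced by the across-column mean of
#' the order statistics, restored to the column's original ranks; ties are
#' assigned the average of their quantile values. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param mat Numeric matrix on the log2 scale, samples in columns.
#' @return The normalized matrix (all columns share identical sorted
#'   values).
#' @export
quantile_normalize <- function(mat) {
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Log2-transform and normalize one omics layer
#'
#' Applies the layer's normalization convention: protein tables are
#' log2-transformed and median-normalized; metabolite tables are
#' log2-transformed and quantile-normalized.
#'
#' @param table A raw-scale, fully imputed [feature_table()].
#' @return The table on the normalized log2 scale
#'   (`scale_state = "normalized"`).
#' @export
normalize_layer <- function(table) {
  stopifnot(inherits(table, "FeatureTable"))
  if (table$scale_state != "raw")
    stop("normalize_layer expects a raw-scale table")
  if (anyNA(table$values))
    stop("normalize_layer expects a complete (imputed) table")
  if (any(table$values <= 0))
    stop("non-positive value encountered before log2 transform")
  lg <- log2(table$values)
  table$values <- switch(table$layer,
                         protein = median_normalize(lg),
                         metabolite = quantile_normalize(lg))
  table$scale_state <- "normalized"
  table
}
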