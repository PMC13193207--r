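#' Intersect the cross-sectional and longitudinal significant sets
#'
#' Returns the features significant on both comparison axes with both
#' axes' statistics attached, plus the direction-concordance class from
#' [classify_direction()]. The two result tables must come from the same
#' feature universe.
#'
#' @param cross,long Data frames from [run_differential()] for the
#'   cross-sectional and longitudinal axes.
#' @return Data frame of `IntersectionRecord`s: `feature_id`, `layer`,
#'   `d_cross`, `d_long`, `log2fc_cross`, `log2fc_long`, `p_cross`,
#'   `p_long`, `class`.
#' @export
intersect_significant <- function(cross, long) {
  if (!setequal(cross$feature_id, long$feature_id))
    stop("cross and longitudinal results cover different feature universes")
  sig <- intersect(cross$feature_id[cross$significant],
                   long$feature_id[long$significant])
  ic <- cross[match(sig, cross$feature_id), ]
  il <- long[match(sig, long$feature_id), ]
  rec <- data.frame(feature_id = sig,
                    layer = ic$layer,
                    d_cross = ic$direction,
                    d_long = il$direction,
                    log2fc_cross = ic$log2fc,
                    log2fc_long = il$log2fc,
                    p_cross = ic$p_value,
                    p_long = il$p_value,
                    stringsAsFactors = FALSE)
  rec$class <- if (nrow(rec)) classify_direction(rec$d_cross, rec$d_long)
               else character(0)
  rec
}

#' Classify a molecule by direction concordance
#'
#' The pathological direction is anchored to the cross-sectional axis (the
#' deviation of the severe phenotype, VH_TRD relative to simpleVH). A
#' molecule whose longitudinal (post vs baseline) change goes the same way
#' is `aggravation`-type — treatment pushes it further along the
#' pathological deviation; opposite-signed changes are `improvement`-type —
#' treatment reverses the deviation. Flat directions are rejected: callers
#' must exclude zero-change features.
#'
#' @param d_cross,d_long Direction vectors, each element `"up"` or
#'   `"down"`.
#' @return Character vector in `improvement` / `aggravation`.
#' @export
classify_direction <- function(d_cross, d_long) {
  ok <- c("up", "down")
  if (!all(d_cross %in% ok) || !all(d_long %in% ok))
    stop("directions must be 'up' or 'down'; flat/zero-change features ",
         "must be excluded by the caller")
  ifelse(d_cross == d_long, "aggravation", "improvement")
}

#' Summarize an intersection classification
#'
#' @param records Data frame of intersection records with `class` and
#'   `layer` columns (as from [intersect_significant()]).
#' @return List of class `ClassSummary`: `n_total`, `n_improvement`,
#'   `n_aggravation`, `per_layer` (layer x class count table),
#'   `pct_improvement`, `pct_aggravation` (one decimal; 0 with
#'   `empty = TRUE` when there are no records).
#' @export
summarize_classification <- function(records) {
  n <- nrow(records)
  n_imp <- sum(records$class == "improvement")
  n_agg <- sum(records$class == "aggravation")
  per_layer <- if (n) table(layer = records$layer, class = records$class)
               else table(layer = character(0), class = character(0))
  out <- list(n_total = n, n_improvement = n_imp, n_aggravation = n_agg,
              per_layer = per_layer,
              pct_improvement = if (n) round(100 * n_imp / n, 1) else 0,
              pct_aggravation = if (n) round(100 * n_agg / n, 1) else 0,
              empty = n == 0)
  class(out) <- "ClassSummary"
  out
}

#' @export
print.ClassSummary <- function(x, ...) {
  cat(sprintf("Intersection molecules: %d\n", x$n_total))
  cat(sprintf("  improvement-type: %d (%.1f%%)\n", x$n_improvement,
              x$pct_improvement))
  cat(sprintf("  aggravation-type: %d (%.1f%%)\n", x$n_aggravation,
              x$pct_aggravation))
  invisible(x)
}

#' Waterfall ordering of intersection molecules
#'
#' Rows are grouped by class (aggravation first, then improvement) and
#' within class sorted by decreasing longitudinal change magnitude
#' `|log2fc_long|`; ties break deterministically by `feature_id`.
#'
#' @param records Data frame of intersection records.
#' @return The reordered data frame.
#' @export
waterfall_table <- function(records) {
  if (!nrow(records)) return(records)
  cls <- factor(records$class, levels = c("aggravation", "improvement"))
  ord <- order(cls, -abs(records$log2fc_long), records$feature_id)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
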