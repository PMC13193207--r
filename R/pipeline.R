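#' Run the full discovery pipeline on a (synthetic or real) cohort
#'
#' Chains the discovery stages per layer — presence filtering, KNN
#' imputation, log2 + layer-specific normalization, assumption-gated
#' differential statistics on both comparison axes with the layer's dual
#' significance thresholds — then intersects the two significant sets and
#' classifies the shared molecules by direction concordance.
#'
#' @param cohort A list with `tables` (named list of raw
#'   [feature_table()]s) and `design`, as returned by
#'   [generate_discovery_cohort()].
#' @param min_frac Presence-filter threshold.
#' @param k KNN imputation neighbours.
#' @param n_components PLS-DA components for metabolite VIP.
#' @param ... Passed to [run_differential()] (thence
#'   [call_significant()]).
#' @return List: `diff` (named list per layer of lists `cross`/`long`
#'   result tables), `records` (classified intersection records across
#'   layers), `summary` (a `ClassSummary`), `background` (named list of
#'   surviving feature ids per layer, the ORA universe).
#' @export
run_discovery_pipeline <- function(cohort, min_frac = 0.5, k = 10,
                                   n_components = 2, ...) {
  diff <- list(); records <- list(); background <- list()
  for (ly in names(cohort$tables)) {
    tab <- cohort$tables[[ly]]
    tab <- filter_presence(tab, cohort$design, min_frac = min_frac)
    tab <- knn_impute(tab, k = k)
    tab <- normalize_layer(tab)
    cross <- run_differential(tab, cohort$design, axis = "cross_sectional",
                              n_components = n_components, ...)
    long <- run_differential(tab, cohort$design, axis = "longitudinal",
                             n_components = n_components, ...)
    diff[[ly]] <- list(cross = cross, long = long)
    records[[ly]] <- intersect_significant(cross, long)
    background[[ly]] <- rownames(tab$values)
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  list(diff = diff, records = records,
       summary = summarize_classification(records),
       background = background)
}
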