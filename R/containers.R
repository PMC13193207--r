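#' Construct a feature-by-sample abundance table
#'
#' Lightweight container for one omics layer: a numeric matrix with features
#' as rows and samples as columns, tagged with the layer name and the current
#' scale of its values. Missing measurements are `NA`.
#'
#' @param values Numeric matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids). Raw-scale values must be
#'   positive where observed.
#' @param layer Omics layer, `"protein"` or `"metabolite"`.
#' @param scale_state One of `"raw"`, `"log2"`, `"normalized"`.
#' @return An object of class `FeatureTable`: a list with elements `values`,
#'   `layer`, `scale_state`.
#' @export
feature_table <- function(values, layer = c("protein", "metabolite"),
                          scale_state = c("raw", "log2", "normalized")) {
  layer <- match.arg(layer)
  scale_state <- match.arg(scale_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (feature ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("feature ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  if (scale_state == "raw") {
    obs <- values[!is.na(values)]
    if (any(obs <= 0))
      stop("raw-scale values must be positive where observed")
  }
  structure(list(values = values, layer = layer, scale_state = scale_state),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable: %d features x %d samples [layer=%s, scale=%s]\n",
              nrow(x$values), ncol(x$values), x$layer, x$scale_state))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.FeatureTable <- function(x) dim(x$values)

#' Construct and validate a study design table
#'
#' Maps each sample to its patient, clinical group, timepoint and baseline
#' covariates. Pairing of the longitudinal axis is by `patient_id`.
#'
#' @param df Data frame with columns `sample_id`, `patient_id`, `group`
#'   (in `control`, `simpleVH`, `VH_TRD`), `timepoint` (in `baseline`,
#'   `post`) and optionally covariates `age`, `sex`, `diabetes_duration`,
#'   `hba1c`.
#' @return The validated data frame with class `StudyDesign` prepended.
#' @export
study_design <- function(df) {
  req <- c("sample_id", "patient_id", "group", "timepoint")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  bad_g <- setdiff(unique(as.character(df$group)),
                   c("control", "simpleVH", "VH_TRD"))
  if (length(bad_g)) stop("unknown group(s): ", paste(bad_g, collapse = ", "))
  bad_t <- setdiff(unique(as.character(df$timepoint)), c("baseline", "post"))
  if (length(bad_t)) stop("unknown timepoint(s): ", paste(bad_t, collapse = ", "))
  df$group <- as.character(df$group)
  df$timepoint <- as.character(df$timepoint)
  # at most one sample per patient x timepoint
  if (anyDuplicated(paste(df$patient_id, df$timepoint)))
    stop("each patient may have at most one sample per timepoint")
  class(df) <- c("StudyDesign", class(df))
  df
}

.design_for <- function(design, sample_ids) {
  idx <- match(sample_ids, design$sample_id)
  if (anyNA(idx))
    stop("design does not cover samples: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  design[idx, , drop = FALSE]
}

#' Read / write feature tables and study designs as TSV
#'
#' The on-disk dialect is plain TSV: feature tables have a first column
#' `feature_id` followed by one column per sample; designs are one row per
#' sample. Missing cells are empty fields / `NA`.
#'
#' @param table A [feature_table()] object.
#' @param path File path.
#' @param layer,scale_state Passed to [feature_table()] when reading.
#' @return `read_feature_table` returns a `FeatureTable`;
#'   `read_study_design` a `StudyDesign`; the writers return `path`
#'   invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "FeatureTable"))
  df <- data.frame(feature_id = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, layer, scale_state = "raw") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  feature_table(m, layer = layer, scale_state = scale_state)
}

#' @rdname write_feature_table
#' @export
write_study_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_study_design <- function(path) {
  study_design(utils::read.delim(path))
}
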