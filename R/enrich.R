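#' Read pathway membership sets in GMT format
#'
#' One pathway per tab-separated line: id, description, then member ids.
#' Duplicate members within a line are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return List of pathway sets, each a list with `pathway_id`,
#'   `description`, `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: expected id, description and at least one member", i))
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in pathway '%s' deduplicated", f[1]))
      members <- unique(members)
    }
    out[[i]] <- list(pathway_id = f[1], description = f[2], members = members)
  }
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, members are first intersected with the background
#' universe; with `N` background features, `K` of them in the pathway,
#' `n` hits and `k` hits in the pathway, the p-value is the upper tail
#' `P(X >= k)` of `Hypergeometric(N, K, n)`. Pathways disjoint from the
#' background are skipped with a warning. Results are sorted by ascending
#' p-value; `significant` flags raw `p < p_threshold` (`adjust = "BH"`
#' flags on Benjamini-Hochberg adjusted values instead).
#'
#' @param hits Character vector of differential feature ids (subset of
#'   `background`).
#' @param background Character vector: the tested universe (features
#'   surviving the presence filter).
#' @param sets Pathway list from [read_gmt()].
#' @param p_threshold Significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame: `pathway_id`, `description`, `k`, `K`, `n`, `N`,
#'   `p_value`, `significant`.
#' @export
ora_hypergeometric <- function(hits, background, sets, p_threshold = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  background <- unique(background)
  hits <- unique(hits)
  if (length(background) == 0) stop("empty background universe")
  if (!all(hits %in% background))
    stop("hits must be a subset of the background universe")
  N <- length(background); n <- length(hits)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$members, background)
    if (length(members) == 0) {
      warning(sprintf("pathway '%s' is disjoint from the background; skipped",
                      s$pathway_id))
      return(NULL)
    }
    K <- length(members)
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = s$pathway_id, description = s$description,
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(pathway_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      significant = logical(0)))
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value, res$pathway_id), , drop = FALSE]
  padj <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  res$significant <- padj < p_threshold
  rownames(res) <- NULL
  res
}
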