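# Over-representation analysis of a query gene list against user-supplied
# gene-set collections (GMT): hypergeometric upper-tail p per set with fold
# enrichment, raw-p filtering by default and optional Benjamini-Hochberg
# adjustment.

#' Hypergeometric over-representation test
#'
#' For each set, with `N` the universe size, `K` the set size after
#' intersection with the universe, `n` the query size and `k` the
#' query/set overlap: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` and
#' `fold_enrichment = (k/n) / (K/N)`. Sets empty after intersection with
#' the universe are skipped with a warning. Results are sorted by p
#' ascending (ties by set id), deterministically.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe`.
#' @param universe Character vector of background genes (non-empty).
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param p_threshold Significance threshold on the raw p-value.
#' @param adjust Apply Benjamini-Hochberg adjustment and flag significance
#'   on the adjusted p instead?
#' @return A data.frame with columns `set_id`, `k`, `n`, `K`, `N`,
#'   `p_value`, `fold_enrichment`, `significant` (and `p_adjusted` when
#'   `adjust = TRUE`).
#' @export
overrepresentation_test <- function(query, universe, sets,
                                    p_threshold = 0.05, adjust = FALSE) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(universe)) stop("overrepresentation_test: empty universe")
  if (!length(query)) stop("overrepresentation_test: empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("overrepresentation_test: query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(sid) {
    set <- intersect(unique(sets[[sid]]), universe)
    K <- length(set)
    if (K == 0) {
      warning("set '", sid, "' is empty after intersection with the ",
              "universe; skipped")
      return(NULL)
    }
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = sid, k = k, n = n, K = K, N = N,
               p_value = p,
               fold_enrichment = (k / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(set_id = character(), k = numeric(), n = numeric(),
                      K = numeric(), N = numeric(), p_value = numeric(),
                      fold_enrichment = numeric(), significant = logical()))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  if (adjust) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adjusted < p_threshold
  } else {
    res$significant <- res$p_value < p_threshold
  }
  rownames(res) <- NULL
  res
}
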