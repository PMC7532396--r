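# Target-gene assignment for differentially expressed eRNAs: candidate
# genes within a +/-300 kb window (nearest by default, all-within-window as
# an alternative), intersection with differentially expressed mRNAs, and
# concordance scoring (same regulation direction in eRNA and target).

#' Assign candidate target genes to DE eRNAs
#'
#' Distance is measured from the eRNA interval to the gene interval (0 on
#' overlap), the window bound is inclusive, and `mode = "nearest"` reports
#' the minimal-distance gene(s) (all ties) while `mode = "all"` reports
#' every gene within the window. eRNAs with no gene in the window appear in
#' the `unassigned` element.
#'
#' @param de_ernas Interval table of the DE eRNA probes (`probe_id` or `id`
#'   column identifies them).
#' @param genes Gene table (see [read_gene_table()]).
#' @param window Window size in nucleotides (default 300 kb).
#' @param mode `"nearest"` or `"all"`.
#' @return A list with `pairs` (data.frame `probe_id`, `gene_id`,
#'   `distance`) and `unassigned` (character vector of eRNA ids).
#' @export
assign_targets <- function(de_ernas, genes, window = 300000,
                           mode = c("nearest", "all")) {
  mode <- match.arg(mode)
  if (is.null(de_ernas$probe_id)) de_ernas$probe_id <- de_ernas$id
  pairs <- vector("list", nrow(de_ernas))
  for (i in seq_len(nrow(de_ernas))) {
    hit <- nearest_within(de_ernas[i, , drop = FALSE], genes,
                          window = window, mode = mode)
    if (nrow(hit)) {
      pairs[[i]] <- data.frame(probe_id = de_ernas$probe_id[i], hit,
                               stringsAsFactors = FALSE)
    }
  }
  found <- !vapply(pairs, is.null, logical(1))
  out <- if (any(found)) {
    do.call(rbind, pairs[found])
  } else {
    data.frame(probe_id = character(), gene_id = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  list(pairs = out, unassigned = de_ernas$probe_id[!found])
}

#' Keep eRNA-gene pairs whose gene is differentially expressed
#'
#' Attaches both differential-expression records and flags concordance
#' (same regulation direction). Discordant pairs are retained with
#' `concordant = FALSE`; pairs whose gene is not significant are dropped.
#'
#' @param triples Pair table from [assign_targets()]`$pairs`.
#' @param de_ernas DE table for the eRNA probes, keyed by `probe_id`.
#' @param de_genes DE table for genes, keyed by a `gene_id` column (mRNA
#'   probe results mapped to their genes).
#' @return A data.frame with per-pair eRNA and gene statistics
#'   (`erna_p`, `erna_fc`, `erna_regulation`, `gene_p`, `gene_fc`,
#'   `gene_regulation`) and a `concordant` flag.
#' @export
integrate_with_de_mrna <- function(triples, de_ernas, de_genes) {
  if (is.null(de_genes$gene_id)) {
    stop("integrate_with_de_mrna: de_genes needs a gene_id column")
  }
  sig <- de_genes[de_genes$significant, , drop = FALSE]
  keep <- triples[triples$gene_id %in% sig$gene_id, , drop = FALSE]
  ei <- match(keep$probe_id, de_ernas$probe_id)
  gi <- match(keep$gene_id, sig$gene_id)
  if (anyNA(ei)) {
    stop("integrate_with_de_mrna: eRNA probe missing from de_ernas")
  }
  out <- data.frame(
    keep,
    erna_p = de_ernas$p_value[ei],
    erna_fc = de_ernas$fold_change[ei],
    erna_regulation = de_ernas$regulation[ei],
    gene_p = sig$p_value[gi],
    gene_fc = sig$fold_change[gi],
    gene_regulation = sig$regulation[gi],
    stringsAsFactors = FALSE
  )
  out$concordant <- out$erna_regulation == out$gene_regulation
  rownames(out) <- NULL
  out
}

#' Concordance summary over eRNA-target pairs
#'
#' An eRNA (gene) counts as concordant when at least one of its pairs is
#' concordant; percentages are reported to one decimal place.
#'
#' @param pairs Pair table from [integrate_with_de_mrna()].
#' @return A one-row data.frame: `n_ernas`, `n_genes`,
#'   `n_concordant_ernas`, `n_concordant_genes`, `pct_ernas`, `pct_genes`.
#' @export
concordance_summary <- function(pairs) {
  if (!nrow(pairs)) {
    return(data.frame(n_ernas = 0, n_genes = 0, n_concordant_ernas = 0,
                      n_concordant_genes = 0, pct_ernas = 0, pct_genes = 0))
  }
  conc_e <- tapply(pairs$concordant, pairs$probe_id, any)
  conc_g <- tapply(pairs$concordant, pairs$gene_id, any)
  data.frame(
    n_ernas = length(conc_e), n_genes = length(conc_g),
    n_concordant_ernas = sum(conc_e), n_concordant_genes = sum(conc_g),
    pct_ernas = round(100 * sum(conc_e) / length(conc_e), 1),
    pct_genes = round(100 * sum(conc_g) / length(conc_g), 1)
  )
}
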