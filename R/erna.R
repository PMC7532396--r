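# eRNA and SE-lncRNA calling by minimal interval overlap of lncRNA probe
# annotations with (super)enhancer catalogues, plus the descriptive
# summaries: per-source breakdowns, class-wise mean signal comparisons and
# distribution tables by subclass / length / chromosome.

#' Call eRNAs from lncRNA probes against an enhancer catalogue
#'
#' A lncRNA probe is called as an eRNA when it shares at least `min_overlap`
#' nucleotides (default 1) with any catalogue enhancer. Each probe yields at
#' most one call; its `sources` is the union of sources over all overlapping
#' enhancers and its `chromatin_state` is derived from the STARR enhancers
#' it overlaps: `"open"` if any overlapping STARR enhancer is open,
#' `"closed"` if it overlaps only closed STARR enhancers, `"unknown"` when
#' it overlaps no STARR enhancer or states are unavailable.
#'
#' @param probes Probe table restricted to `rna_class == "lncRNA"`; passing
#'   an mRNA probe is an error.
#' @param catalogue Merged enhancer catalogue (see [merge_catalogs()]); an
#'   optional `chromatin_state` column ("open"/"closed") feeds the eRNA
#'   state rule.
#' @param min_overlap Minimum shared nucleotides.
#' @return A data.frame with columns `probe_id`, `enhancer_ids`
#'   (";"-separated), `sources` (","-separated) and `chromatin_state`,
#'   ordered by probe id.
#' @export
call_ernas <- function(probes, catalogue, min_overlap = 1L) {
  if (any(probes$rna_class != "lncRNA")) {
    stop("call_ernas: probes must all have rna_class == 'lncRNA'")
  }
  empty <- data.frame(probe_id = character(), enhancer_ids = character(),
                      sources = character(), chromatin_state = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(probes) || !nrow(catalogue)) return(empty)
  hits <- intersect_any(probes, catalogue, min_overlap = min_overlap)
  if (!nrow(hits)) return(empty)
  enh_sources <- stats::setNames(catalogue$sources, catalogue$id)
  enh_state <- if (!is.null(catalogue$chromatin_state)) {
    stats::setNames(catalogue$chromatin_state, catalogue$id)
  } else {
    stats::setNames(rep(NA_character_, nrow(catalogue)), catalogue$id)
  }
  calls <- do.call(rbind, lapply(split(hits$subject_id, hits$query_id),
                                 function(enh) {
    enh <- sort(unique(enh))
    src <- join_sources(unique(unlist(split_sources(enh_sources[enh]))))
    starr <- enh[vapply(split_sources(enh_sources[enh]),
                        function(s) "STARR" %in% s, logical(1))]
    st <- enh_state[starr]
    state <- if (!length(starr) || all(is.na(st))) {
      "unknown"
    } else if (any(st == "open", na.rm = TRUE)) {
      "open"
    } else {
      "closed"
    }
    data.frame(enhancer_ids = paste(enh, collapse = ";"), sources = src,
               chromatin_state = state, stringsAsFactors = FALSE)
  }))
  calls <- data.frame(probe_id = rownames(calls), calls,
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$probe_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Call SE-lncRNAs from lncRNA probes against superenhancers
#'
#' Same minimal-overlap rule as [call_ernas()]; a probe overlapping several
#' superenhancers is called once.
#'
#' @param probes lncRNA probe table.
#' @param superenhancers Superenhancer interval table.
#' @param min_overlap Minimum shared nucleotides.
#' @return A data.frame with columns `probe_id` and `superenhancer_ids`
#'   (";"-separated), ordered by probe id.
#' @export
call_se_lncrnas <- function(probes, superenhancers, min_overlap = 1L) {
  if (any(probes$rna_class != "lncRNA")) {
    stop("call_se_lncrnas: probes must all have rna_class == 'lncRNA'")
  }
  empty <- data.frame(probe_id = character(), superenhancer_ids = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(probes) || is.null(superenhancers) || !nrow(superenhancers)) {
    return(empty)
  }
  hits <- intersect_any(probes, superenhancers, min_overlap = min_overlap)
  if (!nrow(hits)) return(empty)
  se <- vapply(split(hits$subject_id, hits$query_id),
               function(s) paste(sort(unique(s)), collapse = ";"),
               character(1))
  out <- data.frame(probe_id = names(se), superenhancer_ids = unname(se),
                    stringsAsFactors = FALSE)
  out <- out[order(out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-source accounting of eRNA calls
#'
#' A call counts toward every source in its `sources`; `total` is the number
#' of distinct calls, so per-source counts sum to `total` exactly when all
#' calls are single-source.
#'
#' @param calls eRNA call table (see [call_ernas()]).
#' @return A one-row data.frame with columns `total`, `DENDB`, `ENCODE`,
#'   `STARR`.
#' @export
source_breakdown <- function(calls) {
  src <- split_sources(calls$sources)
  counts <- vapply(SOURCE_LEVELS, function(s)
    sum(vapply(src, function(x) s %in% x, logical(1))), numeric(1))
  data.frame(total = nrow(calls), DENDB = counts[["DENDB"]],
             ENCODE = counts[["ENCODE"]], STARR = counts[["STARR"]])
}

#' Compare mean expression signal between two probe classes
#'
#' Means are taken over all probe-by-sample entries of each group; the
#' p-value is a two-sided Mann-Whitney test on the per-probe mean signals
#' (reported as `NA` when either group has fewer than 2 probes).
#'
#' @param m Normalised log2 expression matrix.
#' @param group_a_ids,group_b_ids Probe ids of the two classes (non-empty,
#'   all present in `m`).
#' @return A one-row data.frame: `mean_a`, `mean_b`, `n_a`, `n_b`, `p_value`.
#' @export
mean_signal_by_class <- function(m, group_a_ids, group_b_ids) {
  if (!length(group_a_ids) || !length(group_b_ids)) {
    stop("mean_signal_by_class: both groups must be non-empty")
  }
  missing <- setdiff(c(group_a_ids, group_b_ids), rownames(m))
  if (length(missing)) {
    stop("mean_signal_by_class: probe(s) absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  a <- m[group_a_ids, , drop = FALSE]
  b <- m[group_b_ids, , drop = FALSE]
  p <- if (length(group_a_ids) < 2 || length(group_b_ids) < 2) {
    NA_real_
  } else {
    stats::wilcox.test(rowMeans(a), rowMeans(b), exact = FALSE)$p.value
  }
  data.frame(mean_a = mean(a), mean_b = mean(b),
             n_a = length(group_a_ids), n_b = length(group_b_ids),
             p_value = p)
}

#' Distribution summaries of calls: subclass, length bin, chromosome
#'
#' @param calls Call table with a `probe_id` column.
#' @param probes Probe annotation table supplying coordinates and
#'   `lnc_subclass`.
#' @param length_breaks Interior bin edges for probe length in nucleotides;
#'   defaults give bins <500, 500-1000, 1000-5000, >5000.
#' @return A list of three data.frames (`by_subclass`, `by_length`,
#'   `by_chromosome`), each with `category` and `count`; counts in each
#'   table sum to `nrow(calls)`.
#' @export
summarize_distributions <- function(calls, probes,
                                    length_breaks = c(500, 1000, 5000)) {
  p <- probes[match(calls$probe_id, probes$probe_id), , drop = FALSE]
  if (anyNA(p$probe_id)) stop("summarize_distributions: call without probe")
  tally <- function(x) {
    t <- table(x, useNA = "ifany")
    cat <- names(t)
    cat[is.na(cat)] <- "unclassified"
    data.frame(category = cat, count = as.numeric(t),
               stringsAsFactors = FALSE)
  }
  breaks <- c(0, length_breaks, Inf)
  labels <- c(paste0("<", length_breaks[1]),
              paste0(length_breaks[-length(length_breaks)], "-",
                     length_breaks[-1]),
              paste0(">", length_breaks[length(length_breaks)]))
  len_bin <- cut(p$end - p$start, breaks = breaks, labels = labels,
                 right = TRUE, include.lowest = TRUE)
  list(
    by_subclass = tally(if (is.null(p$lnc_subclass)) {
      rep(NA_character_, nrow(p))
    } else {
      p$lnc_subclass
    }),
    by_length = tally(len_bin),
    by_chromosome = tally(p$chrom)
  )
}
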