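# Interval algebra on 0-based half-open coordinates (BED convention).
# All tables are plain data.frames; GRanges is used internally for the
# overlap join, everything else is vectorised arithmetic.

#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open: a feature covering the first 100 bases of
#' a chromosome is `start = 0, end = 100`. Strand is carried but ignored by
#' all overlap and distance operations.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions; must satisfy `start < end`.
#' @param id Unique identifiers; generated (`feature_1`, ...) when `NULL`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown); recycled.
#'
#' @return A data.frame with columns `chrom`, `start`, `end`, `id`, `strand`.
#' @export
#' @examples
#' genomic_intervals("chr1", c(100, 300), c(200, 400), id = c("a", "b"))
genomic_intervals <- function(chrom, start, end, id = NULL, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  if (is.null(id)) id <- paste0("feature_", seq_len(n))
  df <- data.frame(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), id = as.character(id),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval table") {
  req <- c("chrom", "start", "end", "id")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df)) {
    if (any(!is.finite(df$start)) || any(!is.finite(df$end))) {
      stop(what, ": non-finite coordinates")
    }
    if (any(df$start < 0)) stop(what, ": negative start coordinate")
    if (any(df$start >= df$end)) {
      stop(what, ": start must be < end (0-based half-open)")
    }
    if (anyDuplicated(df$id)) {
      stop(what, ": duplicate id(s): ",
           paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
    }
  }
  invisible(df)
}

as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Overlap length between two intervals
#'
#' Vectorised over pairs (arguments recycled to equal length). Returns 0 for
#' intervals on different chromosomes and for book-ended (touching) intervals;
#' symmetric in its arguments.
#'
#' @param a,b Interval tables (rows are paired positionally).
#' @return Integer vector of overlap lengths in nucleotides.
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ifelse(a$chrom[ai] == b$chrom[bi], pmax(0, ov), 0)
}

#' Gap distance between two intervals
#'
#' 0 when the intervals overlap or touch, the number of intervening bases
#' otherwise, `Inf` across chromosomes. Strand-blind.
#'
#' @inheritParams overlap_length
#' @return Numeric vector of distances.
#' @export
interval_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  gap <- pmax(0, pmax(a$start[ai], b$start[bi]) - pmin(a$end[ai], b$end[bi]))
  ifelse(a$chrom[ai] == b$chrom[bi], gap, Inf)
}

#' All query/subject pairs overlapping by at least `min_overlap` nucleotides
#'
#' The workhorse overlap join behind eRNA and SE-lncRNA calling: every pair
#' with a shared stretch of at least `min_overlap` nucleotides is reported.
#' The default of 1 nt implements the minimal-overlap calling rule.
#'
#' @param queries,subjects Interval tables.
#' @param min_overlap Minimum shared nucleotides (>= 1).
#' @return A data.frame with columns `query_id`, `subject_id`, sorted by
#'   query id then subject id. Empty inputs yield an empty result.
#' @export
intersect_any <- function(queries, subjects, min_overlap = 1L) {
  stopifnot(min_overlap >= 1)
  validate_intervals(queries, "queries")
  validate_intervals(subjects, "subjects")
  empty <- data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(queries) || !nrow(subjects)) return(empty)
  hits <- GenomicRanges::findOverlaps(
    as_granges(queries), as_granges(subjects),
    minoverlap = as.integer(min_overlap)
  )
  if (!length(hits)) return(empty)
  out <- data.frame(
    query_id = queries$id[S4Vectors::queryHits(hits)],
    subject_id = subjects$id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes nearest to (or all within) a window around a query interval
#'
#' Distance is 0 for overlap, else the gap between nearest ends; the window
#' bound is inclusive (a gene at exactly `window` nucleotides is kept).
#' `mode = "nearest"` returns the minimal-distance gene(s) (all ties);
#' `mode = "all"` returns every gene within the window.
#'
#' @param query A single-row interval table.
#' @param genes A gene table (see [read_gene_table()]).
#' @param window Maximum distance in nucleotides (default 300 kb).
#' @param mode `"nearest"` or `"all"`.
#' @return A data.frame with columns `gene_id`, `distance` (possibly 0 rows),
#'   ordered by distance then gene id.
#' @export
nearest_within <- function(query, genes, window = 300000, mode = c("nearest", "all")) {
  mode <- match.arg(mode)
  stopifnot(window >= 0, nrow(query) == 1)
  empty <- data.frame(gene_id = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  g <- genes[genes$chrom == query$chrom, , drop = FALSE]
  if (!nrow(g)) return(empty)
  gap <- pmax(0, pmax(query$start, g$start) - pmin(query$end, g$end))
  keep <- gap <= window
  if (!any(keep)) return(empty)
  g <- g[keep, , drop = FALSE]
  gap <- gap[keep]
  if (mode == "nearest") {
    sel <- gap == min(gap)
    g <- g[sel, , drop = FALSE]
    gap <- gap[sel]
  }
  out <- data.frame(gene_id = g$gene_id, distance = gap,
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
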