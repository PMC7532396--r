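# Enhancer catalogue handling: merging the three source catalogues
# (DENDB / ENCODE / STARR), TSS-proximity classification, chromatin-state
# classification against open-chromatin regions, and the active-enhancer
# rule (open chromatin + high H3K27ac max-Z, plus low H3K4me3 max-Z when
# TSS-proximal).

SOURCE_LEVELS <- c("DENDB", "ENCODE", "STARR")

#' Read an enhancer BED file and tag its source
#'
#' Standard BED columns plus optional columns 7 and 8 holding the H3K27ac
#' and H3K4me3 max-Z scores ("." for missing).
#'
#' @param path File path.
#' @param source One of `"DENDB"`, `"ENCODE"`, `"STARR"`.
#' @return An enhancer data.frame with a `sources` column.
#' @export
read_enhancer_bed <- function(path, source) {
  source <- match.arg(source, SOURCE_LEVELS)
  e <- read_bed(path, extra_cols = c("h3k27ac_maxz", "h3k4me3_maxz"))
  e$sources <- source
  e
}

split_sources <- function(sources) strsplit(sources, ",", fixed = TRUE)

join_sources <- function(x) {
  paste(SOURCE_LEVELS[SOURCE_LEVELS %in% x], collapse = ",")
}

#' Merge the per-source enhancer catalogues
#'
#' Redundancy removal collapses coordinate-identical records (same
#' chromosome, start and end) into a single record whose `sources` is the
#' union; overlapping-but-not-identical records are retained as distinct
#' enhancers. Numeric annotation columns take the first non-missing value
#' among the collapsed records. Idempotent; output is coordinate-sorted.
#'
#' @param ... Enhancer data.frames (each with a `sources` column), or a
#'   single list of them.
#' @return The merged catalogue.
#' @export
merge_catalogs <- function(...) {
  cats <- list(...)
  if (length(cats) == 1 && is.data.frame(cats[[1]]) == FALSE) cats <- cats[[1]]
  cats <- Filter(function(x) !is.null(x) && nrow(x) > 0, cats)
  if (!length(cats)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), id = character(), strand = character(),
                      h3k27ac_maxz = numeric(), h3k4me3_maxz = numeric(),
                      sources = character(), stringsAsFactors = FALSE))
  }
  for (cat in cats) {
    if (is.null(cat$sources)) stop("each catalogue needs a 'sources' column")
  }
  all <- do.call(rbind, lapply(cats, function(x) {
    if (is.null(x$h3k27ac_maxz)) x$h3k27ac_maxz <- NA_real_
    if (is.null(x$h3k4me3_maxz)) x$h3k4me3_maxz <- NA_real_
    x[, c("chrom", "start", "end", "id", "strand",
          "h3k27ac_maxz", "h3k4me3_maxz", "sources")]
  }))
  key <- paste(all$chrom, all$start, all$end, sep = ":")
  first_of <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) v[1] else NA
  }
  idx <- split(seq_len(nrow(all)), key)
  merged <- do.call(rbind, lapply(idx, function(i) {
    rec <- all[i[1], , drop = FALSE]
    rec$sources <- join_sources(unique(unlist(split_sources(all$sources[i]))))
    rec$h3k27ac_maxz <- first_of(all$h3k27ac_maxz[i])
    rec$h3k4me3_maxz <- first_of(all$h3k4me3_maxz[i])
    rec$id <- sort(all$id[i])[1]
    rec
  }))
  merged <- merged[order(merged$chrom, merged$start, merged$end), , drop = FALSE]
  rownames(merged) <- NULL
  if (anyDuplicated(merged$id)) {
    stop("duplicate enhancer id across catalogues after merging; ",
         "ids must be unique within the merged catalogue")
  }
  merged
}

#' Classify enhancers as TSS-proximal or distal
#'
#' Proximal means the distance from the enhancer interval to the nearest
#' TSS is at most `tss_proximal` nucleotides (0 when a TSS lies inside the
#' enhancer); anything farther, including enhancers on chromosomes carrying
#' no TSS, is distal.
#'
#' @param enhancers Enhancer data.frame.
#' @param tss Data.frame with columns `chrom`, `tss` (0-based positions), as
#'   produced by [read_gene_table()].
#' @param tss_proximal Proximity bound in nucleotides (default 2000,
#'   inclusive).
#' @return Character vector, `"proximal"` or `"distal"`, one per enhancer.
#' @export
classify_proximity <- function(enhancers, tss, tss_proximal = 2000) {
  if (!nrow(tss)) stop("classify_proximity: empty TSS list")
  vapply(seq_len(nrow(enhancers)), function(i) {
    t <- tss[tss$chrom == enhancers$chrom[i], , drop = FALSE]
    if (!nrow(t)) return("distal")
    # a TSS is a 1-bp feature [tss, tss + 1)
    gap <- pmax(0, pmax(enhancers$start[i], t$tss) -
                     pmin(enhancers$end[i], t$tss + 1))
    if (min(gap) <= tss_proximal) "proximal" else "distal"
  }, character(1))
}

#' Classify enhancer chromatin state against open-chromatin regions
#'
#' Open means at least `min_overlap` (default 1) nucleotides shared with any
#' open region; everything else is closed.
#'
#' @param enhancers Enhancer data.frame.
#' @param open_regions Interval table of open-chromatin regions (e.g. DHS).
#' @param min_overlap Minimum shared nucleotides.
#' @return Character vector, `"open"` or `"closed"`.
#' @export
classify_chromatin_state <- function(enhancers, open_regions, min_overlap = 1L) {
  if (!nrow(enhancers)) return(character())
  if (is.null(open_regions) || !nrow(open_regions)) {
    return(rep("closed", nrow(enhancers)))
  }
  hits <- intersect_any(enhancers, open_regions, min_overlap = min_overlap)
  ifelse(enhancers$id %in% hits$query_id, "open", "closed")
}

#' Apply the active-enhancer rule
#'
#' An enhancer is active when it lies in open chromatin and has a high
#' H3K27ac max-Z; a TSS-proximal enhancer must in addition have a low
#' H3K4me3 max-Z. "High"/"low" are the `z_high`/`z_low` thresholds
#' (default 1.64, the one-sided 5% normal quantile; the source data carry
#' no stated cutoffs).
#'
#' @param enhancers Enhancer data.frame with `h3k27ac_maxz` (required) and
#'   `h3k4me3_maxz` (required for proximal enhancers).
#' @param open_regions Open-chromatin interval table.
#' @param tss TSS table (see [classify_proximity()]).
#' @param z_high H3K27ac max-Z at or above which the mark counts as high.
#' @param z_low H3K4me3 max-Z at or below which the mark counts as low.
#' @param tss_proximal Proximity bound in nucleotides.
#' @return The input with added/overwritten columns `tss_proximity`,
#'   `open_chromatin` (logical) and `active` (logical).
#' @export
classify_active <- function(enhancers, open_regions, tss,
                            z_high = 1.64, z_low = 1.64,
                            tss_proximal = 2000) {
  if (is.null(enhancers$h3k27ac_maxz) || anyNA(enhancers$h3k27ac_maxz)) {
    stop("classify_active: h3k27ac_maxz must be present for every enhancer")
  }
  prox <- classify_proximity(enhancers, tss, tss_proximal)
  if (any(prox == "proximal" & is.na(enhancers$h3k4me3_maxz))) {
    stop("classify_active: TSS-proximal enhancer with missing h3k4me3_maxz; ",
         "the low-H3K4me3 condition cannot be evaluated")
  }
  open <- classify_chromatin_state(enhancers, open_regions) == "open"
  high_k27 <- enhancers$h3k27ac_maxz >= z_high
  low_k4 <- prox == "distal" | enhancers$h3k4me3_maxz <= z_low
  enhancers$tss_proximity <- prox
  enhancers$open_chromatin <- open
  enhancers$active <- open & high_k27 & low_k4
  enhancers
}
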