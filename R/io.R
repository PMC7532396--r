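# Readers/writers for the tabular formats the pipeline consumes: BED (3-6
# col, plus optional histone max-Z columns for enhancers), tab-separated gene
# and probe annotation tables, expression matrices, sample sheets, GMT gene
# sets, motif-hit tables and BEDPE-like anchor pairs. All coordinates on disk
# are BED-convention 0-based half-open and are kept that way in memory.

split_fields <- function(path, comment = "#") {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, comment)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

bad_line <- function(path, lineno, why) {
  stop(sprintf("%s: line %d: %s", path, lineno, why), call. = FALSE)
}

#' Read a BED file (3-6 columns, optional extra numeric columns)
#'
#' Columns beyond the standard six are read by the names supplied in
#' `extra_cols` (numeric; `NA` allowed as "."). Features without a name
#' column get generated ids.
#'
#' @param path File path.
#' @param extra_cols Optional character vector naming columns 7, 8, ...
#' @return An interval data.frame (`chrom`, `start`, `end`, `id`, `strand`,
#'   plus any extras).
#' @export
read_bed <- function(path, extra_cols = character()) {
  p <- split_fields(path)
  n_extra <- length(extra_cols)
  rows <- vector("list", length(p$fields))
  for (i in seq_along(p$fields)) {
    f <- p$fields[[i]]
    if (length(f) < 3) bad_line(path, p$lineno[i], "fewer than 3 columns")
    st <- suppressWarnings(as.numeric(f[2]))
    en <- suppressWarnings(as.numeric(f[3]))
    if (is.na(st) || is.na(en)) {
      bad_line(path, p$lineno[i], "non-numeric start/end")
    }
    if (st < 0 || st >= en) {
      bad_line(path, p$lineno[i], "requires 0 <= start < end")
    }
    rows[[i]] <- f
  }
  nm <- vapply(rows, function(f) if (length(f) >= 4) f[4] else NA_character_,
               character(1))
  if (anyNA(nm)) nm[is.na(nm)] <- paste0("feature_", which(is.na(nm)))
  out <- data.frame(
    chrom = vapply(rows, `[`, character(1), 1),
    start = as.numeric(vapply(rows, `[`, character(1), 2)),
    end = as.numeric(vapply(rows, `[`, character(1), 3)),
    id = nm,
    strand = vapply(rows, function(f)
      if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*", character(1)),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n_extra)) {
    col <- 6L + j
    v <- vapply(rows, function(f)
      if (length(f) >= col) f[col] else ".", character(1))
    v[v == "."] <- NA_character_
    out[[extra_cols[j]]] <- suppressWarnings(as.numeric(v))
  }
  if (anyDuplicated(out$id)) {
    stop(path, ": duplicate feature id(s): ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }
  validate_intervals(out, path)
  out
}

#' Write an interval table as BED
#'
#' Writes `chrom`, `start`, `end`, `id`, a constant score of 0, `strand`,
#' then any columns named in `extra_cols` (NA as ".").
#'
#' @param df Interval data.frame.
#' @param path Output path.
#' @param extra_cols Extra column names to append after column 6.
#' @export
write_bed <- function(df, path, extra_cols = character()) {
  out <- data.frame(df$chrom, format_coord(df$start), format_coord(df$end),
                    df$id, 0L, df$strand, stringsAsFactors = FALSE)
  for (col in extra_cols) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- "."
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a tab-separated gene annotation table
#'
#' Expected header: `gene_id`, `chrom`, `start`, `end`, `strand`, `biotype`
#' (coding/noncoding). The TSS is derived from strand: `start` for `+`,
#' `end - 1` for `-`.
#'
#' @param path File path.
#' @return A data.frame with the input columns plus `tss` and `id`
#'   (duplicate of `gene_id`, so gene tables work as interval tables).
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  miss <- setdiff(req, names(g))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(g$gene_id)) stop(path, ": duplicate gene_id")
  g$id <- g$gene_id
  g$tss <- ifelse(g$strand == "-", g$end - 1, g$start)
  validate_intervals(g, path)
  if (any(g$tss < g$start | g$tss >= g$end)) stop(path, ": TSS outside gene")
  g
}

#' Read a probe annotation table
#'
#' Expected header: `probe_id`, `chrom`, `start`, `end`, `strand`,
#' `rna_class` (lncRNA/mRNA), `lnc_subclass` (lncRNAs only; "." otherwise)
#' and optionally `gene_id` linking mRNA probes to genes.
#'
#' @param path File path.
#' @return A data.frame; `lnc_subclass` is `NA` for mRNA probes and `id`
#'   duplicates `probe_id`.
#' @export
read_probe_table <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "chrom", "start", "end", "strand", "rna_class")
  miss <- setdiff(req, names(p))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(p$probe_id)) stop(path, ": duplicate probe_id")
  if (!all(p$rna_class %in% c("lncRNA", "mRNA"))) {
    stop(path, ": rna_class must be lncRNA or mRNA")
  }
  if (!is.null(p$lnc_subclass)) {
    p$lnc_subclass[p$lnc_subclass %in% c(".", "")] <- NA_character_
    if (any(p$rna_class == "mRNA" & !is.na(p$lnc_subclass))) {
      stop(path, ": lnc_subclass set on an mRNA probe")
    }
  }
  p$id <- p$probe_id
  validate_intervals(p, path)
  p
}

#' Read a probes x samples expression matrix
#'
#' Tab-separated; first column holds probe ids, header holds sample ids.
#'
#' @param path File path.
#' @return A numeric matrix with probe rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(m[[1]])) stop(path, ": duplicate probe id in matrix")
  rn <- m[[1]]
  m <- as.matrix(m[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric expression values")
  rownames(m) <- rn
  m
}

#' Write an expression matrix
#' @param m Numeric matrix (probes x samples).
#' @param path Output path.
#' @param id_col Name for the leading id column.
#' @export
write_matrix <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expected header: `sample_id`, `condition` (tumor/normal), `pair_id`.
#' The paired design is validated: every tumor pair id must match exactly
#' one normal sample.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(s, path)
  s
}

validate_sample_sheet <- function(s, what = "sample sheet") {
  req <- c("sample_id", "condition", "pair_id")
  miss <- setdiff(req, names(s))
  if (length(miss)) stop(what, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(s$condition %in% c("tumor", "normal"))) {
    stop(what, ": condition must be tumor or normal")
  }
  tum <- s$pair_id[s$condition == "tumor"]
  nor <- s$pair_id[s$condition == "normal"]
  if (anyDuplicated(tum) || anyDuplicated(nor) ||
      !setequal(tum, nor) || length(tum) != length(nor)) {
    stop(what, ": every tumor pair_id must match exactly one normal sample")
  }
  invisible(s)
}

#' Read a GMT gene-set file
#'
#' Each line: set id, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return A named list of character vectors; set descriptions are kept in
#'   the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  p <- split_fields(path)
  sets <- list()
  desc <- character()
  for (i in seq_along(p$fields)) {
    f <- p$fields[[i]]
    if (length(f) < 3) bad_line(path, p$lineno[i],
                                "GMT needs id, description, >=1 gene")
    if (f[1] %in% names(sets)) bad_line(path, p$lineno[i],
                                        paste0("duplicate set id ", f[1]))
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named descriptions (defaults to set ids).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(s)
    paste(c(s, description[[s]], sets[[s]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a motif-hit table (`tf_name`, `region_id`)
#' @param path File path.
#' @return A data.frame with unique (tf_name, region_id) rows.
#' @export
read_motif_hits <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("tf_name", "region_id"), names(h))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  unique(h[, c("tf_name", "region_id")])
}

#' Read chromatin-interaction anchor pairs
#'
#' BEDPE-like, tab-separated with header: `chrom_a`, `start_a`, `end_a`,
#' `chrom_b`, `start_b`, `end_b`, `assay` (3C/4C/5C/ChIA-PET/other).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_anchor_pairs <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")
  miss <- setdiff(req, names(a))
  if (length(miss)) stop(path, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(a$assay)) a$assay <- "other"
  if (nrow(a) && any(a$start_a < 0 | a$start_a >= a$end_a |
                     a$start_b < 0 | a$start_b >= a$end_b)) {
    stop(path, ": anchor coordinates must satisfy 0 <= start < end")
  }
  a
}

#' Write a generic tab-separated table
#' @param records A data.frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
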