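# End-to-end pipeline: threshold configuration, the run_study() driver
# chaining catalogue merging, eRNA/SE-lncRNA calling, differential
# expression, target assignment, enrichment and coordination-network
# construction, and a classed result object with print/summary methods.

#' Pipeline thresholds and mode flags
#'
#' Defaults are the workflow's published values: fold change >= 2 and raw
#' p < 0.05 for differential expression and enrichment, a 300 kb target
#' window, 2 kb promoters, the 2 kb TSS-proximity bound and the 1 nt
#' minimal overlap.
#'
#' @param fc_threshold Linear fold-change threshold (>= 1).
#' @param p_threshold Raw p-value threshold (0-1).
#' @param window Target-gene window in nucleotides.
#' @param promoter_length Promoter length in nucleotides.
#' @param tss_proximal TSS-proximity bound in nucleotides.
#' @param min_overlap Minimal calling overlap in nucleotides (>= 1).
#' @param z_high,z_low Active-enhancer max-Z thresholds.
#' @param pseudocount Added before log2 transformation.
#' @param mode Target assignment mode, `"nearest"` or `"all"`.
#' @param paired Use the paired t-test?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fc_threshold = 2, p_threshold = 0.05,
                            window = 300000, promoter_length = 2000,
                            tss_proximal = 2000, min_overlap = 1,
                            z_high = 1.64, z_low = 1.64, pseudocount = 1,
                            mode = c("nearest", "all"), paired = FALSE) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  num <- c("fc_threshold", "p_threshold", "window", "promoter_length",
           "tss_proximal", "min_overlap", "pseudocount")
  if (any(unlist(cfg[num]) <= 0)) {
    stop("pipeline_config: thresholds must be positive")
  }
  if (cfg$fc_threshold < 1) stop("pipeline_config: fc_threshold must be >= 1")
  if (cfg$p_threshold > 1) stop("pipeline_config: p_threshold must be <= 1")
  if (cfg$min_overlap < 1) stop("pipeline_config: min_overlap must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key-value pipeline configuration file
#'
#' YAML with one scalar per key; keys must be `pipeline_config()` argument
#' names. Values given in the file override the defaults.
#'
#' @param path Config file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop(path, ": unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Run the full identification and network pipeline on a file bundle
#'
#' Reads a study bundle (as written by [generate_study()] or assembled by
#' hand in the same formats), then chains: catalogue merge + active
#' classification, eRNA/SE-lncRNA calling, differential expression, target
#' assignment + DE-mRNA integration + concordance, gene-set
#' over-representation of the target genes, and coordination-network
#' construction with CTCF annotation.
#'
#' @param bundle Either the bundle directory (containing the standard file
#'   names written by [generate_study()]) or a named list/vector of file
#'   paths with the same names.
#' @param config A [pipeline_config()].
#' @param normalize Start from `expression_raw` with quantile
#'   normalisation + log2, instead of the provided log2 matrix?
#' @param outdir Optional directory for output tables and the run log.
#' @return An `erna_study` object: a list with the configuration and every
#'   stage's result table.
#' @export
run_study <- function(bundle, config = pipeline_config(), normalize = FALSE,
                      outdir = NULL) {
  files <- if (is.character(bundle) && length(bundle) == 1 &&
               dir.exists(bundle)) {
    fn <- c(genes = "genes.tsv", probes = "probes.tsv",
            dendb = "enhancers_dendb.bed", encode = "enhancers_encode.bed",
            starr = "enhancers_starr.bed",
            superenhancers = "superenhancers.bed",
            open_regions = "open_regions.bed",
            expression = "expression_log2.tsv",
            expression_raw = "expression_raw.tsv", samples = "samples.tsv",
            enhancer_hits = "motif_hits_enhancers.tsv",
            promoter_hits = "motif_hits_promoters.tsv",
            anchors = "anchors.tsv", ctcf = "ctcf_peaks.bed",
            gene_sets = "gene_sets.gmt")
    stats::setNames(file.path(bundle, fn), names(fn))
  } else {
    unlist(bundle)
  }
  need <- c("genes", "probes", "dendb", "encode", "starr", "expression",
            "samples")
  miss <- setdiff(need, names(files)[file.exists(files)])
  if (length(miss)) {
    stop("run_study: missing input(s): ", paste(miss, collapse = ", "))
  }
  have <- function(x) x %in% names(files) && file.exists(files[[x]])

  genes <- read_gene_table(files[["genes"]])
  probes <- read_probe_table(files[["probes"]])
  open_regions <- if (have("open_regions")) {
    read_bed(files[["open_regions"]])
  } else {
    NULL
  }

  catalogue <- merge_catalogs(
    read_enhancer_bed(files[["dendb"]], "DENDB"),
    read_enhancer_bed(files[["encode"]], "ENCODE"),
    read_enhancer_bed(files[["starr"]], "STARR")
  )
  catalogue$chromatin_state <- classify_chromatin_state(
    catalogue, open_regions, min_overlap = config$min_overlap
  )
  catalogue <- classify_active(
    catalogue, open_regions, genes, z_high = config$z_high,
    z_low = config$z_low, tss_proximal = config$tss_proximal
  )

  lnc <- probes[probes$rna_class == "lncRNA", , drop = FALSE]
  calls <- call_ernas(lnc, catalogue, min_overlap = config$min_overlap)
  se_calls <- if (have("superenhancers")) {
    call_se_lncrnas(lnc, read_bed(files[["superenhancers"]]),
                    min_overlap = config$min_overlap)
  } else {
    NULL
  }

  samples <- read_sample_sheet(files[["samples"]])
  m <- if (normalize) {
    raw <- read_matrix(files[["expression_raw"]])
    log2_transform(quantile_normalize(raw), pseudocount = config$pseudocount)
  } else {
    read_matrix(files[["expression"]])
  }
  de <- differential_expression(m, samples,
                                fc_threshold = config$fc_threshold,
                                p_threshold = config$p_threshold,
                                paired = config$paired)

  is_lnc <- de$probe_id %in% lnc$probe_id
  de_lnc <- de[is_lnc, , drop = FALSE]
  de_mrna <- de[!is_lnc, , drop = FALSE]
  de_mrna$gene_id <- probes$gene_id[match(de_mrna$probe_id, probes$probe_id)]
  de_erna <- de_lnc[de_lnc$significant &
                      de_lnc$probe_id %in% calls$probe_id, , drop = FALSE]
  de_se <- if (!is.null(se_calls)) {
    de_lnc[de_lnc$significant & de_lnc$probe_id %in% se_calls$probe_id, ,
           drop = FALSE]
  } else {
    NULL
  }

  erna_iv <- lnc[match(de_erna$probe_id, lnc$probe_id), , drop = FALSE]
  assigned <- assign_targets(erna_iv, genes, window = config$window,
                             mode = config$mode)
  pairs <- integrate_with_de_mrna(assigned$pairs, de_erna, de_mrna)
  concordance <- concordance_summary(pairs)

  enrichment <- if (have("gene_sets") && nrow(pairs)) {
    overrepresentation_test(unique(pairs$gene_id), genes$gene_id,
                            read_gmt(files[["gene_sets"]]),
                            p_threshold = config$p_threshold)
  } else {
    NULL
  }

  coords <- if (have("enhancer_hits") && have("promoter_hits") &&
                have("anchors") && nrow(pairs)) {
    cc <- build_coordinations(
      pairs, calls, catalogue, genes,
      read_motif_hits(files[["enhancer_hits"]]),
      read_motif_hits(files[["promoter_hits"]]),
      read_anchor_pairs(files[["anchors"]]),
      promoter_length = config$promoter_length
    )
    if (have("ctcf")) {
      cc <- ctcf_mediated(cc, read_bed(files[["ctcf"]]), catalogue, genes,
                          promoter_length = config$promoter_length)
    }
    cc
  } else {
    NULL
  }

  res <- structure(list(
    config = config,
    catalogue = catalogue,
    calls = calls,
    se_calls = se_calls,
    breakdown = source_breakdown(calls),
    de = de,
    de_erna = de_erna,
    de_se_lncrna = de_se,
    target_pairs = assigned$pairs,
    unassigned_ernas = assigned$unassigned,
    pairs = pairs,
    concordance = concordance,
    enrichment = enrichment,
    coordinations = coords,
    degrees = if (!is.null(coords)) node_degrees(coords) else NULL
  ), class = "erna_study")

  if (!is.null(outdir)) write_study_outputs(res, outdir)
  res
}

write_study_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_table(res$calls, p("erna_calls.tsv"))
  if (!is.null(res$se_calls)) write_table(res$se_calls, p("se_lncrna_calls.tsv"))
  write_table(res$breakdown, p("source_breakdown.tsv"))
  write_table(res$de, p("differential_expression.tsv"))
  write_table(res$pairs, p("erna_target_pairs.tsv"))
  if (!is.null(res$enrichment)) write_table(res$enrichment, p("enrichment.tsv"))
  if (!is.null(res$coordinations)) {
    write_table(res$coordinations, p("coordinations.tsv"))
    export_network(res$coordinations, p("network.sif"), format = "sif")
  }
  writeLines(c(
    paste0("ernanet ", as.character(utils::packageVersion("ernanet"))),
    paste0("R ", R.version.string),
    paste0("date ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0(names(unclass(res$config)), " = ",
           vapply(unclass(res$config), function(x)
             paste(as.character(x), collapse = ","), character(1)))
  ), p("run_log.txt"))
  invisible(outdir)
}

#' @export
print.erna_study <- function(x, ...) {
  cat("eRNA regulatory-network study\n")
  cat(sprintf("  enhancer catalogue: %d records (%d active)\n",
              nrow(x$catalogue), sum(x$catalogue$active)))
  cat(sprintf("  eRNAs called: %d (DENDB %d / ENCODE %d / STARR %d)\n",
              x$breakdown$total, x$breakdown$DENDB, x$breakdown$ENCODE,
              x$breakdown$STARR))
  if (!is.null(x$se_calls)) {
    cat(sprintf("  SE-lncRNAs called: %d\n", nrow(x$se_calls)))
  }
  cat(sprintf("  differentially expressed: %d probes (%d eRNAs%s)\n",
              sum(x$de$significant), nrow(x$de_erna),
              if (!is.null(x$de_se_lncrna)) {
                sprintf(", %d SE-lncRNAs", nrow(x$de_se_lncrna))
              } else {
                ""
              }))
  cat(sprintf("  eRNA-target pairs (gene DE): %d; concordant eRNAs %.1f%%\n",
              nrow(x$pairs), x$concordance$pct_ernas))
  if (!is.null(x$coordinations)) {
    cat(sprintf("  coordinations: %d (%d CTCF-mediated)\n",
                nrow(x$coordinations),
                sum(x$coordinations$ctcf_mediated, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.erna_study <- function(object, ...) {
  out <- list(
    breakdown = object$breakdown,
    n_de = sum(object$de$significant),
    n_de_erna = nrow(object$de_erna),
    n_de_se_lncrna = if (!is.null(object$de_se_lncrna)) {
      nrow(object$de_se_lncrna)
    } else {
      NA_integer_
    },
    concordance = object$concordance,
    n_coordinations = if (!is.null(object$coordinations)) {
      nrow(object$coordinations)
    } else {
      NA_integer_
    },
    n_ctcf_mediated = if (!is.null(object$coordinations)) {
      sum(object$coordinations$ctcf_mediated, na.rm = TRUE)
    } else {
      NA_integer_
    },
    top_enhancers = if (!is.null(object$degrees)) {
      utils::head(object$degrees[object$degrees$role == "enhancer", ], 5)
    } else {
      NULL
    }
  )
  class(out) <- "summary.erna_study"
  out
}

#' @export
print.summary.erna_study <- function(x, ...) {
  cat("Source breakdown (calls per source; total = distinct calls):\n")
  print(x$breakdown)
  cat(sprintf("\nDE probes: %d | DE eRNAs: %d | DE SE-lncRNAs: %s\n",
              x$n_de, x$n_de_erna, x$n_de_se_lncrna))
  cat("\nConcordance:\n")
  print(x$concordance)
  cat(sprintf("\nCoordinations: %s (%s CTCF-mediated)\n",
              x$n_coordinations, x$n_ctcf_mediated))
  if (!is.null(x$top_enhancers) && nrow(x$top_enhancers)) {
    cat("\nTop enhancers by degree:\n")
    print(x$top_enhancers)
  }
  invisible(x)
}
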