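# Shared fixtures: interval makers, brute-force oracles, a down-scaled
# simulation config for fast per-module tests, and memoised study bundles
# so the default synthetic study is generated (and run) once per session.

iv <- function(chrom, start, end, id = NULL, strand = "*") {
  genomic_intervals(chrom, start, end, id = id, strand = strand)
}

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                           max_len = 300, prefix = "x") {
  start <- sample.int(max_pos, n, replace = TRUE)
  iv(sample(chroms, n, replace = TRUE), start,
     start + sample.int(max_len, n, replace = TRUE),
     id = paste0(prefix, seq_len(n)))
}

# O(n*m) all-pairs overlap oracle
brute_pairs <- function(queries, subjects, min_overlap = 1) {
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    for (j in seq_len(nrow(subjects))) {
      ov <- if (queries$chrom[i] == subjects$chrom[j]) {
        max(0, min(queries$end[i], subjects$end[j]) -
              max(queries$start[i], subjects$start[j]))
      } else {
        0
      }
      if (ov >= min_overlap) {
        rows[[length(rows) + 1]] <- data.frame(
          query_id = queries$id[i], subject_id = subjects$id[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force distance scan oracle for nearest_within
brute_nearest <- function(query, genes, window, mode = "nearest") {
  d <- numeric(0)
  ids <- character(0)
  for (j in seq_len(nrow(genes))) {
    if (genes$chrom[j] != query$chrom) next
    gap <- max(0, max(query$start, genes$start[j]) -
                  min(query$end, genes$end[j]))
    if (gap <= window) {
      d <- c(d, gap)
      ids <- c(ids, genes$gene_id[j])
    }
  }
  if (!length(ids)) {
    return(data.frame(gene_id = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (mode == "nearest") {
    keep <- d == min(d)
    ids <- ids[keep]
    d <- d[keep]
  }
  o <- order(d, ids)
  data.frame(gene_id = ids[o], distance = d[o], stringsAsFactors = FALSE)
}

# textbook pooled-variance two-sample Student's t
t_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, df = nx + ny - 2,
       p = 2 * stats::pt(-abs(tstat), nx + ny - 2))
}

# exact hypergeometric upper tail by enumeration of the pmf
hyper_oracle <- function(k, K, N, n) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# small, fast study for per-module tests (all planted classes represented);
# `...` overrides any default, including the ones set here
tiny_config <- function(...) {
  args <- list(
    seed = 42, n_genes = 80, n_lncrna_probes = 200, n_mrna_probes = 80,
    n_enhancers = c(DENDB = 40, ENCODE = 16, STARR = 16),
    planted_by_source = c(DENDB = 24, ENCODE = 8, STARR = 8),
    n_duplicate = 3, n_superenhancers = 12, n_planted_se = 10,
    n_target_units = 16, n_discordant = 4, n_coordinations = 8,
    n_ctcf_mediated = 3, n_ctcf_enhancer_only = 2,
    n_decoy_no_anchor = 2, n_decoy_no_motif = 2, n_decoy_adjacent = 6,
    n_decoy_outwindow = 2, n_de_se_lncrnas = 4
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

.bundle_cache <- new.env(parent = emptyenv())

# memoised generate_study: one bundle per (name) per session
study_bundle <- function(name = "default",
                         config = simulation_config(seed = 42)) {
  if (is.null(.bundle_cache[[name]])) {
    dir <- file.path(tempdir(), paste0("ernanet_bundle_", name))
    .bundle_cache[[name]] <- generate_study(config, dir)
  }
  .bundle_cache[[name]]
}

# memoised run_study over a named bundle
study_result <- function(name = "default", ...) {
  key <- paste0("run_", name)
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <- run_study(study_bundle(name, ...)$dir)
  }
  .bundle_cache[[key]]
}

coord_key <- function(d) {
  paste(d$enhancer_id, d$erna_probe_id, d$tf_name, d$gene_id)
}

pair_key <- function(d) paste(d$probe_id, d$gene_id)
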