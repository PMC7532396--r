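# Seeded generator of a complete toy study with planted ground truth:
# genome layout, gene and probe annotation, per-source enhancer catalogues,
# superenhancers, open-chromatin regions, a paired tumour/normal expression
# matrix with planted log2 effects, motif hits, interaction anchors, CTCF
# peaks and gene sets. The genomic layout is a deterministic grid (genes
# every `gene_spacing` nt; planted structures in designated intergenic
# slots) so the deterministic calling rules recover the planted truth
# exactly; only expression noise is random, driven by the seed.
#
# Slot map of the 16 kb gap downstream of gene i (ge = gene end):
#   odd i:        eRNA unit   enhancer [ge+4000, ge+5000), probe inside
#   i %% 4 == 2:  SE unit     superenhancer [ge+4000, ge+9000), probe inside
#   i %% 4 == 0:  fillers     enhancers [ge+6000, ge+6800) / [ge+8000,
#                             ge+8800), adjacency-decoy probe book-ended
#   all i:        null probes 4 slots from ge+10500, 1 kb apart, 900 nt
# Out-of-window decoys live in a gene desert at the end of the last
# chromosome, > 300 kb from every gene.

#' Configuration for the synthetic study generator
#'
#' Defaults give a study of 2 chromosomes x 10 Mb, 1000 genes, 4000 lncRNA
#' and 1000 mRNA probes, 3 tumour/normal sample pairs, 500 planted eRNAs
#' (400/50/50 across DENDB/ENCODE/STARR), 100 planted SE-lncRNAs, 120
#' planted eRNA-target pairs carrying a +/-2 log2 differential-expression
#' effect (20 of them discordant), 50 planted coordinations of which 20 are
#' CTCF-mediated, and decoys for every rule: book-ended probes with zero
#' overlap, differentially expressed eRNAs with no gene within the window,
#' motif-sharing pairs without interaction anchors, anchored pairs without
#' shared motifs, and CTCF peaks at the enhancer only.
#'
#' @param seed Integer RNG seed; drives all expression noise.
#' @param n_genes Number of genes (grid-placed, alternating strand).
#' @param gene_spacing Distance between gene starts in nucleotides.
#' @param n_lncrna_probes,n_mrna_probes Probe counts; mRNA probes cover the
#'   first `n_mrna_probes` genes.
#' @param n_enhancers Named total enhancer counts per source.
#' @param planted_by_source Named counts of planted eRNA units per source.
#' @param n_duplicate Filler enhancers emitted identically in both the
#'   DENDB and ENCODE catalogues (cross-source redundancy).
#' @param open_fraction Fraction of enhancers per source placed in open
#'   chromatin.
#' @param n_superenhancers Superenhancer count (first `n_planted_se` host a
#'   probe).
#' @param n_planted_se Planted SE-lncRNA count.
#' @param n_pairs Tumour/normal sample pairs.
#' @param baseline_mean,baseline_sd Per-probe baseline log2 signal.
#' @param noise_sd Per-sample log2 noise.
#' @param de_effect Planted log2 effect in tumours (0 for a null study).
#' @param open_boost Log2 baseline boost for eRNA probes over open STARR
#'   enhancers.
#' @param n_target_units Planted eRNA units that also carry a
#'   differentially expressed target gene.
#' @param n_discordant Target units whose gene effect has the opposite
#'   direction.
#' @param n_coordinations Target units with planted shared motif + anchor.
#' @param n_ctcf_mediated Coordinations with CTCF peaks at both ends.
#' @param n_ctcf_enhancer_only Coordinations with a CTCF peak at the
#'   enhancer only (must stay unmediated).
#' @param n_decoy_no_anchor Target units with shared motifs but no anchor.
#' @param n_decoy_no_motif Target units with an anchor but no shared motif.
#' @param n_decoy_adjacent Probes book-ended to a filler enhancer.
#' @param n_decoy_outwindow Differentially expressed eRNAs in the gene
#'   desert (no gene within the window).
#' @param n_de_se_lncrnas SE-lncRNA probes given the planted effect.
#' @param n_tfs Distinct planted transcription factors.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 42,
                              n_genes = 1000,
                              gene_spacing = 18000,
                              n_lncrna_probes = 4000,
                              n_mrna_probes = 1000,
                              n_enhancers = c(DENDB = 500, ENCODE = 150,
                                              STARR = 150),
                              planted_by_source = c(DENDB = 400, ENCODE = 50,
                                                    STARR = 50),
                              n_duplicate = 15,
                              open_fraction = 0.5,
                              n_superenhancers = 110,
                              n_planted_se = 100,
                              n_pairs = 3,
                              baseline_mean = 6,
                              baseline_sd = 1,
                              noise_sd = 0.3,
                              de_effect = 2,
                              open_boost = 1,
                              n_target_units = 120,
                              n_discordant = 20,
                              n_coordinations = 50,
                              n_ctcf_mediated = 20,
                              n_ctcf_enhancer_only = 10,
                              n_decoy_no_anchor = 10,
                              n_decoy_no_motif = 10,
                              n_decoy_adjacent = 50,
                              n_decoy_outwindow = 5,
                              n_de_se_lncrnas = 30,
                              n_tfs = 8) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  must <- function(ok, why) if (!ok) stop("simulation_config: ", why,
                                          call. = FALSE)
  counts <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  must(all(counts >= 0), "all counts must be >= 0")
  must(all(c("DENDB", "ENCODE", "STARR") %in% names(cfg$n_enhancers)),
       "n_enhancers needs DENDB, ENCODE, STARR")
  n_planted <- sum(cfg$planted_by_source)
  must(n_planted <= ceiling(cfg$n_genes / 2),
       "more planted eRNA units than odd-gene slots")
  must(all(cfg$planted_by_source <= cfg$n_enhancers[names(cfg$planted_by_source)]),
       "planted enhancers exceed per-source totals")
  fillers <- sum(cfg$n_enhancers) - n_planted - cfg$n_decoy_outwindow
  must(fillers <= 2 * floor(cfg$n_genes / 4),
       "more filler enhancers than filler slots")
  must(cfg$n_duplicate <= cfg$n_enhancers[["ENCODE"]] -
         cfg$planted_by_source[["ENCODE"]],
       "n_duplicate exceeds ENCODE filler budget")
  must(cfg$n_target_units <= n_planted,
       "n_target_units exceeds planted eRNA units")
  must(2 * cfg$n_target_units - 1 <= cfg$n_mrna_probes,
       "target-unit genes must carry mRNA probes (raise n_mrna_probes)")
  must(cfg$n_discordant <= cfg$n_target_units,
       "n_discordant exceeds n_target_units")
  must(cfg$n_coordinations + cfg$n_decoy_no_anchor + cfg$n_decoy_no_motif <=
         cfg$n_target_units,
       "coordination + motif/anchor decoy units exceed n_target_units")
  must(cfg$n_ctcf_mediated + cfg$n_ctcf_enhancer_only <= cfg$n_coordinations,
       "CTCF subsets exceed n_coordinations")
  must(cfg$n_planted_se <= floor(cfg$n_genes / 4),
       "more SE units than SE slots")
  must(cfg$n_planted_se <= cfg$n_superenhancers,
       "n_planted_se exceeds n_superenhancers")
  must(cfg$n_de_se_lncrnas <= cfg$n_planted_se,
       "n_de_se_lncrnas exceeds n_planted_se")
  must(cfg$n_decoy_adjacent <= 2 * floor(cfg$n_genes / 4),
       "more adjacency decoys than filler enhancers")
  n_special <- n_planted + cfg$n_planted_se + cfg$n_decoy_adjacent +
    cfg$n_decoy_outwindow
  must(n_special <= cfg$n_lncrna_probes,
       "n_lncrna_probes too small for the planted probes")
  must(cfg$n_lncrna_probes - n_special <= 4 * cfg$n_genes,
       "too many null probes for the null slots")
  must(cfg$n_mrna_probes <= cfg$n_genes, "n_mrna_probes exceeds n_genes")
  must(cfg$n_pairs >= 2, "need >= 2 sample pairs for the t-test")
  invisible(cfg)
}

#' Generate the synthetic study bundle
#'
#' Writes every input file the pipeline reads, plus `ground_truth.json` and
#' the resolved `config.yaml`, into `outdir`. Identical (config, seed)
#' yield byte-identical bundles.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `files` (named paths),
#'   `ground_truth` and `config`.
#' @export
generate_study <- function(config = simulation_config(), outdir) {
  validate_config(config)
  cfg <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  ## --- genome and genes ------------------------------------------------
  per_chrom <- ceiling(cfg$n_genes / 2)
  desert <- 1e6
  chrom_len <- per_chrom * cfg$gene_spacing + desert
  gene_len <- 2000
  i <- seq_len(cfg$n_genes)
  chrom <- ifelse(i <= per_chrom, "chr1", "chr2")
  within <- ifelse(i <= per_chrom, i, i - per_chrom)
  gstart <- (within - 1) * cfg$gene_spacing + 1000
  gend <- gstart + gene_len
  strand <- ifelse(i %% 4 %in% c(1, 2), "+", "-")
  genes <- data.frame(
    gene_id = sprintf("G%04d", i), chrom = chrom, start = gstart,
    end = gend, strand = strand, biotype = "coding",
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(strand == "-", gend - 1, gstart)
  genes$id <- genes$gene_id

  slot <- function(idx, off, len) {
    data.frame(chrom = genes$chrom[idx], start = genes$end[idx] + off,
               end = genes$end[idx] + off + len, stringsAsFactors = FALSE)
  }

  ## --- planted eRNA units ---------------------------------------------
  n_planted <- sum(cfg$planted_by_source)
  k <- seq_len(n_planted)
  unit_gene <- 2 * k - 1
  enh <- slot(unit_gene, 4000, 1000)
  unit_src <- rep(names(cfg$planted_by_source), cfg$planted_by_source)
  enh$id <- sprintf("%s_enh_U%03d", unit_src, k)
  enh$sources_tag <- unit_src
  # every 10th unit probe overlaps its enhancer by exactly 1 nt
  one_nt <- k %% 10 == 0
  probe_start <- ifelse(one_nt, enh$start + 999, enh$start + 500)
  unit_probes <- data.frame(
    probe_id = sprintf("PL_U%03d", k), chrom = enh$chrom,
    start = probe_start, end = probe_start + 900, stringsAsFactors = FALSE
  )

  ## --- superenhancer units ---------------------------------------------
  se_slots <- which(i %% 4 == 2)
  se_n <- cfg$n_superenhancers
  se_idx <- se_slots[seq_len(min(se_n, length(se_slots)))]
  if (length(se_idx) < se_n) stop("simulation_config: not enough SE slots")
  se <- slot(se_idx, 4000, 5000)
  se$id <- sprintf("SE%03d", seq_len(se_n))
  sp <- seq_len(cfg$n_planted_se)
  se_probes <- data.frame(
    probe_id = sprintf("PL_S%03d", sp), chrom = se$chrom[sp],
    start = se$start[sp] + 2000, end = se$start[sp] + 2900,
    stringsAsFactors = FALSE
  )

  ## --- filler enhancers and adjacency decoys ---------------------------
  filler_need <- cfg$n_enhancers - cfg$planted_by_source
  filler_need[["DENDB"]] <- filler_need[["DENDB"]] - cfg$n_decoy_outwindow
  filler_need[["ENCODE"]] <- filler_need[["ENCODE"]] - cfg$n_duplicate
  filler_slots <- which(i %% 4 == 0)
  n_fill <- sum(filler_need)
  f <- seq_len(n_fill)
  f_gene <- filler_slots[(f - 1) %% length(filler_slots) + 1]
  f_off <- ifelse((f - 1) %/% length(filler_slots) == 0, 8000, 6000)
  fill <- slot(f_gene, 0, 1)  # placeholder, replaced below
  fill$start <- genes$end[f_gene] + f_off
  fill$end <- fill$start + 800
  fill_src <- rep(names(filler_need), filler_need)
  fill$id <- sprintf("%s_enh_F%03d", fill_src, f)
  fill$sources_tag <- fill_src
  # duplicates: first n_duplicate DENDB fillers re-emitted as ENCODE records
  dup_of <- which(fill_src == "DENDB")[seq_len(cfg$n_duplicate)]
  dup <- fill[dup_of, , drop = FALSE]
  if (nrow(dup)) {
    dup$id <- sub("^DENDB", "ENCODE_dup", dup$id)
    dup$sources_tag <- "ENCODE"
  }
  adj <- seq_len(cfg$n_decoy_adjacent)
  adj_probes <- data.frame(
    probe_id = sprintf("PL_A%03d", adj), chrom = fill$chrom[adj],
    start = fill$end[adj], end = fill$end[adj] + 900,
    stringsAsFactors = FALSE
  )

  ## --- out-of-window decoys (gene desert on the last chromosome) -------
  w <- seq_len(cfg$n_decoy_outwindow)
  desert_start <- per_chrom * cfg$gene_spacing + 550000
  ow_enh <- data.frame(
    chrom = "chr2", start = desert_start + (w - 1) * 20000,
    end = desert_start + (w - 1) * 20000 + 1000,
    id = sprintf("DENDB_enh_W%03d", w), sources_tag = "DENDB",
    stringsAsFactors = FALSE
  )
  ow_probes <- data.frame(
    probe_id = sprintf("PL_W%03d", w), chrom = ow_enh$chrom,
    start = ow_enh$start + 500, end = ow_enh$start + 1400,
    stringsAsFactors = FALSE
  )
  if (cfg$n_decoy_outwindow > 0 &&
      min(ow_enh$start) - max(genes$end[genes$chrom == "chr2"]) <= 300000) {
    stop("simulation_config: desert decoys closer than 300 kb to a gene")
  }

  ## --- assemble enhancer catalogues ------------------------------------
  all_enh <- rbind(enh[, c("chrom", "start", "end", "id", "sources_tag")],
                   fill[, c("chrom", "start", "end", "id", "sources_tag")],
                   dup[, c("chrom", "start", "end", "id", "sources_tag")],
                   ow_enh[, c("chrom", "start", "end", "id", "sources_tag")])
  all_enh$strand <- "*"
  # open/closed designation per source, interleaved for determinism
  open_flag <- logical(nrow(all_enh))
  for (s in names(cfg$n_enhancers)) {
    rows <- which(all_enh$sources_tag == s)
    n_open <- round(cfg$open_fraction * length(rows))
    open_flag[rows[seq_len(n_open)]] <- TRUE
  }
  all_enh$open <- open_flag
  all_enh$h3k27ac_maxz <- ifelse(open_flag, 3.0, 0.8)
  all_enh$h3k4me3_maxz <- 0.3

  ## --- null probes ------------------------------------------------------
  n_special <- n_planted + cfg$n_planted_se + cfg$n_decoy_adjacent +
    cfg$n_decoy_outwindow
  n_null <- cfg$n_lncrna_probes - n_special
  q <- seq_len(n_null)
  null_gene <- (q - 1) %% cfg$n_genes + 1
  null_slot <- (q - 1) %/% cfg$n_genes
  null_probes <- data.frame(
    probe_id = sprintf("PL_N%04d", q), chrom = genes$chrom[null_gene],
    start = genes$end[null_gene] + 10500 + 1000 * null_slot,
    end = genes$end[null_gene] + 10500 + 1000 * null_slot + 900,
    stringsAsFactors = FALSE
  )

  subclasses <- c("exonic_sense", "exonic_antisense", "intronic_sense",
                  "intronic_antisense", "intergenic", "other")
  lnc <- rbind(unit_probes, se_probes, adj_probes, ow_probes, null_probes)
  lnc$strand <- rep_len(c("+", "-"), nrow(lnc))
  lnc$rna_class <- "lncRNA"
  lnc$lnc_subclass <- rep_len(subclasses, nrow(lnc))
  lnc$gene_id <- NA_character_
  mi <- seq_len(cfg$n_mrna_probes)
  mrna <- data.frame(
    probe_id = paste0("PM_", genes$gene_id[mi]), chrom = genes$chrom[mi],
    start = genes$start[mi], end = genes$end[mi], strand = genes$strand[mi],
    rna_class = "mRNA", lnc_subclass = NA_character_,
    gene_id = genes$gene_id[mi], stringsAsFactors = FALSE
  )
  probes <- rbind(lnc, mrna)
  probes$id <- probes$probe_id

  ## --- planted differential expression ---------------------------------
  t_units <- seq_len(cfg$n_target_units)
  erna_dir <- ifelse(t_units %% 2 == 1, "up", "down")
  concordant <- t_units <= cfg$n_target_units - cfg$n_discordant
  gene_dir <- ifelse(concordant, erna_dir,
                     ifelse(erna_dir == "up", "down", "up"))
  de <- rbind(
    data.frame(probe_id = sprintf("PL_U%03d", t_units), direction = erna_dir,
               stringsAsFactors = FALSE),
    data.frame(probe_id = paste0("PM_", genes$gene_id[2 * t_units - 1]),
               direction = gene_dir, stringsAsFactors = FALSE),
    data.frame(probe_id = ow_probes$probe_id,
               direction = rep_len("up", nrow(ow_probes)),
               stringsAsFactors = FALSE),
    data.frame(probe_id = sprintf("PL_S%03d", seq_len(cfg$n_de_se_lncrnas)),
               direction = rep_len("up", cfg$n_de_se_lncrnas),
               stringsAsFactors = FALSE)
  )

  ## --- expression matrix ------------------------------------------------
  n_s <- 2 * cfg$n_pairs
  samp <- data.frame(
    sample_id = c(paste0("T", seq_len(cfg$n_pairs)),
                  paste0("N", seq_len(cfg$n_pairs))),
    condition = rep(c("tumor", "normal"), each = cfg$n_pairs),
    pair_id = rep(paste0("P", seq_len(cfg$n_pairs)), 2),
    stringsAsFactors = FALSE
  )
  baseline <- stats::rnorm(nrow(probes), cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- probes$probe_id
  # open-chromatin STARR eRNA probes sit higher on average
  starr_open <- enh$id[unit_src == "STARR" &
                         all_enh$open[match(enh$id, all_enh$id)]]
  boost_probes <- sprintf("PL_U%03d", k[enh$id %in% starr_open])
  baseline[boost_probes] <- baseline[boost_probes] + cfg$open_boost
  sig <- matrix(baseline, nrow = nrow(probes), ncol = n_s) +
    matrix(stats::rnorm(nrow(probes) * n_s, 0, cfg$noise_sd),
           nrow = nrow(probes))
  dimnames(sig) <- list(probes$probe_id, samp$sample_id)
  shift <- ifelse(de$direction == "up", cfg$de_effect, -cfg$de_effect)
  tum_cols <- samp$sample_id[samp$condition == "tumor"]
  sig[de$probe_id, tum_cols] <- sig[de$probe_id, tum_cols] + shift
  sig <- round(sig, 6)
  raw <- round(2^sig - 1, 6)

  ## --- motif hits, anchors, CTCF ---------------------------------------
  c_units <- seq_len(cfg$n_coordinations)
  na_units <- cfg$n_coordinations + seq_len(cfg$n_decoy_no_anchor)
  nm_units <- cfg$n_coordinations + cfg$n_decoy_no_anchor +
    seq_len(cfg$n_decoy_no_motif)
  tf_of <- function(u) sprintf("TF%02d", (u - 1) %% cfg$n_tfs + 1)
  unit_enh_id <- enh$id
  unit_gene_id <- genes$gene_id[unit_gene]
  enh_hits <- rbind(
    data.frame(tf_name = tf_of(c(c_units, na_units)),
               region_id = unit_enh_id[c(c_units, na_units)],
               stringsAsFactors = FALSE),
    # enhancer-only TF: never on a promoter, creates no coordination
    data.frame(tf_name = "TFY",
               region_id = unit_enh_id[c(c_units, nm_units)],
               stringsAsFactors = FALSE)
  )
  pro_hits <- rbind(
    data.frame(tf_name = tf_of(c(c_units, na_units)),
               region_id = unit_gene_id[c(c_units, na_units)],
               stringsAsFactors = FALSE),
    data.frame(tf_name = "TFX",
               region_id = unit_gene_id[c(c_units, nm_units)],
               stringsAsFactors = FALSE)
  )
  promoters <- promoter_region(genes)
  anchor_units <- c(c_units, nm_units)
  ae <- enh[anchor_units, , drop = FALSE]
  ap <- promoters[match(unit_gene_id[anchor_units], promoters$gene_id), ,
                  drop = FALSE]
  swap <- anchor_units %% 2 == 0
  anchors <- data.frame(
    chrom_a = ifelse(swap, ap$chrom, ae$chrom),
    start_a = ifelse(swap, ap$start, ae$start - 50),
    end_a = ifelse(swap, ap$start + 200, ae$end + 50),
    chrom_b = ifelse(swap, ae$chrom, ap$chrom),
    start_b = ifelse(swap, ae$start - 50, ap$start),
    end_b = ifelse(swap, ae$end + 50, ap$start + 200),
    assay = rep_len(c("3C", "4C", "5C", "ChIA-PET"), length(anchor_units)),
    stringsAsFactors = FALSE
  )
  # noise anchors in the chr1 desert: linked to nothing
  noise_a <- data.frame(
    chrom_a = "chr1", start_a = desert_start + (0:4) * 10000,
    end_a = desert_start + (0:4) * 10000 + 500,
    chrom_b = "chr1", start_b = desert_start + (0:4) * 10000 + 5000,
    end_b = desert_start + (0:4) * 10000 + 5500,
    assay = "other", stringsAsFactors = FALSE
  )
  anchors <- rbind(anchors, noise_a)

  ctcf_units <- seq_len(cfg$n_ctcf_mediated)
  ctcf_enh_only <- cfg$n_ctcf_mediated + seq_len(cfg$n_ctcf_enhancer_only)
  ce <- enh[c(ctcf_units, ctcf_enh_only), , drop = FALSE]
  cp <- promoters[match(unit_gene_id[ctcf_units], promoters$gene_id), ,
                  drop = FALSE]
  ctcf <- rbind(
    data.frame(chrom = ce$chrom, start = ce$start + 100, end = ce$start + 300,
               stringsAsFactors = FALSE),
    data.frame(chrom = cp$chrom, start = cp$start + 100, end = cp$start + 300,
               stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", start = desert_start + 100000 + (0:4) * 3000,
               end = desert_start + 100000 + (0:4) * 3000 + 200,
               stringsAsFactors = FALSE)
  )
  ctcf$id <- sprintf("ctcf_%03d", seq_len(nrow(ctcf)))
  ctcf$strand <- "*"

  ## --- gene sets ---------------------------------------------------------
  target_genes <- genes$gene_id[2 * t_units - 1]
  other_genes <- setdiff(genes$gene_id, target_genes)
  sets <- list(
    PLANTED_TARGETS = c(target_genes[seq_len(min(60, length(target_genes)))],
                        other_genes[seq_len(min(40, length(other_genes)))])
  )
  for (j in 1:5) {
    sets[[sprintf("RANDOM_SET_%d", j)]] <-
      sort(sample(genes$gene_id, 50))
  }

  ## --- open regions ------------------------------------------------------
  open_enh <- all_enh[all_enh$open, , drop = FALSE]
  open_regions <- data.frame(
    chrom = open_enh$chrom, start = pmax(0, open_enh$start - 100),
    end = open_enh$end + 100, id = paste0("open_", seq_len(nrow(open_enh))),
    strand = "*", stringsAsFactors = FALSE
  )

  ## --- ground truth -------------------------------------------------------
  pair_dist <- interval_distance(
    unit_probes[t_units, c("chrom", "start", "end")],
    genes[2 * t_units - 1, c("chrom", "start", "end")]
  )
  coord_gt <- data.frame(
    enhancer_id = unit_enh_id[c_units],
    erna_probe_id = sprintf("PL_U%03d", c_units),
    tf_name = tf_of(c_units),
    gene_id = unit_gene_id[c_units],
    ctcf_mediated = c_units %in% ctcf_units,
    stringsAsFactors = FALSE
  )
  ground_truth <- list(
    erna_probes = data.frame(
      probe_id = c(unit_probes$probe_id, ow_probes$probe_id),
      source = c(unit_src, ow_enh$sources_tag), stringsAsFactors = FALSE
    ),
    se_lncrna_probes = se_probes$probe_id,
    de_probes = de,
    target_pairs = data.frame(
      probe_id = sprintf("PL_U%03d", t_units),
      gene_id = genes$gene_id[2 * t_units - 1],
      distance = pair_dist, concordant = concordant,
      stringsAsFactors = FALSE
    ),
    coordinations = coord_gt,
    decoys = list(
      adjacent_probes = adj_probes$probe_id,
      outwindow_probes = ow_probes$probe_id,
      no_anchor_units = data.frame(
        probe_id = sprintf("PL_U%03d", na_units),
        gene_id = unit_gene_id[na_units], stringsAsFactors = FALSE
      ),
      no_motif_units = data.frame(
        probe_id = sprintf("PL_U%03d", nm_units),
        gene_id = unit_gene_id[nm_units], stringsAsFactors = FALSE
      ),
      ctcf_enhancer_only = coord_gt$erna_probe_id[integer(0)]
    )
  )
  ground_truth$decoys$ctcf_enhancer_only <- sprintf("PL_U%03d", ctcf_enh_only)

  ## --- write bundle --------------------------------------------------------
  path <- function(f) file.path(outdir, f)
  files <- c(
    genes = "genes.tsv", probes = "probes.tsv",
    dendb = "enhancers_dendb.bed", encode = "enhancers_encode.bed",
    starr = "enhancers_starr.bed", superenhancers = "superenhancers.bed",
    open_regions = "open_regions.bed", expression = "expression_log2.tsv",
    expression_raw = "expression_raw.tsv", samples = "samples.tsv",
    enhancer_hits = "motif_hits_enhancers.tsv",
    promoter_hits = "motif_hits_promoters.tsv", anchors = "anchors.tsv",
    ctcf = "ctcf_peaks.bed", gene_sets = "gene_sets.gmt",
    ground_truth = "ground_truth.json", config = "config.yaml"
  )
  files <- stats::setNames(vapply(files, path, character(1)), names(files))
  write_table(genes[, c("gene_id", "chrom", "start", "end", "strand",
                        "biotype")], files[["genes"]])
  write_table(probes[, c("probe_id", "chrom", "start", "end", "strand",
                         "rna_class", "lnc_subclass", "gene_id")],
              files[["probes"]])
  for (s in c("DENDB", "ENCODE", "STARR")) {
    sub <- all_enh[all_enh$sources_tag == s, , drop = FALSE]
    write_bed(sub, files[[c(DENDB = "dendb", ENCODE = "encode",
                            STARR = "starr")[[s]]]],
              extra_cols = c("h3k27ac_maxz", "h3k4me3_maxz"))
  }
  se$strand <- "*"
  write_bed(se, files[["superenhancers"]])
  write_bed(open_regions, files[["open_regions"]])
  write_bed(ctcf, files[["ctcf"]])
  write_matrix(sig, files[["expression"]])
  write_matrix(raw, files[["expression_raw"]])
  write_table(samp, files[["samples"]])
  write_table(enh_hits, files[["enhancer_hits"]])
  write_table(pro_hits, files[["promoter_hits"]])
  write_table(anchors, files[["anchors"]])
  write_gmt(sets, files[["gene_sets"]])
  jsonlite::write_json(ground_truth, files[["ground_truth"]],
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_out <- unclass(cfg)
  cfg_out$n_enhancers <- as.list(cfg_out$n_enhancers)
  cfg_out$planted_by_source <- as.list(cfg_out$planted_by_source)
  yaml::write_yaml(cfg_out, files[["config"]])
  invisible(list(dir = outdir, files = files, ground_truth = ground_truth,
                 config = cfg))
}

#' Exact consensus-motif scan of a nucleotide sequence
#'
#' Fixture-level stand-in for a motif scanner: a motif hits when its
#' consensus string, or the reverse complement, occurs verbatim in the
#' sequence.
#'
#' @param sequence A string over A/C/G/T.
#' @param motifs Named character vector of consensus strings (names are TF
#'   names).
#' @param region_id Region identifier attached to the hits.
#' @return A motif-hit data.frame (`tf_name`, `region_id`), possibly empty.
#' @export
scan_consensus <- function(sequence, motifs, region_id = "seq1") {
  if (!length(motifs)) stop("scan_consensus: no motifs supplied")
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    stop("scan_consensus: motifs must be named by TF")
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("scan_consensus: sequence contains characters outside A/C/G/T")
  }
  seq <- Biostrings::DNAString(sequence)
  hit <- vapply(motifs, function(m) {
    if (grepl("[^ACGT]", m)) stop("scan_consensus: invalid motif ", m)
    fwd <- Biostrings::matchPattern(m, seq)
    rev <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(m)), seq
    )
    length(fwd) > 0 || length(rev) > 0
  }, logical(1))
  data.frame(tf_name = names(motifs)[hit],
             region_id = rep_len(region_id, sum(hit)),
             stringsAsFactors = FALSE)
}
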