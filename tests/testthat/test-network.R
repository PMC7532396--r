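# Coordination network: promoter geometry, motif sharing, interaction
# support, assembly of (enhancer, eRNA, TF, gene) quadruples, CTCF
# mediation, incidence degrees and SIF/GraphML export — including the
# published worked-example table of the two highest-degree enhancers.

mk_gene <- function(tss, strand, id = "g1", chrom = "chr1") {
  data.frame(gene_id = id, chrom = chrom,
             start = if (strand == "+") tss else tss - 1999,
             end = if (strand == "+") tss + 2000 else tss + 1,
             strand = strand, tss = tss, id = id, biotype = "coding",
             stringsAsFactors = FALSE)
}

fixture_coords <- function() {
  f <- system.file("extdata", "prostate_top_coordinations.tsv",
                   package = "ernanet")
  utils::read.delim(f, stringsAsFactors = FALSE)
}

test_that("promoter regions are strand-aware and clipped at the origin", {
  plus <- promoter_region(mk_gene(10000, "+"))
  expect_equal(c(plus$start, plus$end), c(8000, 10000))
  minus <- promoter_region(mk_gene(10000, "-"))
  expect_equal(c(minus$start, minus$end), c(10001, 12001))
  clipped <- promoter_region(mk_gene(500, "+"))
  expect_equal(c(clipped$start, clipped$end), c(0, 500))
  expect_equal(promoter_region(mk_gene(10000, "+"), length = 500)$start, 9500)
})

test_that("shared_tfs is a plain set intersection", {
  expect_equal(shared_tfs(c("A", "B"), c("B", "C")), "B")
  expect_equal(shared_tfs(c("A", "B"), c("C", "D")), character(0))
  five <- paste0("T", 1:5)
  expect_equal(shared_tfs(five, five), sort(five))
  hits <- data.frame(tf_name = c("A", "B"), region_id = "e1")
  expect_equal(shared_tfs(hits, c("B")), "B")
})

test_that("interaction support requires both ends, in either anchor order", {
  enh <- iv("chr1", 1000, 2000, "e")
  pro <- iv("chr1", 50000, 52000, "p")
  fwd <- data.frame(chrom_a = "chr1", start_a = 900, end_a = 1100,
                    chrom_b = "chr1", start_b = 51000, end_b = 51500,
                    assay = "3C", stringsAsFactors = FALSE)
  expect_true(interaction_supported(enh, pro, fwd))
  # swapped anchor assignment is equivalent
  swp <- fwd[, c(4:6, 1:3, 7)]
  names(swp) <- names(fwd)
  expect_true(interaction_supported(enh, pro, swp))
  # an anchor pair touching only the enhancer is not support
  half <- fwd
  half$start_b <- 90000
  half$end_b <- 90100
  expect_false(interaction_supported(enh, pro, half))
  expect_false(interaction_supported(enh, pro, fwd[0, ]))
})

test_that("coordinations need shared motif AND interaction, conjointly", {
  gene <- mk_gene(52000, "+")            # promoter [50000, 52000)
  cat1 <- iv("chr1", 1000, 2000, "e1")
  cat1$sources <- "DENDB"
  calls <- data.frame(probe_id = "erna1", enhancer_ids = "e1",
                      sources = "DENDB", stringsAsFactors = FALSE)
  pairs <- data.frame(probe_id = "erna1", gene_id = "g1",
                      stringsAsFactors = FALSE)
  ehits <- data.frame(tf_name = c("TFA", "TFB"), region_id = "e1")
  phits <- data.frame(tf_name = c("TFA", "TFC"), region_id = "g1")
  anch <- data.frame(chrom_a = "chr1", start_a = 900, end_a = 1100,
                     chrom_b = "chr1", start_b = 51000, end_b = 51500,
                     assay = "ChIA-PET", stringsAsFactors = FALSE)
  got <- build_coordinations(pairs, calls, cat1, gene, ehits, phits, anch)
  expect_equal(nrow(got), 1)
  expect_equal(got$tf_name, "TFA")
  expect_true(got$interaction_supported)
  # shared TF but no anchor -> nothing
  expect_equal(nrow(build_coordinations(pairs, calls, cat1, gene, ehits,
                                        phits, anch[0, ])), 0)
  # anchor but disjoint motifs -> nothing
  expect_equal(nrow(build_coordinations(pairs, calls, cat1, gene,
    data.frame(tf_name = "TFZ", region_id = "e1"), phits, anch)), 0)
  # gene-body linkage flag: anchor on the gene body instead of the promoter
  anch_body <- anch
  anch_body$start_b <- 52500
  anch_body$end_b <- 52800
  expect_equal(nrow(build_coordinations(pairs, calls, cat1, gene, ehits,
                                        phits, anch_body)), 0)
  expect_equal(nrow(build_coordinations(pairs, calls, cat1, gene, ehits,
                                        phits, anch_body,
                                        link = "gene_body")), 1)
})

test_that("CTCF mediation needs a peak at each end; one wide peak suffices", {
  gene <- mk_gene(52000, "+")
  cat1 <- iv("chr1", 1000, 2000, "e1")
  coords <- data.frame(enhancer_id = "e1", erna_probe_id = "erna1",
                       tf_name = "TFA", gene_id = "g1",
                       interaction_supported = TRUE, ctcf_mediated = NA,
                       stringsAsFactors = FALSE)
  both <- iv("chr1", c(1500, 50500), c(1600, 50600), c("c1", "c2"))
  expect_true(ctcf_mediated(coords, both, cat1, gene)$ctcf_mediated)
  enh_only <- iv("chr1", 1500, 1600, "c1")
  expect_false(ctcf_mediated(coords, enh_only, cat1, gene)$ctcf_mediated)
  wide <- iv("chr1", 500, 60000, "c1")
  expect_true(ctcf_mediated(coords, wide, cat1, gene)$ctcf_mediated)
})

test_that("the published top-2-enhancer table yields 34 coordinations with the printed degrees", {
  tab <- fixture_coords()
  expect_equal(nrow(unique(tab)), 34)
  deg <- node_degrees(tab)
  enh <- deg[deg$role == "enhancer", ]
  expect_equal(enh$node, c("K562_enhancer_301676", "K562_enhancer_288447"))
  expect_equal(enh$degree, c(25, 9))
  # distinct node tally per role
  roles <- table(deg$role)
  expect_equal(as.numeric(roles[c("enhancer", "eRNA", "TF", "gene")]),
               c(2, 3, 20, 2))
  # degrees within each role sum to the number of coordinations
  for (r in unique(deg$role)) {
    expect_equal(sum(deg$degree[deg$role == r]), nrow(tab))
  }
  # top-2 enhancer selection returns the full table here
  expect_equal(nrow(top_k_by_degree(tab, "enhancer", 2)), 34)
  expect_equal(nrow(top_k_by_degree(tab, "enhancer", 100)), 34)
  expect_equal(unique(top_k_by_degree(tab, "eRNA", 1)$erna_probe_id),
               "lnc-PERP-2:25")   # 13 incident rows, the eRNA maximum
})

test_that("degrees equal a brute-force incidence tally on random sets", {
  set.seed(81)
  for (rep in 1:5) {
    coords <- data.frame(
      enhancer_id = sample(paste0("e", 1:6), 40, TRUE),
      erna_probe_id = sample(paste0("r", 1:5), 40, TRUE),
      tf_name = sample(paste0("t", 1:8), 40, TRUE),
      gene_id = sample(paste0("g", 1:4), 40, TRUE),
      stringsAsFactors = FALSE
    )
    coords <- unique(coords)
    deg <- node_degrees(coords)
    for (i in sample(nrow(deg), 10)) {
      col <- c(enhancer = "enhancer_id", eRNA = "erna_probe_id",
               TF = "tf_name", gene = "gene_id")[[deg$role[i]]]
      expect_equal(deg$degree[i], sum(coords[[col]] == deg$node[i]))
    }
  }
})

test_that("network export: edge model, round trip, node attributes", {
  one <- data.frame(enhancer_id = "e1", erna_probe_id = "r1",
                    tf_name = "t1", gene_id = "g1", stringsAsFactors = FALSE)
  sif <- withr::local_tempfile(fileext = ".sif")
  edges <- export_network(one, sif, "sif")
  expect_equal(nrow(edges), 3)
  expect_setequal(edges$interaction,
                  c("shares_motif", "regulates", "transcribed_as"))
  expect_equal(read_sif(sif), edges)

  tab <- fixture_coords()
  sif2 <- withr::local_tempfile(fileext = ".sif")
  e2 <- export_network(tab, sif2, "sif")
  expect_equal(read_sif(sif2), e2)
  nodes <- utils::read.delim(paste0(tools::file_path_sans_ext(sif2),
                                    "_nodes.tsv"))
  expect_equal(as.numeric(table(nodes$role)[c("enhancer", "eRNA", "TF",
                                              "gene")]), c(2, 3, 20, 2))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(tab, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 27)   # 2 + 3 + 20 + 2 distinct nodes
  expect_equal(igraph::gsize(g), nrow(e2))

  expect_error(export_network(one, sif, "dot"), "unknown format")
})
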