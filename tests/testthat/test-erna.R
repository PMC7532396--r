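# eRNA / SE-lncRNA calling: the 1 nt overlap rule, per-probe deduplication
# with source union, the per-source breakdown convention, class-wise mean
# signal comparison and the distribution summaries.

mk_probe <- function(start, end, id, class = "lncRNA", subclass = "intergenic",
                     chrom = "chr1") {
  data.frame(probe_id = id, chrom = chrom, start = start, end = end,
             id = id, strand = "+", rna_class = class,
             lnc_subclass = if (class == "lncRNA") subclass else NA_character_,
             stringsAsFactors = FALSE)
}

mk_cat <- function(start, end, id, sources, state = NA_character_) {
  e <- iv("chr1", start, end, id)
  e$sources <- sources
  e$chromatin_state <- state
  e
}

test_that("a single shared nucleotide calls an eRNA; zero overlap does not", {
  cat1 <- mk_cat(100, 200, "e1", "DENDB")
  hit <- call_ernas(mk_probe(199, 300, "p1"), cat1)
  expect_equal(hit$probe_id, "p1")
  expect_equal(hit$sources, "DENDB")
  expect_equal(nrow(call_ernas(mk_probe(200, 300, "p1"), cat1)), 0)
  expect_error(call_ernas(mk_probe(100, 200, "p1", class = "mRNA"), cat1),
               "lncRNA")
})

test_that("multi-enhancer probes collapse to one call with unioned sources", {
  cat2 <- rbind(mk_cat(100, 200, "e1", "DENDB"),
                mk_cat(150, 260, "e2", "STARR", state = "open"))
  p <- mk_probe(140, 220, "p1")
  got <- call_ernas(p, cat2)
  expect_equal(nrow(got), 1)
  expect_equal(got$sources, "DENDB,STARR")
  expect_equal(got$enhancer_ids, "e1;e2")
  expect_equal(got$chromatin_state, "open")
  # cross-check the join against the brute-force all-pairs oracle
  expect_equal(sort(strsplit(got$enhancer_ids, ";")[[1]]),
               sort(brute_pairs(p, cat2)$subject_id))
})

test_that("eRNA chromatin state follows overlapping STARR enhancers only", {
  p <- mk_probe(140, 220, "p1")
  st <- function(cat) call_ernas(p, cat)$chromatin_state
  expect_equal(st(mk_cat(100, 200, "e1", "STARR", "closed")), "closed")
  expect_equal(st(rbind(mk_cat(100, 200, "e1", "STARR", "closed"),
                        mk_cat(150, 260, "e2", "STARR", "open"))), "open")
  expect_equal(st(mk_cat(100, 200, "e1", "DENDB", "open")), "unknown")
})

test_that("SE-lncRNA calls deduplicate and respect the overlap boundary", {
  se <- iv("chr1", c(1000, 1500), c(2000, 2600), c("se1", "se2"))
  expect_equal(call_se_lncrnas(mk_probe(1200, 1300, "p1"), se)$probe_id, "p1")
  expect_equal(nrow(call_se_lncrnas(mk_probe(2600, 2700, "p1"), se)), 0)
  two <- call_se_lncrnas(mk_probe(1800, 2100, "p1"), se)
  expect_equal(nrow(two), 1)
  expect_equal(two$superenhancer_ids, "se1;se2")
})

test_that("source breakdown counts calls toward every member source", {
  calls <- data.frame(
    probe_id = c("p1", "p2", "p3"),
    sources = c("DENDB", "ENCODE", "STARR"), stringsAsFactors = FALSE
  )
  b <- source_breakdown(calls)
  expect_equal(unlist(b), c(total = 3, DENDB = 1, ENCODE = 1, STARR = 1))
  multi <- source_breakdown(data.frame(probe_id = "p1",
                                       sources = "DENDB,STARR"))
  expect_equal(unlist(multi), c(total = 1, DENDB = 1, ENCODE = 0, STARR = 1))
})

test_that("mean signal comparison: exchangeability, shift, planted effect", {
  set.seed(51)
  m <- matrix(stats::rnorm(50 * 4, 6, 1), 50, 4,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:4)))
  same <- mean_signal_by_class(m, paste0("p", 1:25), paste0("p", 1:25))
  expect_equal(same$mean_a, same$mean_b)
  expect_gt(same$p_value, 0.99)

  shifted <- m
  shifted[26:50, ] <- m[1:25, ] + 1
  sh <- mean_signal_by_class(shifted, paste0("p", 26:50), paste0("p", 1:25))
  expect_equal(sh$mean_a - sh$mean_b, 1.0)

  # planted open-vs-closed shift of +1 log2 unit, 200 probes per class
  open <- matrix(stats::rnorm(200 * 6, 6.25, 0.5), 200, 6)
  closed <- matrix(stats::rnorm(200 * 6, 5.25, 0.5), 200, 6)
  big <- rbind(open, closed)
  dimnames(big) <- list(paste0("q", 1:400), paste0("s", 1:6))
  got <- mean_signal_by_class(big, paste0("q", 1:200), paste0("q", 201:400))
  expect_lt(got$p_value, 0.001)

  single <- mean_signal_by_class(m, "p1", paste0("p", 2:10))
  expect_true(is.na(single$p_value))
  expect_error(mean_signal_by_class(m, character(), "p1"), "non-empty")
})

test_that("distribution summaries tally subclass, length bin and chromosome", {
  probes <- rbind(
    mk_probe(0, 150, "p1", subclass = "exonic_sense"),
    mk_probe(0, 900, "p2", subclass = "exonic_sense"),
    mk_probe(0, 12000, "p3", subclass = "intergenic"),
    mk_probe(0, 700, "p4", subclass = "intergenic", chrom = "chr2"),
    mk_probe(0, 300, "p5", subclass = "other", chrom = "chr2")
  )
  calls <- data.frame(probe_id = probes$probe_id, stringsAsFactors = FALSE)
  s <- summarize_distributions(calls, probes, length_breaks = c(500, 5000))
  expect_equal(s$by_length$count[match(c("<500", "500-5000", ">5000"),
                                       s$by_length$category)], c(2, 2, 1))
  expect_equal(s$by_chromosome$count[s$by_chromosome$category == "chr2"], 2)
  # every table's counts sum to the number of calls; tallies match table()
  for (t in s) expect_equal(sum(t$count), nrow(calls))
  want <- table(probes$lnc_subclass)
  got <- stats::setNames(s$by_subclass$count, s$by_subclass$category)
  expect_equal(got[names(want)], stats::setNames(as.numeric(want),
                                                 names(want)))
})

test_that("enlarging the catalogue never removes a call", {
  set.seed(53)
  probes <- rand_intervals(60, max_pos = 8000, prefix = "p")
  probes$probe_id <- probes$id
  probes$rna_class <- "lncRNA"
  probes$lnc_subclass <- "intergenic"
  small <- mk_cat(1:20 * 300, 1:20 * 300 + 200, paste0("e", 1:20), "DENDB")
  extra <- mk_cat(1:10 * 700 + 13, 1:10 * 700 + 240, paste0("x", 1:10),
                  "STARR")
  a <- call_ernas(probes, small)
  b <- call_ernas(probes, rbind(small, extra))
  expect_true(all(a$probe_id %in% b$probe_id))
})
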