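# Expression processing: quantile normalisation invariants, log2
# transform, the pooled-variance t-based differential-expression filter
# checked against a textbook oracle, cross-platform validation, and qPCR
# 2^-ddCt quantification.

mk_samples <- function(n_pairs = 3) {
  data.frame(
    sample_id = c(paste0("T", seq_len(n_pairs)), paste0("N", seq_len(n_pairs))),
    condition = rep(c("tumor", "normal"), each = n_pairs),
    pair_id = rep(paste0("P", seq_len(n_pairs)), 2),
    stringsAsFactors = FALSE
  )
}

mk_matrix <- function(values, n_pairs = 3, ids = NULL) {
  m <- matrix(values, ncol = 2 * n_pairs, byrow = TRUE)
  rownames(m) <- if (is.null(ids)) paste0("p", seq_len(nrow(m))) else ids
  colnames(m) <- mk_samples(n_pairs)$sample_id
  m
}

test_that("quantile normalisation equalises column distributions", {
  # hand-computed rank means: columns [2,6] and [4,8] both become [3,7]
  m <- matrix(c(2, 6, 4, 8), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  got <- quantile_normalize(m)
  expect_equal(unname(got), matrix(c(3, 7, 3, 7), 2, 2))
  expect_equal(dimnames(got), dimnames(m))

  const <- matrix(5, 4, 3)
  expect_equal(quantile_normalize(const), const)

  set.seed(61)
  r <- matrix(stats::rexp(500 * 6, 1 / 50), 500, 6)
  qn <- quantile_normalize(r)
  sorted <- apply(qn, 2, sort)
  for (j in 2:ncol(sorted)) expect_identical(sorted[, j], sorted[, 1])
  expect_equal(colMeans(qn), rep(mean(colMeans(qn)), 6),
               ignore_attr = TRUE)
  expect_equal(sum(qn), sum(r), tolerance = 1e-9)

  expect_error(quantile_normalize(matrix(-1:2, 2, 2)), "negative")
  expect_error(quantile_normalize(matrix(1:4, 4, 1)), "2 samples")
})

test_that("log2 transform applies the pseudocount", {
  expect_equal(log2_transform(matrix(c(1, 0, 7), 1)),
               matrix(c(1, 0, 3), 1))
  expect_equal(log2_transform(matrix(4, 1), pseudocount = 0),
               matrix(2, 1))
  expect_error(log2_transform(matrix(0, 1), pseudocount = 0), "non-finite")
})

test_that("differential expression matches the textbook pooled-variance t", {
  m <- mk_matrix(c(1, 2, 3, 4, 5, 6))   # tumor (1,2,3) vs normal (4,5,6)
  de <- differential_expression(m, mk_samples())
  o <- t_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(o$t), 3.674, tolerance = 1e-3)
  expect_equal(de$p_value, o$p, tolerance = 1e-12)
  expect_equal(de$p_value, 0.0213, tolerance = 5e-3)
  expect_equal(de$fold_change, 8)
  expect_equal(de$regulation, "down")
  expect_true(de$significant)
})

test_that("fold change is a magnitude with direction in `regulation`", {
  m <- mk_matrix(c(5, 5, 5, 3, 3, 3,   # up, fc 4
                   2, 2, 2, 4, 4, 4))  # down, fc 4
  de <- suppressWarnings(differential_expression(m, mk_samples()))
  expect_equal(de$fold_change, c(4, 4))
  expect_equal(de$regulation, c("up", "down"))
  expect_true(all(de$fold_change >= 1))
})

test_that("ties and zero-variance probes follow the stated conventions", {
  m <- mk_matrix(c(2, 2, 2, 2, 2, 2,       # constant, equal means
                   1, 2, 3, 1, 2, 3))      # identical groups, equal means
  de <- differential_expression(m, mk_samples())
  expect_equal(de$p_value[1], 1)
  expect_equal(de$fold_change, c(1, 1))
  expect_equal(de$regulation, c("up", "up"))
  expect_false(any(de$significant))
})

test_that("p-values agree with the oracle to 1e-10 on random probes", {
  set.seed(63)
  m <- mk_matrix(stats::rnorm(100 * 8, 6, 1), n_pairs = 4)
  de <- differential_expression(m, mk_samples(4))
  want <- vapply(seq_len(nrow(m)), function(i)
    t_oracle(m[i, 1:4], m[i, 5:8])$p, numeric(1))
  expect_equal(de$p_value, want, tolerance = 1e-10)
})

test_that("the paired mode removes between-pair variance", {
  set.seed(65)
  pair_effect <- stats::rnorm(4, 0, 5)
  tum <- pair_effect + 1 + stats::rnorm(4, 0, 0.1)
  nor <- pair_effect + stats::rnorm(4, 0, 0.1)
  m <- matrix(c(tum, nor), 1, dimnames = list("p1", mk_samples(4)$sample_id))
  un <- differential_expression(m, mk_samples(4))
  pa <- differential_expression(m, mk_samples(4), paired = TRUE)
  expect_lt(pa$p_value, un$p_value)
  expect_lt(pa$p_value, 0.01)
})

test_that("cross-platform validation recovers planted effects and trends", {
  set.seed(67)
  n_true <- 20
  ids <- paste0("p", 1:120)
  # platform A: log2 microarray-like with planted +2 effects on p1..p20
  la <- matrix(stats::rnorm(120 * 6, 6, 0.3), 120, 6,
               dimnames = list(ids, mk_samples()$sample_id))
  la[1:n_true, 1:3] <- la[1:n_true, 1:3] + 2
  de_a <- differential_expression(la, mk_samples())
  # platform B: linear RPKM-like, same effects (ratio 4 on the same probes)
  lb <- 2^matrix(stats::rnorm(120 * 10, 5, 0.3), 120, 10,
                 dimnames = list(ids, mk_samples(5)$sample_id))
  lb[1:n_true, 1:5] <- lb[1:n_true, 1:5] * 4
  v <- validate_cross_platform(de_a, lb, mk_samples(5))
  expect_setequal(v$shared_ids, ids)
  expect_setequal(v$de_both_ids, ids[1:n_true])
  expect_equal(v$same_trend_ids, v$de_both_ids)
})

test_that("a flat second platform yields no significant calls", {
  de_a <- data.frame(probe_id = paste0("p", 1:10), fold_change = 4,
                     regulation = "up", p_value = 0.01, significant = TRUE,
                     stringsAsFactors = FALSE)
  flat <- matrix(7, 10, 8, dimnames = list(paste0("p", 1:10),
                                           mk_samples(4)$sample_id))
  v <- validate_cross_platform(de_a, flat, mk_samples(4))
  expect_equal(v$de_both_ids, character(0))
  # opposite direction on platform B: DE-in-both but not same-trend
  down_b <- flat + matrix(stats::runif(80, 0, 0.01), 10)  # break ties
  down_b[, 1:4] <- down_b[, 1:4] / 7
  v2 <- validate_cross_platform(de_a, down_b, mk_samples(4))
  expect_setequal(v2$de_both_ids, paste0("p", 1:10))
  expect_equal(v2$same_trend_ids, character(0))
  # disjoint ids warn and return empty
  expect_warning(validate_cross_platform(de_a, matrix(1, 1, 8,
    dimnames = list("zz", mk_samples(4)$sample_id)), mk_samples(4)),
    "no shared")
})

test_that("2^-ddCt relative expression follows the comparative formula", {
  expect_equal(ddct_relative_expression(20, 20, 20, 20), 1.0)
  expect_equal(ddct_relative_expression(25, 20, 28, 21), 4.0)
  base <- ddct_relative_expression(24, 20, 25, 20)
  expect_equal(ddct_relative_expression(25, 20, 25, 20), base / 2)
  expect_error(ddct_relative_expression(NA, 20, 20, 20), "finite")
})
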