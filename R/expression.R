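# Expression processing: quantile normalisation (via limma, which the
# original microarray workflow also used), log2 transformation, two-group
# differential expression with fold-change/p filtering, cross-platform
# validation on linear-scale abundances, and 2^-ddCt qPCR quantification.

#' Quantile-normalise an expression matrix
#'
#' After normalisation every column shares the identical sorted value
#' vector (the row-wise mean of the per-column sorted values). Row and
#' column labels are preserved. Negative input values are an error; raw
#' intensities are expected.
#'
#' @param raw Numeric matrix, probes x samples (>= 2 samples).
#' @return The normalised matrix.
#' @export
quantile_normalize <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) < 2) stop("quantile_normalize: need >= 2 samples")
  if (any(!is.finite(raw))) stop("quantile_normalize: non-finite values")
  if (any(raw < 0)) stop("quantile_normalize: negative intensities")
  out <- limma::normalizeQuantiles(raw)
  dimnames(out) <- dimnames(raw)
  out
}

#' Log2-transform an expression matrix
#'
#' A pseudocount (default 1) is added first; any non-finite result is an
#' error.
#'
#' @param m Numeric matrix.
#' @param pseudocount Value added before taking log2.
#' @return `log2(m + pseudocount)`.
#' @export
log2_transform <- function(m, pseudocount = 1.0) {
  out <- log2(m + pseudocount)
  if (any(!is.finite(out))) {
    stop("log2_transform: non-finite result; values + pseudocount must be > 0")
  }
  out
}

#' Two-group differential expression on log2 signals
#'
#' Per probe: group means on the log2 scale, linear fold change
#' `2^|mean_tumor - mean_normal|` (magnitude >= 1, direction carried by
#' `regulation`), and a two-sided Student's t-test (pooled variance;
#' optionally paired). A probe is `significant` iff
#' `fold_change >= fc_threshold` and `p_value < p_threshold` (raw p, no
#' multiplicity correction). Equal group means give `regulation = "up"`,
#' `fold_change = 1` and are never significant; a probe constant within
#' both groups gets p = 1 when the means agree and p = 0 otherwise.
#'
#' @param m Normalised log2 expression matrix (probes x samples).
#' @param samples Sample sheet (`sample_id`, `condition`, `pair_id`).
#' @param fc_threshold Linear fold-change threshold (>= 1).
#' @param p_threshold Raw p-value threshold.
#' @param paired Use the paired t-test (samples matched by `pair_id`)?
#' @return A data.frame with columns `probe_id`, `mean_tumor`,
#'   `mean_normal`, `fold_change`, `regulation`, `p_value`, `significant`.
#' @export
differential_expression <- function(m, samples, fc_threshold = 2,
                                    p_threshold = 0.05, paired = FALSE) {
  validate_sample_sheet(samples)
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  missing <- setdiff(samples$sample_id, colnames(m))
  if (length(missing)) {
    stop("differential_expression: sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  tum <- samples[samples$condition == "tumor", , drop = FALSE]
  nor <- samples[samples$condition == "normal", , drop = FALSE]
  if (nrow(tum) < 2 || nrow(nor) < 2) {
    stop("differential_expression: need >= 2 samples per condition")
  }
  if (paired) {
    tum <- tum[order(tum$pair_id), , drop = FALSE]
    nor <- nor[order(nor$pair_id), , drop = FALSE]
  }
  mt <- m[, tum$sample_id, drop = FALSE]
  mn <- m[, nor$sample_id, drop = FALSE]
  mean_t <- rowMeans(mt)
  mean_n <- rowMeans(mn)
  p <- vapply(seq_len(nrow(m)), function(i) {
    tryCatch(
      stats::t.test(mt[i, ], mn[i, ], var.equal = TRUE,
                    paired = paired)$p.value,
      error = function(e) if (mean_t[i] == mean_n[i]) 1 else 0
    )
  }, numeric(1))
  diff <- mean_t - mean_n
  fc <- 2^abs(diff)
  res <- data.frame(
    probe_id = rownames(m),
    mean_tumor = unname(mean_t), mean_normal = unname(mean_n),
    fold_change = unname(fc),
    regulation = ifelse(diff < 0, "down", "up"),
    p_value = p,
    stringsAsFactors = FALSE
  )
  res$significant <- res$fold_change >= fc_threshold & res$p_value < p_threshold
  rownames(res) <- NULL
  res
}

#' Cross-platform validation of differential-expression calls
#'
#' Re-tests probes on a second platform whose values are linear-scale
#' abundances (RPKM-like): the second-platform test is a two-sided
#' Mann-Whitney on the linear values and its fold change is the ratio of
#' linear group means. Reports which probes are shared, DE on both
#' platforms, and DE with the same regulation direction on both.
#'
#' @param de_a Differential-expression table of platform A (see
#'   [differential_expression()]).
#' @param matrix_b Linear-scale expression matrix of platform B.
#' @param samples_b Sample sheet for platform B.
#' @param fc_threshold,p_threshold Significance filter for platform B.
#' @return A list with `shared_ids`, `de_b` (platform-B DE table over the
#'   shared probes), `de_both_ids`, `same_trend_ids`.
#' @export
validate_cross_platform <- function(de_a, matrix_b, samples_b,
                                    fc_threshold = 2, p_threshold = 0.05) {
  validate_sample_sheet(samples_b)
  shared <- intersect(de_a$probe_id, rownames(matrix_b))
  if (!length(shared)) {
    warning("validate_cross_platform: no shared probe ids")
    return(list(shared_ids = character(),
                de_b = NULL, de_both_ids = character(),
                same_trend_ids = character()))
  }
  mb <- matrix_b[shared, samples_b$sample_id, drop = FALSE]
  is_t <- samples_b$condition == "tumor"
  mean_t <- rowMeans(mb[, is_t, drop = FALSE])
  mean_n <- rowMeans(mb[, !is_t, drop = FALSE])
  p <- vapply(seq_len(nrow(mb)), function(i) {
    pv <- suppressWarnings(
      stats::wilcox.test(mb[i, is_t], mb[i, !is_t], exact = TRUE)$p.value
    )
    if (!is.finite(pv)) 1 else pv   # fully tied values carry no signal
  }, numeric(1))
  ratio <- mean_t / mean_n
  de_b <- data.frame(
    probe_id = shared,
    fold_change = pmax(ratio, 1 / ratio),
    regulation = ifelse(mean_t < mean_n, "down", "up"),
    p_value = p,
    stringsAsFactors = FALSE
  )
  de_b$significant <- de_b$fold_change >= fc_threshold &
    de_b$p_value < p_threshold
  sig_a <- de_a$probe_id[de_a$significant]
  both <- intersect(de_b$probe_id[de_b$significant], sig_a)
  reg_a <- stats::setNames(de_a$regulation, de_a$probe_id)
  reg_b <- stats::setNames(de_b$regulation, de_b$probe_id)
  same <- both[reg_a[both] == reg_b[both]]
  list(shared_ids = shared, de_b = de_b, de_both_ids = sort(both),
       same_trend_ids = sort(same))
}

#' Relative expression by the comparative 2^-ddCt method
#'
#' `ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,cal - Ct_ref,cal)`;
#' the reference gene (e.g. beta-actin) normalises loading and the
#' calibrator sample anchors the scale. Vectorised.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in the
#'   case sample.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and reference
#'   gene in the calibrator sample.
#' @return Linear fold change `2^-ddCt`.
#' @export
ddct_relative_expression <- function(ct_target_case, ct_ref_case,
                                     ct_target_calibrator,
                                     ct_ref_calibrator) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_calibrator,
           ct_ref_calibrator)
  if (any(!is.finite(cts))) {
    stop("ddct_relative_expression: all Ct values must be finite")
  }
  ddct <- (ct_target_case - ct_ref_case) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
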