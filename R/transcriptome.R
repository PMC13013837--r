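# Transcriptome analysis: TPM normalization, per-gene Welch differential
# expression on log2(TPM + pseudocount), DEG calling under the
# p < 0.05 & (FC > 2 | FC < 0.5) rule, and per-gene z-scaling for display.

#' Convert counts to transcripts per million
#'
#' `rate = count / length_kb; TPM = rate / sum(rate) * 1e6` per sample, so
#' every column sums to one million.
#'
#' @param counts genes x samples matrix of nonnegative counts.
#' @param lengths_bp per-gene transcript lengths in bp (> 0), recycled by
#'   name when named.
#' @return TPM matrix with `lengths_bp` attached as attribute `lengths`.
#' @export
counts_to_tpm <- function(counts, lengths_bp) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths_bp)) && !is.null(rownames(counts))) {
    lengths_bp <- lengths_bp[rownames(counts)]
  }
  assert_that(length(lengths_bp) == nrow(counts),
              "one length per gene required")
  assert_that(all(lengths_bp > 0), "gene lengths must be positive")
  assert_that(all(counts >= 0), "counts must be nonnegative")
  rate <- counts / (lengths_bp / 1000)
  totals <- colSums(rate)
  if (any(totals == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  attr(tpm, "lengths") <- lengths_bp
  tpm
}

#' Per-gene differential expression between two groups
#'
#' Fold change is computed on the linear scale,
#' `log2FC = log2((meanA + ps) / (meanB + ps))`; the p-value is a Welch
#' t-test on `log2(x + ps)` per gene, with BH q-values alongside. Genes
#' with zero variance in both groups are flagged as degenerate: p = 1 when
#' the group means are also equal, p = 0 when they differ (noiseless data
#' carry unambiguous evidence; this keeps DEG recovery exact on noiseless
#' synthetic cohorts).
#'
#' @param expr genes x samples matrix (TPM or any linear expression).
#' @param sample_groups group label per column (named or positional).
#' @param groupA,groupB the contrasted groups (A vs B; B is the baseline).
#' @param pseudocount added before log2 (default 1).
#' @return data.frame with `gene`, `log2fc`, `p_value`, `q_value`,
#'   `degenerate`.
#' @export
differential_expression <- function(expr, sample_groups, groupA, groupB,
                                    pseudocount = 1) {
  expr <- as.matrix(expr)
  if (!is.null(names(sample_groups)) && !is.null(colnames(expr))) {
    sample_groups <- sample_groups[colnames(expr)]
  }
  assert_that(length(sample_groups) == ncol(expr),
              "one group label per sample required")
  a <- expr[, sample_groups == groupA, drop = FALSE]
  b <- expr[, sample_groups == groupB, drop = FALSE]
  assert_that(ncol(a) >= 2 && ncol(b) >= 2,
              "each contrasted group needs >= 2 samples")
  log2fc <- log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))

  la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
  na <- ncol(la); nb <- ncol(lb)
  va <- row_vars(la); vb <- row_vars(lb)
  degenerate <- va == 0 & vb == 0
  se2 <- va / na + vb / nb
  tt <- (rowMeans(la) - rowMeans(lb)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tt), df)
  p[degenerate] <- ifelse(rowMeans(la)[degenerate] == rowMeans(lb)[degenerate],
                          1, 0)
  data.frame(
    gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
    log2fc = unname(log2fc), p_value = unname(p),
    q_value = bh_adjust(unname(p)), degenerate = unname(degenerate),
    stringsAsFactors = FALSE
  )
}

#' Call differentially expressed genes
#'
#' A gene is `up` iff p < `p_thresh` and fold change > `fc_up`, `down` iff
#' p < `p_thresh` and fold change < `fc_down`, otherwise `none`. Defaults
#' follow the rule p < 0.05 with FC > 2 or FC < 0.5 on the raw p-value;
#' set `use_q = TRUE` to gate on BH q instead.
#'
#' @param de_results output of [differential_expression()].
#' @param p_thresh significance threshold (default 0.05).
#' @param fc_up,fc_down linear fold-change cutoffs (defaults 2 and 0.5).
#' @param use_q gate on `q_value` instead of `p_value`.
#' @return `de_results` with a `deg_class` factor column.
#' @export
call_degs <- function(de_results, p_thresh = 0.05, fc_up = 2, fc_down = 0.5,
                      use_q = FALSE) {
  p <- if (use_q) de_results$q_value else de_results$p_value
  fc <- 2^de_results$log2fc
  cls <- ifelse(p < p_thresh & fc > fc_up, "up",
                ifelse(p < p_thresh & fc < fc_down, "down", "none"))
  de_results$deg_class <- factor(cls, levels = c("up", "down", "none"))
  de_results
}

#' Z-scale expression rows for display
#'
#' Per-gene standardization across samples (mean 0, sample SD 1), as used
#' for DEG heatmaps. Zero-variance genes are dropped with a warning.
#'
#' @param expr genes x samples matrix.
#' @param genes optional subset of row names to scale.
#' @return the scaled matrix (possibly fewer rows).
#' @export
scale_rows <- function(expr, genes = NULL) {
  m <- as.matrix(expr)
  if (!is.null(genes)) m <- m[intersect(genes, rownames(m)), , drop = FALSE]
  sds <- sqrt(row_vars(m))
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance gene(s) from scaling")
    m <- m[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  (m - rowMeans(m)) / sds
}
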