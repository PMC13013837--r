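# TF-activity / transcriptome integration: regulon-level coupling,
# enrichment, shift and variance statistics, driver ranking, and the
# activity-behavior correlation.

#' Couple TF activity changes to their regulons' expression changes
#'
#' For each TF with at least one predicted target carrying a DE result,
#' pairs the TF's activity log2 fold change with the unweighted mean log2
#' fold change of its targets (the scatter behind activity-vs-downstream
#' plots), plus the regulon-level enrichment and shift statistics.
#'
#' @param activity_summary data.frame with `tf_id` and `mean_log2fc` (one
#'   group contrast, e.g. from [tfap_summary()]).
#' @param de_results data.frame from [differential_expression()], with
#'   `deg_class` if DEG enrichment is wanted (see [call_degs()]).
#' @param regulon_map a `regulon_map`.
#' @param weighted if `TRUE`, weight target fold changes by the regulon's
#'   best motif scores (default unweighted mean).
#' @return data.frame of integration records: `tf_id`, `activity_log2fc`,
#'   `mean_target_log2fc`, `n_targets`, `enrichment_p`, `shift_p`. TFs with
#'   empty regulons are excluded with a warning.
#' @export
tf_regulon_coupling <- function(activity_summary, de_results, regulon_map,
                                weighted = FALSE) {
  de_lfc <- setNames(de_results$log2fc, de_results$gene)
  universe <- de_results$gene
  deg_set <- if (!is.null(de_results$deg_class)) {
    de_results$gene[de_results$deg_class != "none"]
  } else NULL
  rows <- list()
  for (i in seq_len(nrow(activity_summary))) {
    tf <- activity_summary$tf_id[i]
    targets <- intersect(regulon_map$targets[[tf]], universe)
    if (!length(targets)) {
      warning("TF with no scored targets excluded from integration: ", tf)
      next
    }
    lfc <- de_lfc[targets]
    mt <- if (weighted) {
      w <- regulon_map$best_scores[[tf]][targets]
      if (all(is.finite(w))) sum(w * lfc) / sum(w) else mean(lfc)
    } else mean(lfc)
    enr <- if (!is.null(deg_set) && length(deg_set)) {
      regulon_deg_enrichment(deg_set, targets, universe)
    } else NA_real_
    shift <- if (length(targets) < length(universe)) {
      regulon_shift_test(de_lfc[universe], targets)$p
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      tf_id = tf, activity_log2fc = activity_summary$mean_log2fc[i],
      mean_target_log2fc = unname(mt), n_targets = length(targets),
      enrichment_p = enr, shift_p = shift, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric DEG enrichment of a regulon
#'
#' Upper-tail probability of observing at least the actual overlap between
#' the DEG set and the regulon when drawing `|deg_set|` genes from a
#' universe of `N` containing `|regulon|` regulon members.
#'
#' @param deg_set,regulon,universe character vectors of gene ids
#'   (`deg_set`, `regulon` subsets of `universe`).
#' @return upper-tail p-value, `P(X >= overlap)`.
#' @export
regulon_deg_enrichment <- function(deg_set, regulon, universe) {
  assert_that(length(universe) >= 1, "empty gene universe")
  deg_set <- intersect(deg_set, universe)
  regulon <- intersect(regulon, universe)
  k <- length(intersect(deg_set, regulon))
  phyper(k - 1, length(regulon), length(universe) - length(regulon),
         length(deg_set), lower.tail = FALSE)
}

#' Wilcoxon rank-sum shift test of a regulon's fold changes
#'
#' Two-sided rank-sum test of the absolute log2 fold changes of regulon
#' members against all other genes — are downstream genes more affected
#' than the background? Exact null distribution when there are no ties and
#' `n + m <= 30`, otherwise a normal approximation with tie correction
#' (no continuity correction).
#'
#' @param de_log2fc named numeric vector of log2 fold changes, all genes.
#' @param regulon_membership gene ids (or logical mask) of regulon members.
#' @return list with `W` (Mann-Whitney U of the regulon), `p`, `exact`.
#' @export
regulon_shift_test <- function(de_log2fc, regulon_membership) {
  if (is.logical(regulon_membership)) {
    inset <- regulon_membership
  } else {
    inset <- names(de_log2fc) %in% regulon_membership
  }
  x <- abs(de_log2fc[inset]); y <- abs(de_log2fc[!inset])
  n <- length(x); m <- length(y)
  assert_that(n >= 1 && m >= 1,
              "regulon and background must both be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n + m <= 30) {
    p <- if (U == n * m / 2) 1 else if (U > n * m / 2) {
      2 * pwilcox(U - 1, n, m, lower.tail = FALSE)
    } else {
      2 * pwilcox(U, n, m)
    }
    return(list(W = U, p = min(1, p), exact = TRUE))
  }
  tie_counts <- table(r)
  sigma2 <- n * m / 12 *
    ((n + m + 1) - sum(tie_counts^3 - tie_counts) / ((n + m) * (n + m - 1)))
  if (sigma2 == 0) {
    return(list(W = U, p = 1, exact = FALSE)) # all values tied
  }
  z <- (U - n * m / 2) / sqrt(sigma2)
  list(W = U, p = min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

#' Two-sided F-test for variance broadening
#'
#' Compares the spread of two fold-change vectors (e.g. a TF's regulon
#' under two treatments): `F = var(x) / var(y)` with `(n1 - 1, n2 - 1)`
#' degrees of freedom and `p = min(1, 2 * min(P(F <= f), P(F >= f)))`.
#'
#' @param x,y numeric vectors, each n >= 2.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
variance_broadening_test <- function(x, y) {
  assert_that(length(x) >= 2 && length(y) >= 2,
              "each contrast needs n >= 2")
  v1 <- var(x); v2 <- var(y)
  if (v2 == 0) stop("zero variance in the denominator contrast")
  f <- v1 / v2
  df1 <- length(x) - 1; df2 <- length(y) - 1
  p <- 2 * min(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE))
  list(F = f, df1 = df1, df2 = df2, p = min(1, p))
}

#' Rank candidate driver TFs
#'
#' Composite score: `|activity_log2fc| * |mean_target_log2fc| * c`, where
#' the concordance multiplier `c` is 1 when the signs of the activity and
#' downstream changes agree under the TF's declared mode (activator:
#' same sign; repressor: opposite) and `discordance_factor` otherwise.
#' The ranking criterion is a declared choice of this package, not a
#' published one. Ties are broken by enrichment p, then TF name.
#'
#' @param records data.frame from [tf_regulon_coupling()].
#' @param modes named character vector, `"activator"` (default) or
#'   `"repressor"` per TF.
#' @param discordance_factor multiplier when signs conflict (default 0.25).
#' @return `records` sorted by descending `driver_score`, with `rank`.
#' @export
rank_candidate_drivers <- function(records, modes = NULL,
                                   discordance_factor = 0.25) {
  assert_that(nrow(records) >= 1, "no integration records to rank")
  mode <- rep("activator", nrow(records))
  if (!is.null(modes)) {
    mm <- modes[records$tf_id]
    mode[!is.na(mm)] <- mm[!is.na(mm)]
  }
  expected_sign <- ifelse(mode == "repressor", -1, 1) * sign(records$activity_log2fc)
  concord <- ifelse(sign(records$mean_target_log2fc) == expected_sign &
                      expected_sign != 0, 1, discordance_factor)
  records$driver_score <- abs(records$activity_log2fc) *
    abs(records$mean_target_log2fc) * concord
  enr <- records$enrichment_p
  enr[is.na(enr)] <- 1
  o <- order(-records$driver_score, enr, records$tf_id)
  out <- records[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Correlate TF activity with social-interaction behavior
#'
#' Per-TF Pearson correlation between animals' normalized activities and
#' SI-rates (two-sided t-based p). In joint mode, SI is regressed on all
#' requested TF activities together and the multiple correlation
#' coefficient `R` with the overall F-test p is returned — the joint R can
#' be weaker than the best single-TF r when the TFs carry redundant
#' information.
#'
#' @param activities data.frame with `animal_id`, `tf_id`,
#'   `normalized_activity` (e.g. a `tfap`).
#' @param si_rates named numeric vector of SI-rates by animal.
#' @param tf_subset TFs to analyze (default: all in `activities`).
#' @param joint if `TRUE`, fit one multiple regression over `tf_subset`.
#' @return data.frame with `tf_id` (or `"joint"`), `r`, `n`, `p`.
#' @export
activity_behavior_correlation <- function(activities, si_rates,
                                          tf_subset = NULL, joint = FALSE) {
  tfs <- tf_subset %||% unique(activities$tf_id)
  wide <- lapply(tfs, function(tf) {
    sub <- activities[activities$tf_id == tf, ]
    setNames(sub$normalized_activity, sub$animal_id)
  })
  names(wide) <- tfs
  if (!joint) {
    out <- do.call(rbind, lapply(tfs, function(tf) {
      act <- wide[[tf]]
      common <- intersect(names(act), names(si_rates))
      assert_that(length(common) >= 3, "need >= 3 paired animals for ", tf)
      pc <- pearson_cor(act[common], si_rates[common])
      data.frame(tf_id = tf, r = pc$r, n = pc$n, p = pc$p,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  common <- Reduce(intersect, c(lapply(wide, names), list(names(si_rates))))
  assert_that(length(common) >= length(tfs) + 2,
              "joint mode needs n >= #TFs + 2 animals")
  X <- do.call(cbind, lapply(wide, `[`, common))
  fit <- lm(si_rates[common] ~ X)
  sm <- summary(fit)
  r2 <- sm$r.squared
  fs <- sm$fstatistic
  data.frame(tf_id = "joint", r = sqrt(r2), n = length(common),
             p = pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}
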