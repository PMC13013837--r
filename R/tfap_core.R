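# TFAP assembly: control normalization within experiments, group-level
# log2 fold-change summaries, the package's group-comparison tests, and
# the per-cell high/low activity rule.

#' Normalize raw activities to within-experiment controls
#'
#' Every measurement is divided by the mean raw activity of the control
#' animals for the same TF within the same experiment, so multi-experiment
#' batteries can be pooled into one TF activity profile (TFAP). Each
#' (experiment, TF) stratum must contain at least one control animal.
#'
#' @param measurements data.frame with `animal_id`, `experiment_id`,
#'   `tf_id`, `raw_activity`, and either a `group` column or one joined
#'   from `group_labels`.
#' @param group_labels optional data.frame (`animal_id`, `group`) if
#'   `measurements` lacks a `group` column.
#' @param control_group name of the control group.
#' @return object of class `tfap`: the input rows plus a
#'   `normalized_activity` column.
#' @export
normalize_to_controls <- function(measurements, group_labels = NULL,
                                  control_group = "control") {
  m <- measurements
  if (is.null(m$group)) {
    assert_that(!is.null(group_labels), "group labels required")
    m <- merge(m, group_labels[, c("animal_id", "group")], by = "animal_id")
  }
  assert_that(all(c("experiment_id", "tf_id", "raw_activity") %in% names(m)),
              "measurements must carry experiment_id, tf_id, raw_activity")
  key <- interaction(m$experiment_id, m$tf_id, drop = TRUE)
  ctrl_mean <- tapply(m$raw_activity[m$group == control_group],
                      droplevels(key[m$group == control_group]), mean)
  missing <- setdiff(levels(key), names(ctrl_mean))
  if (length(missing)) {
    stop("no control measurements in stratum (experiment.tf): ",
         paste(missing, collapse = ", "))
  }
  m$normalized_activity <- m$raw_activity / as.numeric(ctrl_mean[as.character(key)])
  structure(m, class = c("tfap", "data.frame"))
}

#' Group-level activity change for one TF
#'
#' The "corrected" mean log2 fold change: mean per-animal log2 normalized
#' activity in `group` minus the same mean in `reference_group`, with the
#' SEM taken from the `group` animals. (With per-experiment control
#' normalization the reference term is ~0; subtracting it makes the
#' contrast exact for arbitrary reference groups.)
#'
#' @param tfap a `tfap` from [normalize_to_controls()].
#' @param tf TF id.
#' @param group group being contrasted.
#' @param reference_group baseline group (default `"control"`).
#' @return data.frame row with `tf_id`, `group`, `mean_log2fc`,
#'   `sem_log2fc`, `n`.
#' @export
group_log2fc <- function(tfap, tf, group, reference_group = "control") {
  x <- log2(tfap$normalized_activity[tfap$tf_id == tf & tfap$group == group])
  r <- log2(tfap$normalized_activity[tfap$tf_id == tf &
                                       tfap$group == reference_group])
  if (!length(x) || !length(r)) {
    stop("empty group for ", tf, ": ", group, " vs ", reference_group)
  }
  data.frame(
    tf_id = tf, group = group,
    mean_log2fc = mean(x) - mean(r),
    sem_log2fc = if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_,
    n = length(x), stringsAsFactors = FALSE
  )
}

#' Group-level activity changes for all TFs and groups
#'
#' @param tfap a `tfap`.
#' @param reference_group baseline group.
#' @return data.frame, one row per (TF, non-reference group) present.
#' @export
tfap_summary <- function(tfap, reference_group = "control") {
  combos <- unique(tfap[tfap$group != reference_group, c("tf_id", "group")])
  combos <- combos[order(combos$tf_id, combos$group), ]
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    group_log2fc(tfap, combos$tf_id[i], combos$group[i], reference_group)
  }))
  rownames(out) <- NULL
  out
}

#' Dunnett-style many-to-one comparisons by Monte Carlo
#'
#' Compares each treatment group to the shared control with Welch t
#' statistics and adjusts for the family by simulating the joint null
#' distribution of max |t| (control draw shared across comparisons, unit
#' normal samples at the observed group sizes). The Monte Carlo adjusted
#' p is capped at the Bonferroni bound `min(1, m * p_welch)`, which is a
#' valid upper bound for many-to-one families.
#'
#' @param control_values numeric control sample (n >= 2).
#' @param treatment_groups named list of numeric samples (each n >= 2).
#' @param n_mc Monte Carlo replicates (a warning below 1000).
#' @param seed integer seed for the null simulation.
#' @return data.frame with `comparison`, `t`, `df`, `p_raw` (unadjusted
#'   Welch), `p_adjusted`.
#' @export
dunnett_many_to_one <- function(control_values, treatment_groups,
                                n_mc = 10000, seed = 1L) {
  assert_that(is.list(treatment_groups) && length(treatment_groups) >= 1,
              "at least one treatment group required")
  assert_that(length(control_values) >= 2 &&
                all(lengths(treatment_groups) >= 2),
              "each group needs n >= 2")
  if (n_mc < 1000) warning("n_mc < 1000: Dunnett adjustment will be noisy")
  m <- length(treatment_groups)
  nms <- names(treatment_groups) %||% paste0("trt", seq_len(m))
  obs <- lapply(treatment_groups, function(g) welch_t(g, control_values))
  t_obs <- vapply(obs, `[[`, numeric(1), "t")
  df_obs <- vapply(obs, `[[`, numeric(1), "df")
  p_raw <- vapply(obs, `[[`, numeric(1), "p")

  n0 <- length(control_values)
  ns <- lengths(treatment_groups)
  set.seed(child_seed(seed, "dunnett"))
  ctrl <- matrix(rnorm(n_mc * n0), nrow = n_mc)
  cm <- rowMeans(ctrl)
  cv <- row_vars(ctrl)
  max_abs <- rep(-Inf, n_mc)
  for (j in seq_len(m)) {
    trt <- matrix(rnorm(n_mc * ns[j]), nrow = n_mc)
    tj <- (rowMeans(trt) - cm) / sqrt(row_vars(trt) / ns[j] + cv / n0)
    max_abs <- pmax(max_abs, abs(tj))
  }
  p_mc <- vapply(t_obs, function(t0) {
    (1 + sum(max_abs >= abs(t0))) / (n_mc + 1)
  }, numeric(1))
  data.frame(
    comparison = nms, t = unname(t_obs), df = unname(df_obs),
    p_raw = unname(p_raw),
    p_adjusted = unname(pmin(p_mc, m * p_raw, 1)),
    stringsAsFactors = FALSE
  )
}

#' Classify per-cell TF activity as high or low
#'
#' A cell is "high" iff its activity exceeds the control-group average of
#' its cluster; ties classify as low. Cluster labels come from an external
#' clustering (not computed here).
#'
#' @param cell_activities numeric vector, one value per cell.
#' @param cluster_labels cluster id per cell (same length).
#' @param control_cluster_means named numeric vector: control average
#'   activity per cluster.
#' @return character vector `"high"`/`"low"` per cell.
#' @export
classify_cell_activity <- function(cell_activities, cluster_labels,
                                   control_cluster_means) {
  assert_that(length(cell_activities) == length(cluster_labels),
              "one cluster label per cell required")
  cl <- as.character(cluster_labels)
  missing <- setdiff(unique(cl), names(control_cluster_means))
  if (length(missing)) {
    stop("no control mean for cluster(s): ", paste(missing, collapse = ", "))
  }
  unname(ifelse(cell_activities > control_cluster_means[cl], "high", "low"))
}
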