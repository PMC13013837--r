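# Social-interaction phenotyping: SI-rates, the >4 outlier rule, the
# susceptible/resilient cutoff, day-wise control normalization, Hedge's g
# effect sizes, and the binomial recovery-proportion test.

#' Social interaction rate of a trial
#'
#' Ratio of time in the interaction zone with the display cage occupied to
#' the time with it empty (`direction = "with_over_without"`, the
#' convention under which susceptible animals score below 1). The reversed
#' ratio is available via `direction = "without_over_with"`.
#'
#' @param time_with_mouse,time_no_mouse seconds in the interaction zone
#'   (vectorized).
#' @param direction which ratio to form.
#' @return numeric SI-rates; `NA` (with a warning) where the denominator
#'   is zero — such trials are excluded downstream.
#' @export
si_rate <- function(time_with_mouse, time_no_mouse,
                    direction = c("with_over_without", "without_over_with")) {
  direction <- match.arg(direction)
  assert_that(all(time_with_mouse >= 0) && all(time_no_mouse >= 0),
              "zone times must be nonnegative")
  num <- if (direction == "with_over_without") time_with_mouse else time_no_mouse
  den <- if (direction == "with_over_without") time_no_mouse else time_with_mouse
  bad <- den == 0
  if (any(bad)) {
    warning(sum(bad), " trial(s) with zero denominator time: SI-rate undefined, excluded")
  }
  out <- num / den
  out[bad] <- NA_real_
  out
}

#' Flag SI-rate outliers
#'
#' Excludes trials whose SI-rate is strictly larger than 4; the boundary
#' value 4.0 is retained. Undefined (NA) SI-rates are also flagged.
#'
#' @param si_rates numeric vector.
#' @param threshold exclusion threshold (default 4).
#' @return logical vector, `TRUE` = excluded.
#' @export
apply_outlier_rule <- function(si_rates, threshold = 4) {
  is.na(si_rates) | si_rates > threshold
}

#' Classify animals as susceptible, resilient or control
#'
#' Stressed animals with SI-rate < 1 are susceptible, >= 1 resilient;
#' non-stressed animals are controls regardless of SI-rate. Excluded
#' (outlier) trials must not be passed in.
#'
#' @param si_rates numeric vector (no NAs, no excluded trials).
#' @param stressed logical vector: was the animal defeated?
#' @return character vector in `{susceptible, resilient, control}`.
#' @export
classify_phenotype <- function(si_rates, stressed) {
  assert_that(length(si_rates) == length(stressed),
              "si_rates and stressed must align")
  if (any(is.na(si_rates))) {
    stop("excluded/undefined trials cannot be classified; drop them first")
  }
  ifelse(!stressed, "control",
         ifelse(si_rates < 1, "susceptible", "resilient"))
}

#' Normalize SI-rates to the day-matched control average
#'
#' For time-course analysis, each trial's SI-rate is divided by the mean
#' SI-rate of control animals tested the same day.
#'
#' @param trials data.frame with `day`, `group`, `si_rate`.
#' @param control_group name of the control group.
#' @return the input with a `normalized_si` column.
#' @export
normalize_si_by_day <- function(trials, control_group = "control") {
  assert_that(all(c("day", "group", "si_rate") %in% names(trials)),
              "trials must carry day, group, si_rate")
  ctrl <- trials[trials$group == control_group & !is.na(trials$si_rate), ]
  day_mean <- tapply(ctrl$si_rate, ctrl$day, mean)
  missing <- setdiff(unique(as.character(trials$day)), names(day_mean))
  if (length(missing)) {
    stop("no control trials on day(s): ", paste(missing, collapse = ", "))
  }
  trials$normalized_si <- trials$si_rate /
    as.numeric(day_mean[as.character(trials$day)])
  trials
}

#' Hedge's g standardized mean difference
#'
#' Bias-corrected Cohen's d:
#' `g = (meanA - meanB) / s_pooled * J`, `J = 1 - 3 / (4(nA + nB) - 9)`,
#' with the pooled SD weighted by degrees of freedom. Used on raw SI-rate
#' scores to quantify drug effects on behavior.
#'
#' @param a,b numeric samples, each n >= 2.
#' @return g (signed).
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  assert_that(na >= 2 && nb >= 2, "hedges_g: each group needs n >= 2")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("hedges_g: zero pooled SD")
  J <- 1 - 3 / (4 * (na + nb) - 9)
  (mean(a) - mean(b)) / sqrt(sp2) * J
}

#' Recovery-proportion test against vehicle controls
#'
#' For each treated cohort, tests whether the proportion of animals not
#' exhibiting depressive symptoms (a per-animal boolean flag; default
#' criterion elsewhere in the pipeline: normalized SI-rate >= 1) differs
#' from the vehicle proportion, using the exact two-sided
#' (minimum-likelihood) binomial test, Holm-corrected across cohorts.
#'
#' @param cohort_flags named list of logical vectors, one per cohort.
#' @param vehicle_flags logical vector for the vehicle cohort; its mean is
#'   the null proportion and must lie strictly inside (0, 1).
#' @param m_comparisons family size for Holm (default: number of cohorts).
#' @return data.frame with `cohort`, `n`, `k`, `proportion`, `p`, `p_holm`.
#' @export
recovery_proportion_test <- function(cohort_flags, vehicle_flags,
                                     m_comparisons = length(cohort_flags)) {
  p0 <- mean(vehicle_flags)
  if (p0 <= 0 || p0 >= 1) {
    stop("degenerate null: vehicle proportion must be strictly inside (0, 1)")
  }
  res <- do.call(rbind, lapply(names(cohort_flags), function(nm) {
    fl <- cohort_flags[[nm]]
    k <- sum(fl); n <- length(fl)
    data.frame(cohort = nm, n = n, k = k, proportion = k / n,
               p = binom_test_minlik(k, n, p0), stringsAsFactors = FALSE)
  }))
  res$p_holm <- holm_adjust(res$p, m = m_comparisons)
  rownames(res) <- NULL
  res
}
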