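# Absolute qPCR quantification: standard curves, Cq -> copies inversion,
# and the raw reporter:reference activity ratio.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 template copies. Amplification
#' efficiency follows the standard qPCR convention
#' `E = 10^(-1/slope) - 1`, so the canonical slope of -3.321928 cycles per
#' tenfold dilution gives E = 1 (100%).
#'
#' @param series a `qpcr_standard_series` (see
#'   [simulate_standard_series()]) or a data.frame with columns
#'   `log10_copies` and `cq_cycles`.
#' @return object of class `standard_curve` with `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `target_id`.
#' @export
fit_standard_curve <- function(series) {
  pts <- if (inherits(series, "qpcr_standard_series")) series$points else series
  target <- if (inherits(series, "qpcr_standard_series")) series$target_id else "std"
  assert_that(is.data.frame(pts) &&
                all(c("log10_copies", "cq_cycles") %in% names(pts)),
              "series must carry log10_copies and cq_cycles")
  assert_that(nrow(pts) >= 3, "standard-curve fit needs >= 3 points")
  fit <- lm(cq_cycles ~ log10_copies, data = pts)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("standard-curve fit error: nonnegative slope (", format(slope),
         "); Cq must decrease with template amount")
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((pts$cq_cycles - mean(pts$cq_cycles))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(
    target_id = target, slope = slope, intercept = unname(coef(fit)[1]),
    efficiency = 10^(-1 / slope) - 1, r_squared = r2
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s: slope %.4f, intercept %.3f, E = %.1f%%, r2 = %.5f\n",
              x$target_id, x$slope, x$intercept, 100 * x$efficiency,
              x$r_squared))
  invisible(x)
}

#' Convert Cq values to absolute template copies
#'
#' Inverts the standard curve: `copies = 10^((cq - intercept)/slope)`.
#' Estimates below one copy are allowed (absolute quantification can yield
#' fractional template estimates) but flagged with a warning.
#'
#' @param cq numeric vector of quantification cycles.
#' @param curve a `standard_curve`.
#' @return copies, strictly positive.
#' @export
cq_to_copies <- function(cq, curve) {
  assert_that(inherits(curve, "standard_curve"), "curve must be a standard_curve")
  copies <- 10^((cq - curve$intercept) / curve$slope)
  if (any(copies < 1)) {
    warning(sum(copies < 1), " Cq value(s) correspond to < 1 template copy")
  }
  copies
}

#' Raw TF activity of a reporter construct
#'
#' The reporter:reference transcript ratio from a single construct. The
#' ratio convention is direction-free: for repressive TFs such as REST,
#' increased activity is still reported as elevation of the
#' reporter-to-reference ratio.
#'
#' @param reporter_copies,reference_copies positive numerics (vectorized).
#' @return `reporter_copies / reference_copies`.
#' @export
raw_activity <- function(reporter_copies, reference_copies) {
  if (any(!is.finite(reference_copies)) || any(reference_copies <= 0)) {
    stop("undefined activity: reference copies must be positive and finite")
  }
  if (any(!is.finite(reporter_copies)) || any(reporter_copies <= 0)) {
    stop("undefined activity: reporter copies must be positive and finite")
  }
  reporter_copies / reference_copies
}

#' Attach raw activities to a reporter measurement table
#'
#' @param measurements data.frame with `reporter_copies` and
#'   `reference_copies` (e.g. from [simulate_reporter_counts()]).
#' @return the same data.frame with a `raw_activity` column.
#' @export
compute_measurements <- function(measurements) {
  measurements$raw_activity <- raw_activity(measurements$reporter_copies,
                                            measurements$reference_copies)
  measurements
}
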