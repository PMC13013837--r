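#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef rnorm runif rlnorm sd var pt pf phyper pnorm
#'   pwilcox dbinom complete.cases setNames
#' @importFrom utils read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-component child seed from a root seed
#'
#' All generators in the package draw their randomness from one root seed.
#' Each named stream gets its own deterministic child so that, e.g., adding
#' animals to the behavior simulation cannot perturb the expression matrix.
#' The derivation is `(seed + 7919 * offset(stream)) mod 2147483299` (both
#' constants prime, result always a valid 32-bit R integer).
#'
#' @param seed integer root seed.
#' @param stream one of `"truth"`, `"reporters"`, `"expression"`,
#'   `"behavior"`, `"promoters"`, `"standards"`, `"motifs"`, `"dunnett"`,
#'   `"pipeline"`.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stream) {
  offsets <- c(
    truth = 101L, reporters = 211L, expression = 307L, behavior = 401L,
    promoters = 503L, standards = 601L, motifs = 653L, dunnett = 701L,
    pipeline = 809L
  )
  if (!stream %in% names(offsets)) {
    stop("unknown seed stream: ", stream)
  }
  as.integer((as.numeric(seed) + 7919 * offsets[[stream]]) %% 2147483299)
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(x, path, row.names = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = row.names,
              col.names = TRUE)
  invisible(path)
}
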