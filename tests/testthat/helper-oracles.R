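# Independent oracles and small fixture factories. Every oracle here
# recomputes a quantity by brute force or via a reference routine from
# stats, never by calling the package path it checks.

# Naive PWM scan: enumerate every offset on both strands and recompute the
# log2-odds sum position by position.
oracle_pwm_scan <- function(seq_chr, motif, background = rep(0.25, 4),
                            min_score_bits) {
  bases <- strsplit(toupper(seq_chr), "")[[1]]
  L <- ncol(motif$matrix)
  n <- length(bases)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_at <- function(window) {
    s <- 0
    for (j in seq_len(L)) {
      b <- window[j]
      if (!b %in% c("A", "C", "G", "T")) return(-Inf)
      s <- s + log2(motif$matrix[b, j] / background[match(b, c("A", "C", "G", "T"))])
    }
    s
  }
  rows <- list()
  if (n >= L) {
    for (off in 0:(n - L)) {
      w <- bases[(off + 1):(off + L)]
      s_fwd <- score_at(w)
      if (is.finite(s_fwd) && s_fwd >= min_score_bits) {
        rows[[length(rows) + 1]] <- data.frame(offset = off, strand = "+",
                                               score = s_fwd)
      }
      w_rc <- rev(unname(comp[w]))
      w_rc[is.na(w_rc)] <- "N"
      s_rev <- score_at(w_rc)
      if (is.finite(s_rev) && s_rev >= min_score_bits) {
        rows[[length(rows) + 1]] <- data.frame(offset = off, strand = "-",
                                               score = s_rev)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # first K elements are the "successes"
  mean(hits >= k)
}

# Exact two-sided rank-sum p by enumerating every assignment of the pooled
# values into the two groups.
oracle_ranksum_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); m <- length(y)
  idx <- utils::combn(n + m, n)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u_all <- apply(idx, 2, function(i) sum(r[i])) - n * (n + 1) / 2
  d <- abs(u_obs - n * m / 2)
  mean(abs(u_all - n * m / 2) >= d - 1e-12)
}

# Random reporter-cohort fixture small enough for per-test use.
tiny_config <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_tfs = 6, n_genes = 60, n_drivers = 2, n_animals_per_group = 6,
    battery_size = 3, regulon_size = 8, seed = seed
  ), list(...))
  do.call(sim_config, args)
}
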