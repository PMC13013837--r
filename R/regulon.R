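# Regulon prediction: promoter-window extraction around TSSs, log-odds PWM
# scanning of both strands, and assembly of the TF -> target map.

#' Extract promoter sequences around TSSs
#'
#' Plus-strand genes get the genomic window `[TSS - upstream, TSS + downstream)`;
#' minus-strand genes get the mirrored window reverse-complemented, so the
#' returned sequence always reads 5' upstream to 3' downstream of the gene.
#' Windows are clipped at contig bounds with a warning. Coordinates are
#' BED-style 0-based half-open throughout.
#'
#' @param tss BED6-style data.frame (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`; `start` is the 0-based TSS) or a path to a BED file.
#' @param genome a named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param upstream,downstream window extents in bp (defaults 1000 / 200).
#' @return a `promoter_set`: list with `seqs` (named DNAStringSet) and
#'   `coords` (data.frame with the genomic window actually used).
#' @export
extract_promoters <- function(tss, genome, upstream = 1000, downstream = 200) {
  if (is.character(tss)) tss <- read_bed6(tss)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  assert_that(all(c("chrom", "start", "strand", "name") %in% names(tss)),
              "tss must carry chrom, start, name, strand")
  missing <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing)) {
    stop("TSS contig(s) absent from the genome: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(tss)
  w0 <- ifelse(tss$strand == "+", tss$start - upstream,
               tss$start - downstream + 1L)
  w1 <- w0 + upstream + downstream
  clen <- setNames(Biostrings::width(genome), names(genome))[tss$chrom]
  c0 <- pmax(w0, 0L)
  c1 <- pmin(w1, clen)
  if (any(c0 != w0 | c1 != w1)) {
    warning("promoter window clipped at contig bounds for ",
            sum(c0 != w0 | c1 != w1), " gene(s)")
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(n), function(i) {
    s <- Biostrings::subseq(genome[[tss$chrom[i]]], start = c0[i] + 1L,
                            end = c1[i])
    if (tss$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1)))
  names(seqs) <- tss$name
  structure(list(
    seqs = seqs,
    coords = data.frame(gene = tss$name, chrom = tss$chrom, start = c0,
                        end = c1, strand = tss$strand,
                        stringsAsFactors = FALSE)
  ), class = "promoter_set")
}

#' Read a BED6 file
#' @param path BED file path (tab-separated, no header).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed6 <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(bed) >= 6, "BED6 requires 6 columns (strand needed)")
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  assert_that(all(bed$strand %in% c("+", "-")),
              "BED strand must be '+' or '-'")
  bed[, 1:6]
}

#' Write a BED6 data.frame
#' @param bed data.frame with chrom, start, end, name, score, strand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(bed, path) {
  write.table(bed[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

base_codes <- function(seq_chr) {
  # A=1 C=2 G=3 T=4, anything else (N, IUPAC) = 5 which scores -Inf
  code <- match(strsplit(toupper(seq_chr), "")[[1]], DNA_BASES)
  code[is.na(code)] <- 5L
  code
}

#' Log2-odds scoring matrix of a motif
#'
#' @param motif a [tfap_motif].
#' @param background length-4 base frequencies (A, C, G, T), summing to 1.
#' @return 5 x L matrix in bits; row 5 (ambiguous base) is `-Inf`.
#' @export
pwm_log_odds <- function(motif, background = rep(0.25, 4)) {
  assert_that(abs(sum(background) - 1) < 1e-9,
              "background frequencies must sum to 1")
  lom <- log2(motif$matrix / background)
  rbind(lom, `N` = rep(-Inf, ncol(lom)))
}

scan_one_strand <- function(codes, lom) {
  L <- ncol(lom)
  n_off <- length(codes) - L + 1L
  if (n_off < 1L) return(numeric(0))
  acc <- numeric(n_off)
  for (j in seq_len(L)) {
    acc <- acc + lom[codes[j:(j + n_off - 1L)], j]
  }
  acc
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every offset on the forward sequence and on its reverse
#' complement with the motif's log2-odds matrix; reverse-strand hits are
#' reported at the forward-coordinate offset of the site's leftmost base.
#' Positions containing `N` score `-Inf` and can never reach a finite
#' threshold.
#'
#' @param sequence character string or [Biostrings::DNAString].
#' @param motif a [tfap_motif].
#' @param background length-4 base frequencies.
#' @param min_score_bits report hits with score >= this threshold.
#' @return data.frame with `offset` (0-based), `strand`, `score`; empty if
#'   the motif is longer than the sequence.
#' @export
pwm_scan <- function(sequence, motif, background = rep(0.25, 4),
                     min_score_bits) {
  seq_chr <- as.character(sequence)
  lom <- pwm_log_odds(motif, background)
  L <- ncol(motif$matrix)
  codes <- base_codes(seq_chr)
  n <- length(codes)
  fwd <- scan_one_strand(codes, lom)
  # reverse strand: scan the reverse complement, map offset o (0-based on
  # the revcomp) back to forward offset n - o - L
  rc_codes <- rev(5L - ifelse(codes == 5L, 0L, codes))
  rc_codes[rc_codes == 5L | rc_codes < 1L] <- 5L
  rev_ <- scan_one_strand(rc_codes, lom)
  hits <- list()
  if (length(fwd)) {
    keep <- which(fwd >= min_score_bits)
    if (length(keep)) {
      hits[[1]] <- data.frame(offset = keep - 1L, strand = "+",
                              score = fwd[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(rev_)) {
    keep <- which(rev_ >= min_score_bits)
    if (length(keep)) {
      hits[[length(hits) + 1L]] <- data.frame(offset = n - (keep - 1L) - L,
                                              strand = "-", score = rev_[keep],
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum achievable log2-odds score of a motif
#' @param motif a [tfap_motif].
#' @param background length-4 base frequencies.
#' @return score in bits.
#' @export
pwm_max_score <- function(motif, background = rep(0.25, 4)) {
  lom <- pwm_log_odds(motif, background)[1:4, , drop = FALSE]
  sum(apply(lom, 2, max))
}

new_regulon_map <- function(targets, best_scores, threshold_policy, threshold) {
  structure(list(targets = targets, best_scores = best_scores,
                 threshold_policy = threshold_policy, threshold = threshold),
            class = "regulon_map")
}

#' @export
print.regulon_map <- function(x, ...) {
  sizes <- lengths(x$targets)
  cat("<regulon_map>", length(x$targets), "TFs; regulon sizes",
      min(sizes), "-", max(sizes), "(policy:", x$threshold_policy, ")\n")
  invisible(x)
}

#' Predict regulons by scanning promoters with TF motifs
#'
#' A gene joins TF t's regulon iff its promoter has at least one PWM hit
#' (either strand) at or above the threshold; the best score per gene is
#' retained. Membership is a set, so palindromic motifs hitting both
#' strands at one site count once.
#'
#' @param promoters a `promoter_set` from [extract_promoters()] or a named
#'   [Biostrings::DNAStringSet].
#' @param motifs named list of [tfap_motif] objects.
#' @param threshold_policy `"fraction"` (threshold = `threshold` x the
#'   motif's maximum achievable score, default) or `"bits"` (absolute).
#' @param threshold numeric; fraction in `(0, 1]` or bits.
#' @param background length-4 base frequencies.
#' @return a `regulon_map`; TFs whose regulon is empty are kept and flagged
#'   via a warning.
#' @export
build_regulon_map <- function(promoters, motifs,
                              threshold_policy = c("fraction", "bits"),
                              threshold = 0.8, background = rep(0.25, 4)) {
  threshold_policy <- match.arg(threshold_policy)
  seqs <- if (inherits(promoters, "promoter_set")) promoters$seqs else promoters
  assert_that(length(seqs) >= 1 && length(motifs) >= 1,
              "need at least one promoter and one motif")
  seq_chr <- as.character(seqs)
  targets <- list()
  scores <- list()
  for (tf in names(motifs)) {
    m <- motifs[[tf]]
    thr <- if (threshold_policy == "fraction") {
      threshold * pwm_max_score(m, background)
    } else threshold
    best <- vapply(seq_chr, function(s) {
      h <- pwm_scan(s, m, background, min_score_bits = thr)
      if (nrow(h)) max(h$score) else NA_real_
    }, numeric(1), USE.NAMES = FALSE)
    names(best) <- names(seqs)
    hit <- !is.na(best)
    targets[[tf]] <- names(seqs)[hit]
    scores[[tf]] <- best[hit]
  }
  empty <- names(targets)[lengths(targets) == 0]
  if (length(empty)) {
    warning("empty regulon for: ", paste(empty, collapse = ", "))
  }
  new_regulon_map(targets, scores, threshold_policy, threshold)
}

#' Regulon map as a long data.frame
#' @param x a `regulon_map`.
#' @param ... unused.
#' @return data.frame with tf_id, gene, best_score_bits.
#' @export
as.data.frame.regulon_map <- function(x, ...) {
  rows <- lapply(names(x$targets), function(tf) {
    g <- x$targets[[tf]]
    if (!length(g)) return(NULL)
    data.frame(tf_id = tf, gene = g,
               best_score_bits = as.numeric(x$best_scores[[tf]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf_id = character(0), gene = character(0),
                      best_score_bits = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Write a regulon map as GMT gene sets
#' @param map a `regulon_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tf in names(map$targets)) {
    writeLines(paste(c(tf, "tfap_regulon", map$targets[[tf]]),
                     collapse = "\t"), con)
  }
  invisible(path)
}
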