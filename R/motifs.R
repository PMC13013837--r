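# Position frequency matrices: construction, JASPAR-style text I/O, and
# random sharply-peaked motifs for the synthetic generator.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a TF binding motif
#'
#' Stores a 4 x L position matrix (rows A, C, G, T). Counts or frequencies
#' are accepted; columns are regularized with a per-cell pseudocount and
#' renormalized to probabilities, so each column sums to one.
#'
#' @param tf_id TF name the motif belongs to.
#' @param matrix numeric 4 x L matrix, L >= 4; rownames `A,C,G,T` assumed
#'   in that order if absent.
#' @param pseudocount added to every cell (after scaling columns to sum 1)
#'   before renormalization; default 0.01.
#' @return object of class `tfap_motif`.
#' @export
tfap_motif <- function(tf_id, matrix, pseudocount = 0.01) {
  m <- as.matrix(matrix)
  assert_that(nrow(m) == 4, "motif matrix must have 4 rows (A, C, G, T)")
  assert_that(ncol(m) >= 4, "motif length must be >= 4")
  assert_that(all(m >= 0), "motif matrix entries must be nonnegative")
  m <- sweep(m, 2, colSums(m), "/")          # to frequencies
  m <- m + pseudocount
  m <- sweep(m, 2, colSums(m), "/")          # renormalize
  rownames(m) <- DNA_BASES
  structure(list(tf_id = tf_id, matrix = m, pseudocount = pseudocount),
            class = "tfap_motif")
}

#' @export
print.tfap_motif <- function(x, ...) {
  cat("<tfap_motif>", x$tf_id, "length", ncol(x$matrix),
      "consensus", motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a motif (most probable base per column)
#' @param motif a [tfap_motif].
#' @return character string of length L.
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$matrix, 2, which.max)], collapse = "")
}

#' Generate random sharply-peaked motifs
#'
#' One motif per TF: a random consensus with probability `peak` on the
#' consensus base and the remainder spread evenly — informative enough that
#' implanted sites are recovered at stringent scan thresholds while random
#' background rarely matches.
#'
#' @param tf_ids character vector of TF names.
#' @param length_range motif lengths drawn uniformly from this range.
#' @param peak consensus-base probability per column.
#' @param seed integer seed.
#' @return named list of [tfap_motif] objects.
#' @export
make_motifs <- function(tf_ids, length_range = c(8, 12), peak = 0.85,
                        seed = 1L) {
  set.seed(seed)
  lens <- seq(length_range[1], length_range[2])
  out <- lapply(tf_ids, function(tf) {
    L <- lens[sample.int(length(lens), 1)] # guard against sample(n, 1) scalar rule
    cons <- sample.int(4, L, replace = TRUE)
    m <- matrix((1 - peak) / 3, nrow = 4, ncol = L)
    m[cbind(cons, seq_len(L))] <- peak
    tfap_motif(tf, m)
  })
  names(out) <- tf_ids
  out
}

#' Read motifs from JASPAR PFM text
#'
#' Parses the four-row bracketed JASPAR format:
#' ```
#' >MA0001.1 TF01
#' A [ 10  2 ... ]
#' C [  1  0 ... ]
#' ...
#' ```
#' The second header token (or the accession if absent) becomes `tf_id`.
#'
#' @param path file path.
#' @param pseudocount passed to [tfap_motif()].
#' @return named list of [tfap_motif] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- grep("^>", lines)
  assert_that(length(idx) >= 1, "no motif headers found in ", path)
  out <- list()
  for (i in seq_along(idx)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[idx[i]]), "\\s+")[[1]]
    tf <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    body <- lines[(idx[i] + 1):(idx[i] + 4)]
    rows <- lapply(body, function(l) {
      nums <- gsub("^[ACGTacgt]?\\s*\\[|\\]\\s*$", "", trimws(l))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    assert_that(length(unique(lengths(rows))) == 1,
                "ragged PFM rows for motif ", tf)
    out[[tf]] <- tfap_motif(tf, do.call(rbind, rows), pseudocount)
  }
  out
}

#' Write motifs as JASPAR PFM text
#'
#' @param motifs named list of [tfap_motif] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(sprintf(">%s %s", sprintf("MA%04d.1", i), m$tf_id), con)
    for (r in 1:4) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[r],
                         paste(sprintf("%.6f", m$matrix[r, ]), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
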