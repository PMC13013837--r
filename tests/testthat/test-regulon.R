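toy_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

test_that("extract_promoters uses BED 0-based half-open windows per strand", {
  set.seed(2)
  chr <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  genome <- toy_genome(c(chr1 = chr))
  tss <- data.frame(chrom = "chr1", start = c(1000L, 1000L), end = 1001L,
                    name = c("plus_g", "minus_g"), score = 0,
                    strand = c("+", "-"))
  ps <- extract_promoters(tss, genome, upstream = 500, downstream = 100)
  # plus strand: genomic slice [500, 1100)
  expect_equal(as.character(ps$seqs[["plus_g"]]), substr(chr, 501, 1100))
  # minus strand: mirrored window [901, 1501) reverse-complemented
  mirror <- substr(chr, 902, 1501)
  expect_equal(as.character(ps$seqs[["minus_g"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(mirror))))
  expect_equal(unique(Biostrings::width(ps$seqs)), 600)

  # clipping at the contig start warns and shortens
  tss2 <- data.frame(chrom = "chr1", start = 10L, end = 11L, name = "edge",
                     score = 0, strand = "+")
  expect_warning(ps2 <- extract_promoters(tss2, genome, 500, 100), "clipped")
  expect_equal(Biostrings::width(ps2$seqs["edge"]), 110)

  tss3 <- transform(tss2, chrom = "chrX")
  expect_error(extract_promoters(tss3, genome, 500, 100), "chrX")
})

test_that("pwm_scan finds an embedded consensus exactly once at the max score", {
  m <- make_motifs("M", length_range = c(8, 8), seed = 5)[[1]]
  cons <- motif_consensus(m)
  set.seed(7)
  bg <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  bg[101:108] <- strsplit(cons, "")[[1]]
  s <- paste(bg, collapse = "")
  hits <- pwm_scan(s, m, min_score_bits = pwm_max_score(m) - 1e-9)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 100)
  expect_equal(hits$strand, "+")

  # reverse-complemented input: same hits with strands flipped, offsets mirrored
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  hits_rc <- pwm_scan(rc, m, min_score_bits = pwm_max_score(m) - 1e-9)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$offset, nchar(s) - 100 - 8)
  expect_equal(hits_rc$score, hits$score, tolerance = 1e-12)

  # motif longer than sequence -> empty hit list
  expect_equal(nrow(pwm_scan("ACGT", m, min_score_bits = -100)), 0)
  # N positions can never match a finite threshold
  expect_equal(nrow(pwm_scan(strrep("N", 50), m, min_score_bits = -1e6)), 0)
})

test_that("pwm_scan agrees exactly with the brute-force oracle", {
  set.seed(99)
  motifs <- make_motifs(paste0("M", 1:3), length_range = c(5, 9), seed = 6)
  for (rep_i in 1:12) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 120,
                      replace = TRUE, prob = c(rep(0.245, 4), 0.02)),
               collapse = "")
    m <- motifs[[sample(3, 1)]]
    thr <- runif(1, -5, 5)
    got <- pwm_scan(s, m, min_score_bits = thr)
    want <- oracle_pwm_scan(s, m, min_score_bits = thr)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("regulon maps shrink monotonically with threshold and flag emptiness", {
  cfg <- tiny_config(seed = 41, n_genes = 30, regulon_size = 5)
  tr <- make_truth(cfg)
  motifs <- make_motifs(tr$tf_ids, seed = 4)
  sim <- simulate_promoters(tr, motifs, cfg)
  prom <- extract_promoters(sim$tss, sim$genome, cfg$promoter_upstream,
                            cfg$promoter_downstream)

  m80 <- build_regulon_map(prom, motifs, threshold = 0.80)
  m95 <- build_regulon_map(prom, motifs, threshold = 0.95)
  for (tf in tr$tf_ids) {
    expect_true(all(m95$targets[[tf]] %in% m80$targets[[tf]]))
    # implanted sites guarantee the true regulon is contained
    expect_true(all(tr$gene_ids[tr$regulon_weights[tf, ] != 0] %in%
                      m95$targets[[tf]]))
  }
  # determinism
  expect_identical(m80, build_regulon_map(prom, motifs, threshold = 0.80))

  # threshold above the max achievable score empties every regulon
  expect_warning(
    m_hi <- build_regulon_map(prom, motifs["TF01"], threshold_policy = "bits",
                              threshold = 1e6),
    "empty regulon")
  expect_equal(lengths(m_hi$targets)[["TF01"]], 0L)

  df <- as.data.frame(m95)
  expect_true(all(c("tf_id", "gene", "best_score_bits") %in% names(df)))
})

test_that("JASPAR text round-trips motifs", {
  motifs <- make_motifs(c("TFA", "TFB"), seed = 9)
  path <- tempfile(fileext = ".jaspar")
  on.exit(unlink(path))
  write_jaspar(motifs, path)
  # the stored matrix is already pseudocount-regularized; read it back raw
  back <- read_jaspar(path, pseudocount = 0)
  expect_equal(names(back), c("TFA", "TFB"))
  for (tf in names(motifs)) {
    expect_equal(back[[tf]]$matrix, motifs[[tf]]$matrix, tolerance = 1e-4)
    expect_equal(motif_consensus(back[[tf]]), motif_consensus(motifs[[tf]]))
  }
  expect_error(tfap_motif("X", matrix(0.25, 4, 3)), "length")
  expect_error(tfap_motif("X", matrix(0.25, 3, 8)), "4 rows")
})
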