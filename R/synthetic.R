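# Synthetic-cohort generator with known ground truth. The generator
# emulates the study design it is meant to test: latent per-group TF
# activities read out by reporter/reference constructs delivered in
# batteries of at most six per animal, a TF-weighted log-linear
# transcriptome, social-interaction behavior coupled to the driver TFs,
# promoters carrying implanted binding sites, and qPCR standard curves.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic cohort. Defaults describe the
#' reference scenario used throughout the test suite: 30 TFs of which 2 are
#' true drivers with a +0.5 log2 activity shift in the stressed group,
#' regulons of 30 genes with unit weight, 10 animals per group, reporter
#' batteries of 6 constructs, and Gaussian log2-scale expression noise of
#' SD 0.25.
#'
#' @param n_tfs number of TF reporters in the panel.
#' @param n_genes number of genes in the transcriptome.
#' @param n_drivers number of true driver TFs (first `n_drivers` TFs).
#' @param n_animals_per_group animals per group in the reporter cohort.
#' @param groups character vector of group names; the first is the control.
#' @param battery_size constructs delivered per animal, in `[1, 6]`.
#' @param regulon_size true targets per TF.
#' @param effect_log2fc driver activity shift (log2) in non-control groups.
#' @param regulon_weight weight linking driver activity to target expression.
#' @param baseline_expr_range range of per-gene baseline log2 expression.
#' @param gene_length_range range of simulated transcript lengths (bp).
#' @param behavior_baseline control-group SI-rate baseline.
#' @param behavior_coupling per-driver coefficient linking activity (log2)
#'   to SI-rate; negative values model sociality loss when drivers rise.
#' @param behavior_time_no_mouse seconds in the interaction zone with the
#'   display cage empty (used to back-compute zone times from SI-rates).
#' @param reference_meanlog,reference_sdlog lognormal parameters for
#'   reference-transcript copies per construct.
#' @param noise_sd_reporter SD of reporter multiplicative noise, log2 scale.
#' @param noise_sd_expr SD of expression noise, log2 scale.
#' @param noise_sd_behavior SD of additive SI-rate noise.
#' @param promoter_upstream,promoter_downstream promoter window around the
#'   TSS (bp).
#' @param seed root seed; all generators derive child seeds from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_tfs = 30, n_genes = 1000, n_drivers = 2,
                       n_animals_per_group = 10,
                       groups = c("control", "susceptible"),
                       battery_size = 6, regulon_size = 30,
                       effect_log2fc = 0.5, regulon_weight = 1,
                       baseline_expr_range = c(5, 12),
                       gene_length_range = c(500, 3000),
                       behavior_baseline = 1.3,
                       behavior_coupling = -0.5,
                       behavior_time_no_mouse = 50,
                       reference_meanlog = log(1e4),
                       reference_sdlog = 0.3,
                       noise_sd_reporter = 0.1,
                       noise_sd_expr = 0.25,
                       noise_sd_behavior = 0.15,
                       promoter_upstream = 1000,
                       promoter_downstream = 200,
                       seed = 1L) {
  cfg <- list(
    n_tfs = n_tfs, n_genes = n_genes, n_drivers = n_drivers,
    n_animals_per_group = n_animals_per_group, groups = groups,
    battery_size = battery_size, regulon_size = regulon_size,
    effect_log2fc = effect_log2fc, regulon_weight = regulon_weight,
    baseline_expr_range = baseline_expr_range,
    gene_length_range = gene_length_range,
    behavior_baseline = behavior_baseline,
    behavior_coupling = behavior_coupling,
    behavior_time_no_mouse = behavior_time_no_mouse,
    reference_meanlog = reference_meanlog,
    reference_sdlog = reference_sdlog,
    noise_sd_reporter = noise_sd_reporter,
    noise_sd_expr = noise_sd_expr,
    noise_sd_behavior = noise_sd_behavior,
    promoter_upstream = promoter_upstream,
    promoter_downstream = promoter_downstream,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$battery_size >= 1 && cfg$battery_size <= 6,
              "battery_size must be in [1, 6] (at most six constructs per animal)")
  assert_that(cfg$n_tfs >= 1 && cfg$n_genes >= 1 && cfg$n_animals_per_group >= 1,
              "n_tfs, n_genes and n_animals_per_group must all be >= 1")
  assert_that(cfg$n_drivers >= 0, "n_drivers must be >= 0")
  assert_that(cfg$n_drivers <= cfg$n_tfs, "n_drivers cannot exceed n_tfs")
  assert_that(cfg$regulon_size >= 1 && cfg$regulon_size <= cfg$n_genes,
              "regulon_size must be in [1, n_genes]")
  assert_that(length(cfg$groups) >= 1, "at least one group (the control) required")
  assert_that(all(c(cfg$noise_sd_reporter, cfg$noise_sd_expr,
                    cfg$noise_sd_behavior) >= 0),
              "noise SDs must be nonnegative")
  invisible(cfg)
}

#' Draw the ground truth of a synthetic cohort
#'
#' Builds the latent state every downstream estimate is checked against:
#' TF identities, the driver subset, per-group activity log2 fold changes
#' (zero for the control group and for all non-drivers), the TF-by-gene
#' regulon weight matrix whose row support defines the true regulons,
#' per-gene baseline log2 expression, and the driver-to-behavior couplings.
#'
#' @param config a [sim_config()].
#' @return object of class `tfap_truth`.
#' @export
make_truth <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "truth"))
  tf_ids <- sprintf("TF%02d", seq_len(config$n_tfs))
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  drivers <- tf_ids[seq_len(config$n_drivers)]

  activity <- matrix(0, nrow = config$n_tfs, ncol = length(config$groups),
                     dimnames = list(tf_ids, config$groups))
  if (length(config$groups) > 1 && config$n_drivers > 0) {
    activity[drivers, config$groups[-1]] <- config$effect_log2fc
  }

  weights <- matrix(0, nrow = config$n_tfs, ncol = config$n_genes,
                    dimnames = list(tf_ids, gene_ids))
  # Driver regulons are disjoint gene modules, and non-driver regulons are
  # drawn from the unshifted remainder (they may overlap each other), so at
  # zero noise each driver's mean target shift equals its activity shift
  # exactly and every non-driver's is exactly zero. Falls back to free
  # sampling if the gene pool is too small to honor the partition.
  pool <- seq_len(config$n_genes)
  driver_idx <- match(drivers, tf_ids)
  for (t in driver_idx) {
    if (length(pool) >= config$regulon_size) {
      take <- sample(pool, config$regulon_size)
      pool <- setdiff(pool, take)
    } else {
      take <- sample.int(config$n_genes, config$regulon_size)
    }
    weights[t, take] <- config$regulon_weight
  }
  for (t in setdiff(seq_len(config$n_tfs), driver_idx)) {
    take <- if (length(pool) >= config$regulon_size) {
      sample(pool, config$regulon_size)
    } else {
      sample.int(config$n_genes, config$regulon_size)
    }
    weights[t, take] <- config$regulon_weight
  }

  baseline <- runif(config$n_genes, config$baseline_expr_range[1],
                    config$baseline_expr_range[2])
  names(baseline) <- gene_ids

  coupling <- setNames(rep(config$behavior_coupling, config$n_drivers), drivers)

  structure(list(
    tf_ids = tf_ids, gene_ids = gene_ids, driver_set = drivers,
    activity_log2fc = activity, regulon_weights = weights,
    baseline_expr = baseline, behavior_coupling = coupling,
    groups = config$groups, seed = config$seed
  ), class = "tfap_truth")
}

#' True regulon map from a simulation truth
#'
#' The row support of `regulon_weights` as a [regulon_map] object, usable
#' wherever a motif-derived map is, e.g. to test the integration stage in
#' isolation from the promoter scanner.
#'
#' @param truth a `tfap_truth`.
#' @return a `regulon_map` (targets only; best scores set to `NA`).
#' @export
regulon_map_from_truth <- function(truth) {
  targets <- lapply(seq_along(truth$tf_ids), function(t) {
    truth$gene_ids[truth$regulon_weights[t, ] != 0]
  })
  names(targets) <- truth$tf_ids
  scores <- lapply(targets, function(g) setNames(rep(NA_real_, length(g)), g))
  new_regulon_map(targets, scores, threshold_policy = "truth", threshold = NA_real_)
}

# Battery panels: TFs are split into ceiling(n_tfs / battery_size) fixed
# panels and animals cycle through the panels within each group, so every
# TF is measured in every group whenever n_animals_per_group >= n_panels.
battery_panels <- function(tf_ids, battery_size) {
  split(tf_ids, ceiling(seq_along(tf_ids) / battery_size))
}

#' Simulate reporter/reference transcript copies
#'
#' Each animal carries one battery of at most six reporter constructs; a
#' construct's reference transcript is drawn lognormally (constitutive PGK
#' promoter) and its reporter transcript equals
#' `reference * 2^activity_log2fc * 2^eps` with
#' `eps ~ N(0, noise_sd_reporter)` — multiplicative lognormal noise, so the
#' reporter:reference ratio stays positive and ratio-scaled.
#'
#' @param truth a `tfap_truth`.
#' @param config the matching [sim_config()].
#' @return data.frame with columns `animal_id`, `experiment_id`, `group`,
#'   `tf_id`, `reporter_copies`, `reference_copies`.
#' @export
simulate_reporter_counts <- function(truth, config) {
  assert_that(identical(truth$tf_ids, sprintf("TF%02d", seq_len(config$n_tfs))),
              "truth and config disagree on the TF panel")
  set.seed(child_seed(config$seed, "reporters"))
  panels <- battery_panels(truth$tf_ids, config$battery_size)
  n_panels <- length(panels)
  if (config$n_animals_per_group < n_panels) {
    warning("fewer animals per group (", config$n_animals_per_group,
            ") than battery panels (", n_panels,
            "): some TFs will be unmeasured in some groups")
  }
  rows <- list()
  for (g in truth$groups) {
    for (i in seq_len(config$n_animals_per_group)) {
      p <- ((i - 1) %% n_panels) + 1
      tfs <- panels[[p]]
      ref <- rlnorm(length(tfs), config$reference_meanlog, config$reference_sdlog)
      eps <- rnorm(length(tfs), 0, config$noise_sd_reporter)
      rep_copies <- ref * 2^(truth$activity_log2fc[tfs, g] + eps)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("%s_%02d", g, i),
        experiment_id = sprintf("exp%02d", p),
        group = g, tf_id = tfs,
        reporter_copies = rep_copies, reference_copies = ref,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a transcriptome under the log-linear regulon model
#'
#' Per gene and sample, log2 expression is
#' `baseline + sum_t weight[t, gene] * activity_log2fc[t, group] + eps`,
#' `eps ~ N(0, noise_sd_expr)`. Counts are the rounded linear values; the
#' unrounded linear matrix is returned as `expr` so that noiseless runs can
#' be checked for exact identity (rounding and within-sample TPM
#' renormalization each perturb fold changes at the last decimal).
#'
#' @param truth a `tfap_truth`.
#' @param config the matching [sim_config()].
#' @return list with `counts` (genes x samples integer-valued matrix),
#'   `expr` (unrounded linear matrix), `lengths` (named bp vector),
#'   `sample_groups` (named character vector).
#' @export
simulate_expression <- function(truth, config) {
  assert_that(nrow(truth$regulon_weights) == config$n_tfs &&
                ncol(truth$regulon_weights) == config$n_genes,
              "regulon_weights must be n_tfs x n_genes")
  set.seed(child_seed(config$seed, "expression"))
  samples <- unlist(lapply(truth$groups, function(g)
    sprintf("%s_s%02d", g, seq_len(config$n_animals_per_group))))
  sample_groups <- setNames(rep(truth$groups, each = config$n_animals_per_group),
                            samples)
  # group-level deterministic log2 means: baseline + W' a_g
  shift <- crossprod(truth$regulon_weights, truth$activity_log2fc) # genes x groups
  log2_mean <- outer(truth$baseline_expr, rep(1, length(samples))) +
    shift[, sample_groups, drop = FALSE]
  noise <- matrix(rnorm(length(log2_mean), 0, config$noise_sd_expr),
                  nrow = nrow(log2_mean))
  expr <- 2^(log2_mean + noise)
  dimnames(expr) <- list(truth$gene_ids, samples)
  lengths <- round(runif(config$n_genes, config$gene_length_range[1],
                         config$gene_length_range[2]))
  names(lengths) <- truth$gene_ids
  list(counts = round(expr), expr = expr, lengths = lengths,
       sample_groups = sample_groups)
}

#' Simulate social-interaction trials
#'
#' SI-rate for an animal in group g is
#' `baseline + sum_d coupling[d] * activity_log2fc[d, g] + eps`, floored at
#' zero, with `eps ~ N(0, noise_sd_behavior)`. Interaction-zone times are
#' back-computed so that `time_with_mouse / time_no_mouse` reproduces the
#' simulated SI-rate exactly.
#'
#' @param truth a `tfap_truth`.
#' @param config the matching [sim_config()].
#' @param day integer day label attached to every trial.
#' @return data.frame with columns `animal_id`, `group`, `day`,
#'   `time_no_mouse`, `time_with_mouse`.
#' @export
simulate_behavior <- function(truth, config, day = 1L) {
  set.seed(child_seed(config$seed, "behavior"))
  rows <- lapply(truth$groups, function(g) {
    drift <- if (length(truth$driver_set)) {
      sum(truth$behavior_coupling * truth$activity_log2fc[truth$driver_set, g])
    } else 0
    si <- pmax(0, config$behavior_baseline + drift +
                 rnorm(config$n_animals_per_group, 0, config$noise_sd_behavior))
    data.frame(
      animal_id = sprintf("%s_%02d", g, seq_len(config$n_animals_per_group)),
      group = g, day = as.integer(day),
      time_no_mouse = config$behavior_time_no_mouse,
      time_with_mouse = si * config$behavior_time_no_mouse,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate promoter sequences with implanted binding sites
#'
#' Lays the genes along one synthetic chromosome on alternating strands,
#' fills the sequence with i.i.d. uniform A/C/G/T background, and implants
#' one consensus instance of TF t's motif (strand-aware, non-overlapping
#' within a promoter) into the promoter window of every true target of t.
#'
#' @param truth a `tfap_truth`.
#' @param motifs list of [tfap_motif] objects, one per TF in `truth$tf_ids`.
#' @param config the matching [sim_config()].
#' @return list with `genome` (named [Biostrings::DNAStringSet], one
#'   chromosome), `tss` (BED-style data.frame: chrom, start, end, name,
#'   score, strand; 0-based half-open), and `implants` (data.frame of the
#'   implanted site coordinates).
#' @export
simulate_promoters <- function(truth, motifs, config) {
  assert_that(all(truth$tf_ids %in% names(motifs)),
              "one motif per TF is required")
  win <- config$promoter_upstream + config$promoter_downstream
  max_len <- max(vapply(motifs, function(m) ncol(m$matrix), integer(1)))
  if (max_len > win) {
    stop("motif longer than the promoter window (", win, " bp)")
  }
  set.seed(child_seed(config$seed, "promoters"))
  spacing <- win + 200L
  n <- config$n_genes
  glen <- n * spacing + spacing
  genome_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

  strand <- rep(c("+", "-"), length.out = n)
  # 0-based TSS position, anchored so each promoter window sits inside its
  # spacing slot: plus-strand window is [tss - up, tss + down), minus-strand
  # window is [tss - down + 1, tss + up + 1)
  tss0 <- ifelse(strand == "+",
                 (seq_len(n) - 1L) * spacing + config$promoter_upstream,
                 (seq_len(n) - 1L) * spacing + config$promoter_downstream)
  tss0 <- as.integer(tss0)

  implants <- list()
  occupied <- vector("list", n)
  for (t in seq_along(truth$tf_ids)) {
    tf <- truth$tf_ids[t]
    cons <- motif_consensus(motifs[[tf]])
    L <- nchar(cons)
    targets <- which(truth$regulon_weights[t, ] != 0)
    for (gi in targets) {
      # promoter window in genomic (0-based, half-open) coordinates
      if (strand[gi] == "+") {
        w0 <- tss0[gi] - config$promoter_upstream
      } else {
        w0 <- tss0[gi] - config$promoter_downstream + 1L
      }
      placed <- FALSE
      for (try in 1:200) {
        off <- sample.int(win - L + 1L, 1L) - 1L
        s0 <- w0 + off
        clash <- any(vapply(occupied[[gi]], function(iv)
          s0 < iv[2] && (s0 + L) > iv[1], logical(1)))
        if (!clash) {
          site <- if (strand[gi] == "+") cons else revcomp_chr(cons)
          genome_chars[(s0 + 1):(s0 + L)] <- strsplit(site, "")[[1]]
          occupied[[gi]] <- c(occupied[[gi]], list(c(s0, s0 + L)))
          implants[[length(implants) + 1L]] <- data.frame(
            tf_id = tf, gene = truth$gene_ids[gi], start = s0, end = s0 + L,
            strand = strand[gi], stringsAsFactors = FALSE
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) warning("could not place site for ", tf, " in ",
                           truth$gene_ids[gi])
    }
  }
  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- "chr1"
  tss <- data.frame(
    chrom = "chr1", start = tss0, end = tss0 + 1L, name = truth$gene_ids,
    score = 0L, strand = strand, stringsAsFactors = FALSE
  )
  list(genome = genome, tss = tss,
       implants = do.call(rbind, implants) %||% data.frame())
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate a qPCR standard dilution series
#'
#' `Cq = intercept + slope * log10(copies) + eps`, `eps ~ N(0, noise_sd)`.
#' The canonical 100%-efficiency slope is `-1/log10(2) = -3.321928` cycles
#' per tenfold dilution.
#'
#' @param slope cycles per log10 copies (negative).
#' @param intercept cycles at 1 copy.
#' @param dilutions vector of template copy numbers (>= 3 points, all > 0).
#' @param noise_sd Gaussian Cq noise SD (cycles).
#' @param target_id label for the series.
#' @param seed optional seed; `NULL` leaves the RNG state alone.
#' @return object of class `qpcr_standard_series`.
#' @export
simulate_standard_series <- function(slope, intercept, dilutions,
                                     noise_sd = 0, target_id = "std",
                                     seed = NULL) {
  assert_that(length(dilutions) >= 3,
              "a standard series needs at least 3 dilution points")
  if (any(dilutions <= 0)) stop("standard-series copies must be positive")
  if (!is.null(seed)) set.seed(seed)
  lg <- log10(dilutions)
  cq <- intercept + slope * lg + rnorm(length(lg), 0, noise_sd)
  structure(list(
    target_id = target_id,
    points = data.frame(log10_copies = lg, cq_cycles = cq)
  ), class = "qpcr_standard_series")
}
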