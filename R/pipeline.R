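# Pipeline orchestration: one YAML config with per-stage blocks, a single
# root seed fanned out to every stochastic component, plain-text outputs,
# and a JSON manifest with checksums for reproducibility audits.

pipeline_schema <- list(
  seed = "integer", out_dir = "character",
  stages = list(simulate = "flag", quantify = "flag", profile = "flag",
                behavior = "flag", de = "flag", regulon = "flag",
                integrate = "flag"),
  simulate = list(
    n_tfs = c(1, Inf), n_genes = c(1, Inf), n_drivers = c(0, Inf),
    n_animals_per_group = c(1, Inf), groups = "character",
    battery_size = c(1, 6), regulon_size = c(1, Inf),
    effect_log2fc = c(-Inf, Inf), regulon_weight = c(-Inf, Inf),
    noise_sd_reporter = c(0, Inf), noise_sd_expr = c(0, Inf),
    noise_sd_behavior = c(0, Inf),
    promoter_upstream = c(1, Inf), promoter_downstream = c(0, Inf)
  ),
  behavior = list(si_direction = "character", outlier_threshold = c(0, Inf)),
  de = list(pseudocount = c(0, Inf), p_thresh = c(0, 1), fc_up = c(1, Inf),
            fc_down = c(0, 1), use_q = "flag",
            contrast_group = "character"),
  regulon = list(threshold_policy = "character", threshold = c(0, Inf)),
  integrate = list(discordance_factor = c(0, 1), use_true_regulons = "flag")
)

stage_deps <- list(
  simulate = character(0),
  quantify = "simulate",
  profile = "quantify",
  behavior = "simulate",
  de = "simulate",
  regulon = "simulate",
  integrate = c("profile", "de", "regulon")
)

#' Default pipeline configuration
#'
#' The shipped defaults describe the reference synthetic scenario (see
#' [sim_config()]) with every stage enabled.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  yaml::read_yaml(system.file("extdata", "default_config.yaml",
                              package = "tfap"))
}

#' Validate a pipeline configuration
#'
#' Checks the config against the schema: unknown keys, missing
#' requirements, and out-of-range values are all listed.
#'
#' @param config a configuration list or path to a YAML file.
#' @return character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not readable: ", config)
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  unknown <- setdiff(names(config), names(pipeline_schema))
  for (k in unknown) note("unknown top-level key: ", k)
  if (is.null(config$seed)) note("missing required key: seed")

  for (blk in intersect(names(config), names(pipeline_schema))) {
    spec <- pipeline_schema[[blk]]
    if (!is.list(spec)) next
    for (k in setdiff(names(config[[blk]]), names(spec))) {
      note("unknown key: ", blk, ".", k)
    }
    for (k in intersect(names(config[[blk]]), names(spec))) {
      rule <- spec[[k]]
      v <- config[[blk]][[k]]
      if (is.numeric(rule)) {
        if (!is.numeric(v) || any(v < rule[1]) || any(v > rule[2])) {
          note(blk, ".", k, " = ", paste(v, collapse = ","),
               " out of range [", rule[1], ", ", rule[2], "]")
        }
      } else if (identical(rule, "flag") && !is.logical(v)) {
        note(blk, ".", k, " must be true/false")
      }
    }
  }
  enabled <- names(Filter(isTRUE, config$stages %||% list()))
  for (st in enabled) {
    missing_dep <- setdiff(stage_deps[[st]], enabled)
    if (length(missing_dep)) {
      note("stage '", st, "' enabled but depends on disabled stage(s): ",
           paste(missing_dep, collapse = ", "))
    }
  }
  problems
}

pipeline_log <- function(level, ...) {
  message(format(Sys.time(), "[%H:%M:%S] "), level, " ", ...)
}

#' Run the synthetic TFAP pipeline
#'
#' Executes the enabled stages in dependency order —
#' simulate, quantify, profile, behavior, de, regulon, integrate — writing
#' plain-text outputs under `out_dir` and a `manifest.json` recording the
#' configuration, the seed, every threshold applied, and an MD5 checksum
#' per output file. Identical config and seed give byte-identical outputs.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param seed optional root-seed override.
#' @param out_dir optional output-directory override.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "))
  }
  out <- config$out_dir %||% "tfap_run"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  enabled <- names(Filter(isTRUE, config$stages))
  run_stage <- function(st) st %in% enabled
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  simcfg <- do.call(sim_config, c(config$simulate %||% list(),
                                  list(seed = config$seed)))
  st <- list() # in-memory stage products

  if (run_stage("simulate")) {
    pipeline_log("INFO", "simulate: ", simcfg$n_tfs, " TFs, ",
                 simcfg$n_genes, " genes, seed ", simcfg$seed)
    st$truth <- make_truth(simcfg)
    st$motifs <- make_motifs(st$truth$tf_ids,
                             seed = child_seed(simcfg$seed, "motifs"))
    st$reporters <- simulate_reporter_counts(st$truth, simcfg)
    st$exprsim <- simulate_expression(st$truth, simcfg)
    st$behavior_trials <- simulate_behavior(st$truth, simcfg)
    st$prom <- simulate_promoters(st$truth, st$motifs, simcfg)
    emit(write_tsv(st$reporters, file.path(out, "reporters.tsv")))
    emit(write_tsv(st$behavior_trials, file.path(out, "behavior.tsv")))
    emit(write_tsv(data.frame(gene = names(st$exprsim$lengths),
                              length_bp = st$exprsim$lengths),
                   file.path(out, "lengths.tsv")))
    counts_df <- data.frame(gene = rownames(st$exprsim$counts),
                            st$exprsim$counts, check.names = FALSE)
    emit(write_tsv(counts_df, file.path(out, "counts.tsv")))
    Biostrings::writeXStringSet(st$prom$genome, file.path(out, "genome.fasta"))
    emit(file.path(out, "genome.fasta"))
    emit(write_bed6(st$prom$tss, file.path(out, "tss.bed")))
    emit(write_jaspar(st$motifs, file.path(out, "motifs.jaspar")))
    truth_json <- file.path(out, "truth.json")
    jsonlite::write_json(list(
      tf_ids = st$truth$tf_ids, driver_set = st$truth$driver_set,
      groups = st$truth$groups, seed = st$truth$seed,
      activity_log2fc = as.data.frame(st$truth$activity_log2fc),
      behavior_coupling = as.list(st$truth$behavior_coupling)
    ), truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(truth_json)
  }

  if (run_stage("quantify")) {
    st$measurements <- compute_measurements(st$reporters)
    pipeline_log("INFO", "quantify: ", nrow(st$measurements),
                 " reporter measurements")
    emit(write_tsv(st$measurements, file.path(out, "measurements.tsv")))
  }

  if (run_stage("profile")) {
    st$tfap <- normalize_to_controls(st$measurements,
                                     control_group = simcfg$groups[1])
    st$activity_summary <- tfap_summary(st$tfap,
                                        reference_group = simcfg$groups[1])
    pipeline_log("INFO", "profile: normalized to per-experiment '",
                 simcfg$groups[1], "' means")
    emit(write_tsv(as.data.frame(st$tfap), file.path(out, "tfap.tsv")))
    emit(write_tsv(st$activity_summary, file.path(out, "group_summary.tsv")))
  }

  if (run_stage("behavior")) {
    bcfg <- config$behavior %||% list()
    thr <- bcfg$outlier_threshold %||% 4
    tr <- st$behavior_trials
    tr$si_rate <- si_rate(tr$time_with_mouse, tr$time_no_mouse,
                          direction = bcfg$si_direction %||% "with_over_without")
    tr$excluded <- apply_outlier_rule(tr$si_rate, threshold = thr)
    pipeline_log("INFO", "behavior: SI outlier rule > ", thr, " excluded ",
                 sum(tr$excluded), " trial(s)")
    keep <- tr[!tr$excluded, ]
    keep$phenotype <- classify_phenotype(keep$si_rate,
                                         keep$group != simcfg$groups[1])
    keep <- normalize_si_by_day(keep, control_group = simcfg$groups[1])
    st$behavior_table <- keep
    emit(write_tsv(tr, file.path(out, "si_trials.tsv")))
    emit(write_tsv(keep[, c("animal_id", "group", "day", "si_rate",
                            "normalized_si", "phenotype")],
                   file.path(out, "phenotypes.tsv")))
  }

  if (run_stage("de")) {
    dcfg <- config$de %||% list()
    contrast <- dcfg$contrast_group %||% simcfg$groups[2]
    tpm <- counts_to_tpm(st$exprsim$counts, st$exprsim$lengths)
    de <- differential_expression(tpm, st$exprsim$sample_groups,
                                  groupA = contrast,
                                  groupB = simcfg$groups[1],
                                  pseudocount = dcfg$pseudocount %||% 1)
    de <- call_degs(de, p_thresh = dcfg$p_thresh %||% 0.05,
                    fc_up = dcfg$fc_up %||% 2, fc_down = dcfg$fc_down %||% 0.5,
                    use_q = isTRUE(dcfg$use_q))
    pipeline_log("INFO", "de: ", contrast, " vs ", simcfg$groups[1],
                 ", DEG rule p < ", dcfg$p_thresh %||% 0.05, " & FC > ",
                 dcfg$fc_up %||% 2, " | FC < ", dcfg$fc_down %||% 0.5, ": ",
                 sum(de$deg_class == "up"), " up, ",
                 sum(de$deg_class == "down"), " down")
    st$de <- de
    emit(write_tsv(de, file.path(out, "de_results.tsv")))
    emit(write_tsv(de[de$deg_class != "none", ], file.path(out, "degs.tsv")))
  }

  if (run_stage("regulon")) {
    rcfg <- config$regulon %||% list()
    promoters <- extract_promoters(st$prom$tss, st$prom$genome,
                                   upstream = simcfg$promoter_upstream,
                                   downstream = simcfg$promoter_downstream)
    st$regulons <- build_regulon_map(
      promoters, st$motifs,
      threshold_policy = rcfg$threshold_policy %||% "fraction",
      threshold = rcfg$threshold %||% 0.8
    )
    pipeline_log("INFO", "regulon: policy ",
                 rcfg$threshold_policy %||% "fraction", " @ ",
                 rcfg$threshold %||% 0.8, ", median regulon size ",
                 stats::median(lengths(st$regulons$targets)))
    emit(write_tsv(as.data.frame(st$regulons), file.path(out, "regulons.tsv")))
    emit(write_gmt(st$regulons, file.path(out, "regulons.gmt")))
  }

  if (run_stage("integrate")) {
    icfg <- config$integrate %||% list()
    contrast <- (config$de %||% list())$contrast_group %||% simcfg$groups[2]
    summ <- st$activity_summary[st$activity_summary$group == contrast, ]
    rmap <- if (isTRUE(icfg$use_true_regulons)) {
      regulon_map_from_truth(st$truth)
    } else st$regulons
    rec <- tf_regulon_coupling(summ, st$de, rmap)
    drivers <- rank_candidate_drivers(
      rec, discordance_factor = icfg$discordance_factor %||% 0.25)
    pipeline_log("INFO", "integrate: top candidate driver ",
                 drivers$tf_id[1], " (score ",
                 signif(drivers$driver_score[1], 4), ")")
    emit(write_tsv(rec, file.path(out, "integration.tsv")))
    emit(write_tsv(drivers, file.path(out, "drivers.tsv")))
  }

  manifest <- list(
    package = "tfap",
    version = as.character(utils::packageVersion("tfap")),
    seed = config$seed,
    config = config,
    outputs = as.list(tools::md5sum(sort(unique(files))))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
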