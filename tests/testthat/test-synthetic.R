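test_that("make_truth is seeded, validates, and encodes effects by construction", {
  cfg <- tiny_config(seed = 11, effect_log2fc = 0.5)
  t1 <- make_truth(cfg)
  t2 <- make_truth(cfg)
  expect_identical(t1, t2)

  # drivers carry exactly the configured effect in every non-control group
  expect_true(all(t1$activity_log2fc[t1$driver_set, -1] == 0.5))
  nondriver <- setdiff(t1$tf_ids, t1$driver_set)
  expect_true(all(t1$activity_log2fc[nondriver, ] == 0))
  expect_true(all(t1$activity_log2fc[, "control"] == 0))
  expect_true(all(rowSums(t1$regulon_weights != 0) == cfg$regulon_size))

  t0 <- make_truth(tiny_config(seed = 11, n_drivers = 0))
  expect_true(all(t0$activity_log2fc == 0))

  expect_error(tiny_config(n_drivers = 10), "n_drivers")
  expect_error(tiny_config(battery_size = 7), "battery_size")
  expect_error(tiny_config(noise_sd_expr = -1), "noise")
})

test_that("reporter batteries respect the six-construct cap and cover every TF", {
  cfg <- sim_config(n_tfs = 30, battery_size = 6, n_animals_per_group = 10,
                    n_genes = 100, regulon_size = 5, seed = 3)
  truth <- make_truth(cfg)
  rep <- simulate_reporter_counts(truth, cfg)
  per_animal <- tapply(rep$tf_id, rep$animal_id, function(x) length(unique(x)))
  expect_true(all(per_animal <= 6))
  # cycling panels covers all 30 TFs in every group
  for (g in cfg$groups) {
    expect_setequal(unique(rep$tf_id[rep$group == g]), truth$tf_ids)
  }
  expect_true(all(rep$reporter_copies > 0 & rep$reference_copies > 0))
  expect_identical(rep, simulate_reporter_counts(truth, cfg))
})

test_that("noiseless reporters invert to the exact activity ratio", {
  cfg <- tiny_config(seed = 5, noise_sd_reporter = 0, effect_log2fc = 1)
  truth <- make_truth(cfg)
  rep <- simulate_reporter_counts(truth, cfg)
  ratio <- rep$reporter_copies / rep$reference_copies
  driver <- rep$tf_id %in% truth$driver_set & rep$group != "control"
  expect_equal(ratio[driver], rep(2, sum(driver)), tolerance = 1e-12)
  expect_equal(ratio[!driver], rep(1, sum(!driver)), tolerance = 1e-12)
})

test_that("expression follows the log-linear regulon model", {
  # null case: no weights, no noise -> identical group means
  cfg0 <- tiny_config(seed = 7, noise_sd_expr = 0, regulon_weight = 0)
  tr0 <- make_truth(cfg0)
  ex0 <- simulate_expression(tr0, cfg0)
  ga <- rowMeans(ex0$expr[, tr0$groups[1] == ex0$sample_groups])
  gb <- rowMeans(ex0$expr[, tr0$groups[2] == ex0$sample_groups])
  expect_equal(ga, gb, tolerance = 1e-12)

  # construction: w = 1, a = 0.5, noise 0 -> target log2FC exactly 0.5
  cfg1 <- tiny_config(seed = 7, noise_sd_expr = 0, effect_log2fc = 0.5)
  tr1 <- make_truth(cfg1)
  ex1 <- simulate_expression(tr1, cfg1)
  shift <- as.numeric(crossprod(tr1$regulon_weights,
                                tr1$activity_log2fc)[, "susceptible"])
  lfc <- log2(rowMeans(ex1$expr[, ex1$sample_groups == "susceptible"]) /
                rowMeans(ex1$expr[, ex1$sample_groups == "control"]))
  expect_equal(unname(lfc), shift, tolerance = 1e-9)
  expect_true(all(ex1$counts >= 0) && all(ex1$lengths > 0))
})

test_that("expression noise SD matches the configured value over 200 replicates", {
  cfg <- tiny_config(n_tfs = 2, n_genes = 5, n_animals_per_group = 1,
                     regulon_size = 2, noise_sd_expr = 0.25)
  tr <- make_truth(cfg)
  vals <- vapply(1:200, function(s) {
    c2 <- tiny_config(n_tfs = 2, n_genes = 5, n_animals_per_group = 1,
                      regulon_size = 2, noise_sd_expr = 0.25, seed = s)
    log2(simulate_expression(tr, c2)$expr[3, 1])
  }, numeric(1))
  mc_se <- 0.25 / sqrt(2 * (200 - 1))
  expect_lt(abs(sd(vals) - 0.25), 3 * mc_se)
})

test_that("behavior couples SI-rate to driver activity", {
  cfg0 <- tiny_config(seed = 9, noise_sd_behavior = 0, behavior_coupling = 0)
  tr0 <- make_truth(cfg0)
  b0 <- simulate_behavior(tr0, cfg0)
  expect_equal(b0$time_with_mouse / b0$time_no_mouse,
               rep(cfg0$behavior_baseline, nrow(b0)), tolerance = 1e-12)

  cfgn <- tiny_config(seed = 9, noise_sd_behavior = 0, behavior_coupling = -0.4)
  trn <- make_truth(cfgn)
  bn <- simulate_behavior(trn, cfgn)
  si <- bn$time_with_mouse / bn$time_no_mouse
  expect_lt(mean(si[bn$group == "susceptible"]), mean(si[bn$group == "control"]))
  expect_identical(bn, simulate_behavior(trn, cfgn))
})

test_that("promoter simulation implants recoverable sites", {
  cfg <- tiny_config(seed = 13, n_genes = 40, regulon_size = 6)
  tr <- make_truth(cfg)
  motifs <- make_motifs(tr$tf_ids, seed = 2)
  sim <- simulate_promoters(tr, motifs, cfg)
  prom <- extract_promoters(sim$tss, sim$genome,
                            cfg$promoter_upstream, cfg$promoter_downstream)
  # every implanted target recovered at the zero-tolerance (max score) cut
  for (tf in tr$tf_ids) {
    thr <- pwm_max_score(motifs[[tf]])
    targets <- tr$gene_ids[tr$regulon_weights[tf, ] != 0]
    for (g in targets) {
      hits <- pwm_scan(as.character(prom$seqs[[g]]), motifs[[tf]],
                       min_score_bits = thr - 1e-9)
      expect_gt(nrow(hits), 0)
    }
  }
  # minus-strand genes included above; confirm both strands exercised
  expect_setequal(unique(sim$tss$strand), c("+", "-"))
  # motif longer than the window is rejected
  long_m <- tfap_motif("LONG", matrix(0.25, 4, 2000))
  expect_error(
    simulate_promoters(tr, modifyList(motifs, list(TF01 = long_m)), cfg),
    "longer than the promoter window")
})

test_that("background hit rate matches the closed-form binomial expectation", {
  # sharp length-5 motif: a max-score hit needs all 5 consensus bases, so
  # per offset/strand the background match probability is 0.25^5
  m <- tfap_motif("M", {
    mm <- matrix(0.05, 4, 5); mm[cbind(c(1, 3, 2, 4, 1), 1:5)] <- 0.85; mm
  })
  thr <- pwm_max_score(m) - 1e-9
  set.seed(42)
  n_seq <- 600; len <- 200
  hits <- vapply(seq_len(n_seq), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    nrow(pwm_scan(s, m, min_score_bits = thr))
  }, numeric(1))
  p <- 0.25^5
  trials <- n_seq * (len - 5 + 1) * 2
  expected <- trials * p
  expect_lt(abs(sum(hits) - expected), 3 * sqrt(trials * p * (1 - p)))
})

test_that("standard series follows the Cq formula and validates inputs", {
  s <- simulate_standard_series(-3.321928, 40, 10^(2:7))
  expect_equal(s$points$cq_cycles[s$points$log10_copies == 6],
               20.068432, tolerance = 1e-9)
  fit <- fit_standard_curve(s)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(simulate_standard_series(-3.3, 40, c(10, 100)), "3 dilution")
  expect_error(simulate_standard_series(-3.3, 40, c(0, 10, 100)), "positive")
})
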