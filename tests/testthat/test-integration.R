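test_that("tf_regulon_coupling averages target fold changes and excludes empty TFs", {
  de <- data.frame(gene = paste0("g", 1:6),
                   log2fc = c(1, 1, 1, 0, -1, 2),
                   p_value = rep(0.5, 6), q_value = rep(0.5, 6))
  summ <- data.frame(tf_id = c("T1", "T2"), mean_log2fc = c(0.5, -0.2))
  rmap <- structure(list(
    targets = list(T1 = c("g1", "g2", "g3"), T2 = character(0)),
    best_scores = list(T1 = c(g1 = 1, g2 = 1, g3 = 1), T2 = numeric(0)),
    threshold_policy = "bits", threshold = 0
  ), class = "regulon_map")
  expect_warning(rec <- tf_regulon_coupling(summ, de, rmap), "T2")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mean_target_log2fc, 1.0)
  expect_equal(rec$n_targets, 3)
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # N=10, K=5, n=5, overlap=5 -> 1/C(10,5) = 1/252
  uni <- paste0("g", 1:10)
  p <- regulon_deg_enrichment(uni[1:5], uni[1:5], uni)
  expect_equal(p, 1 / 252, tolerance = 1e-12)
  # zero overlap -> upper tail is 1
  expect_equal(regulon_deg_enrichment(uni[1:5], uni[6:10], uni), 1)

  set.seed(14)
  for (i in 1:20) {
    N <- sample(8:15, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    uni <- paste0("g", 1:N)
    reg <- uni[1:K]
    deg <- sample(uni, n)
    k <- length(intersect(deg, reg))
    p_pkg <- regulon_deg_enrichment(deg, reg, uni)
    p_enum <- oracle_hyper_enum(N, K, n, k)
    expect_equal(p_pkg, p_enum, tolerance = 1e-12)
  }
})

test_that("regulon shift test matches enumeration, symmetry and tie handling", {
  lfc <- c(a = 2, b = 3, x = 0, y = 1) # |lfc| regulon {2,3} vs background {0,1}
  r <- regulon_shift_test(lfc, c("a", "b"))
  expect_true(r$exact)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)

  # label swap leaves p unchanged
  r_sw <- regulon_shift_test(lfc, c("x", "y"))
  expect_equal(r_sw$p, r$p, tolerance = 1e-12)

  # all values tied -> p = 1 with the approximate path flagged
  tied <- setNames(rep(1.5, 6), paste0("g", 1:6))
  rt <- regulon_shift_test(tied, paste0("g", 1:2))
  expect_equal(rt$p, 1)
  expect_false(rt$exact)
})

test_that("variance broadening test matches var.test and reciprocates", {
  x <- c(1, 3, 5, 7); y <- c(2, 3, 4, 5) # variances 20/3 and 5/3 -> F = 4
  r <- variance_broadening_test(x, y)
  expect_equal(r$F, 4.0, tolerance = 1e-12)
  expect_equal(r$df1, 3); expect_equal(r$df2, 3)
  ref <- var.test(x, y)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  # equal variances, equal n -> F = 1, p = 1
  r1 <- variance_broadening_test(c(0, 2), c(5, 7))
  expect_equal(r1$F, 1); expect_equal(r1$p, 1)

  # swapping inputs inverts F and preserves p
  r_sw <- variance_broadening_test(y, x)
  expect_equal(r_sw$F, 1 / r$F, tolerance = 1e-12)
  expect_equal(r_sw$p, r$p, tolerance = 1e-12)
  expect_error(variance_broadening_test(c(1, 2), c(3, 3)), "zero variance")
})

test_that("driver ranking places constructed drivers first and is stable", {
  cfg <- tiny_config(seed = 51, noise_sd_reporter = 0, noise_sd_expr = 0,
                     effect_log2fc = 0.5)
  tr <- make_truth(cfg)
  tfp <- normalize_to_controls(compute_measurements(
    simulate_reporter_counts(tr, cfg)))
  summ <- tfap_summary(tfp)
  ex <- simulate_expression(tr, cfg)
  de <- call_degs(differential_expression(ex$expr, ex$sample_groups,
                                          "susceptible", "control",
                                          pseudocount = 0))
  rec <- tf_regulon_coupling(summ, de, regulon_map_from_truth(tr))
  ranked <- rank_candidate_drivers(rec)
  expect_setequal(ranked$tf_id[1:2], tr$driver_set)

  # noiseless construction: drivers couple exactly, non-drivers are ~0
  drec <- rec[rec$tf_id %in% tr$driver_set, ]
  expect_equal(drec$mean_target_log2fc, drec$activity_log2fc, tolerance = 1e-9)
  nd <- rec[!rec$tf_id %in% tr$driver_set, ]
  expect_true(all(abs(nd$mean_target_log2fc) < 1e-9))

  # permutation invariance: shuffling record order leaves scores unchanged
  ranked2 <- rank_candidate_drivers(rec[sample(nrow(rec)), ])
  expect_equal(ranked2$tf_id, ranked$tf_id)
  expect_equal(ranked2$driver_score, ranked$driver_score, tolerance = 1e-12)
})

test_that("all-null truth yields near-zero scores with a documented tie-break", {
  cfg <- tiny_config(seed = 52, n_drivers = 0, noise_sd_reporter = 0,
                     noise_sd_expr = 0)
  tr <- make_truth(cfg)
  tfp <- normalize_to_controls(compute_measurements(
    simulate_reporter_counts(tr, cfg)))
  ex <- simulate_expression(tr, cfg)
  de <- call_degs(differential_expression(ex$expr, ex$sample_groups,
                                          "susceptible", "control",
                                          pseudocount = 0))
  rec <- tf_regulon_coupling(tfap_summary(tfp), de, regulon_map_from_truth(tr))
  ranked <- rank_candidate_drivers(rec)
  expect_true(all(ranked$driver_score < 1e-12))
  expect_equal(ranked$tf_id, sort(ranked$tf_id)) # tie-break by name
})

test_that("activity-behavior correlation handles single and joint modes", {
  acts <- data.frame(
    animal_id = rep(sprintf("a%d", 1:6), 2),
    tf_id = rep(c("T1", "T2"), each = 6),
    normalized_activity = c(1:6, c(2, 1, 4, 3, 6, 5))
  )
  si <- setNames(2 * (1:6) + 3, sprintf("a%d", 1:6)) # exactly linear in T1
  r <- activity_behavior_correlation(acts, si, tf_subset = "T1")
  expect_equal(r$r, 1)
  expect_lt(r$p, 1e-6)

  # hand-computed zero correlation
  acts0 <- data.frame(animal_id = sprintf("a%d", 1:3), tf_id = "T0",
                      normalized_activity = c(1, 2, 3))
  si0 <- setNames(c(1, -2, 1), sprintf("a%d", 1:3))
  expect_equal(activity_behavior_correlation(acts0, si0)$r, 0,
               tolerance = 1e-12)

  # affine invariance
  r2 <- activity_behavior_correlation(
    transform(acts, normalized_activity = 3 * normalized_activity + 7),
    si, tf_subset = "T1")
  expect_equal(r2$r, r$r, tolerance = 1e-12)

  # exact linear dependence makes lm warn about a perfect fit; that is the
  # intended fixture
  rj <- suppressWarnings(activity_behavior_correlation(acts, si, joint = TRUE))
  expect_equal(rj$tf_id, "joint")
  expect_gte(rj$r, 0.99) # T1 alone already explains SI
  expect_error(activity_behavior_correlation(acts0, si0[1:2]), ">= 3")
})
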