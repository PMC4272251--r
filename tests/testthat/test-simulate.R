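test_that("identical seeds reproduce identical cohorts", {
  cfg <- sim_config(seed = 42, n_samples = 2, baseline_depth = 25)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$pileups, s2$pileups)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$gold, s2$gold)
  s3 <- simulate_cohort(sim_config(seed = 43, n_samples = 2,
                                   baseline_depth = 25))
  expect_false(identical(s1$pileups, s3$pileups))
})

test_that("extending the cohort leaves earlier samples untouched", {
  s_small <- simulate_cohort(sim_config(seed = 42, n_samples = 2))
  s_big <- simulate_cohort(sim_config(seed = 42, n_samples = 4))
  expect_identical(s_small$pileups[["S01"]], s_big$pileups[["S01"]])
  expect_identical(s_small$pileups[["S02"]], s_big$pileups[["S02"]])
})

test_that("a variant- and error-free genome matches the reference everywhere", {
  cfg <- sim_config(seed = 3, n_samples = 1, baseline_depth = 20,
                    sample_sd = 0, error_rate = 0,
                    n_homoplasmic = 0L, n_heteroplasmic = 0L,
                    artifact_positions = integer(0))
  sim <- simulate_cohort(cfg)
  pu <- sim$pileups[[1]]
  ref_count <- purrr::map2_int(seq_len(nrow(pu)), pu$ref, function(i, r)
    if (r %in% c("A", "C", "G", "T")) as.integer(pu[[r]][i]) else 0L)
  expect_equal(ref_count[pu$ref != "N"], pu$depth[pu$ref != "N"])
  expect_equal(nrow(sim$truth), 0)
})

test_that("mean realized depth converges to baseline x mean dip adjustment", {
  cfg <- sim_config(seed = 8, n_samples = 1, baseline_depth = 40,
                    sample_sd = 0)
  sim <- simulate_cohort(cfg)
  L <- 16569
  dip <- rep(1, L)
  dip[cfg$dips$start[1]:cfg$dips$end[1]] <- cfg$dips$multiplier[1]
  expected <- cfg$baseline_depth * mean(dip)
  expect_equal(sim$profiles[[1]]$mean_depth, expected, tolerance = 0.01)
})

test_that("variant reads are binomial draws at the programmed fraction", {
  cfg <- sim_config(seed = 12, n_samples = 2, baseline_depth = 100,
                    sample_sd = 0, noise_sd = 0, smooth_scale = 0,
                    error_rate = 0, n_homoplasmic = 0L,
                    n_heteroplasmic = 400L, het_vaf_range = c(0.5, 0.5),
                    artifact_positions = integer(0),
                    dips = tibble::tibble(start = integer(), end = integer(),
                                          multiplier = numeric()))
  sim <- simulate_cohort(cfg)
  frac <- sim$truth$sim_v / sim$truth$sim_depth
  expect_equal(mean(frac), 0.5, tolerance = 0.02)
  # dispersion consistent with Binomial(n~100, 0.5), not degenerate
  expect_gt(stats::sd(frac), 0.02)
})

test_that("the poly-C tract carries an elevated error rate", {
  cfg <- sim_config(seed = 14, n_samples = 6, baseline_depth = 200,
                    sample_sd = 0, error_rate = 2e-3,
                    n_homoplasmic = 0L, n_heteroplasmic = 0L,
                    artifact_positions = integer(0))
  sim <- simulate_cohort(cfg)
  err_frac <- function(pu, idx) {
    sub <- pu[idx, ]
    ref_count <- purrr::map2_int(seq_len(nrow(sub)), sub$ref, function(i, r)
      as.integer(sub[[r]][i]))
    sum(sub$depth - ref_count) / sum(sub$depth)
  }
  polyc <- 16184:16193
  outside <- setdiff(seq_len(16569), c(polyc, 3107))
  in_rate <- mean(purrr::map_dbl(sim$pileups, err_frac, idx = polyc))
  out_rate <- mean(purrr::map_dbl(sim$pileups, err_frac, idx = outside))
  expect_gt(in_rate, 5 * out_rate)
})

test_that("gold-standard sets contain every real truth site", {
  cfg <- sim_config(seed = 15, n_samples = 3)
  sim <- simulate_cohort(cfg)
  real <- sim$truth[sim$truth$type != "artifact", ]
  expect_true(all(paste(real$sample_id, real$position) %in%
                    paste(sim$gold$sample_id, sim$gold$position)))
  arts <- sim$truth[sim$truth$type == "artifact", ]
  expect_false(any(paste(arts$sample_id, arts$position) %in%
                     paste(sim$gold$sample_id, sim$gold$position)))
})

test_that("simulated recurrent artifacts are caught by the cohort flagger", {
  cfg <- sim_config(seed = 16, n_samples = 5, baseline_depth = 60,
                    sample_sd = 0)
  sim <- simulate_cohort(cfg)
  th <- calling_thresholds()
  cohort <- purrr::imap_dfr(sim$pileups, function(pu, sid)
    dplyr::mutate(call_variants(pu, th), sample_id = sid))
  flagged <- flag_recurrent_artifacts(cohort, th, cfg$reference)
  arts <- attr(flagged, "artifact_sites")
  hit <- intersect(arts$position, cfg$artifact_positions)
  expect_gte(length(hit), 7)   # nearly all nine positions recur cohort-wide
  expect_true(all(arts$n_samples[arts$position %in% hit] >=
                    th$recurrent_min_samples))
})

test_that("detection rates match direct binomial tail computations", {
  rec <- recovery_experiment(true_vafs = c(0.01, 0.5),
                             depths = c(10, 100),
                             n_sites = 500L, seed = 4)
  hi <- rec[rec$true_vaf == 0.5 & rec$mean_depth == 100, ]
  expect_gt(hi$detection_rate, 0.99)   # P(miss) negligible at depth 100
  lo <- rec[rec$true_vaf == 0.01 & rec$mean_depth == 10, ]
  expect_lt(lo$detection_rate, 0.01)   # P(v >= 3 | Bin(10, 0.01)) ~ 1e-4
})

test_that("exact intervals cover the truth in at least 93% of detected sites", {
  rec <- recovery_experiment(true_vafs = c(0.2, 0.5, 0.8),
                             depths = c(30, 50, 100),
                             n_sites = 400L, seed = 5)
  detected <- rec[!is.na(rec$ci_coverage), ]
  pooled <- sum(detected$ci_coverage * detected$detected) /
    sum(detected$detected)
  expect_gte(sum(detected$detected), 1000)
  expect_gte(pooled, 0.93)
})

test_that("configuration errors are rejected up front", {
  expect_error(sim_config(artifact_positions = 99999L), "outside")
  expect_error(sim_config(error_rate = 2), "rates")
  expect_error(sim_config(dips = tibble::tibble(start = 1L, end = 5L,
                                                multiplier = 0)), "multipliers")
})
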