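test_that("toy two-set comparison classifies all 30 bases by hand count", {
  prof <- coverage_profile(rep(10L, 30), genome_length = 30L, sample_id = "S1")
  led <- compare_callsets(
    tibble::tibble(sample_id = "S1", position = c(5L, 10L)),
    tibble::tibble(sample_id = "S1", position = c(10L, 20L)),
    depth_a = list(S1 = prof), genome_length = 30L)
  cn <- tidy(led)
  expect_equal(cn$codetected, 1L)
  expect_equal(cn$a_only, 1L)
  expect_equal(cn$b_only, 1L)
  expect_equal(cn$low_coverage, 0L)
  expect_equal(cn$concordant_ref, 27L)
})

test_that("gold-only sites under the depth threshold become low_coverage", {
  depth <- rep(10L, 30); depth[20] <- 2L
  prof <- coverage_profile(depth, genome_length = 30L, sample_id = "S1")
  led <- compare_callsets(
    tibble::tibble(sample_id = "S1", position = 5L),
    tibble::tibble(sample_id = "S1", position = c(5L, 20L)),
    depth_a = list(S1 = prof), genome_length = 30L, min_depth = 5L)
  cn <- tidy(led)
  expect_equal(cn$low_coverage, 1L)
  expect_equal(cn$b_only, 0L)
  expect_equal(led$sites$category[led$sites$position == 20], "low_coverage")
})

test_that("category counts always partition the per-sample genome", {
  prof <- coverage_profile(rep(8L, 200), genome_length = 200L)
  for (seed in 1:5) {
    set.seed(seed)
    a <- sort(sample(200, 15)); b <- sort(sample(200, 12))
    led <- compare_callsets(
      tibble::tibble(sample_id = "X", position = a),
      tibble::tibble(sample_id = "X", position = b),
      depth_a = prof, genome_length = 200L)
    cn <- tidy(led)
    expect_equal(cn$codetected + cn$a_only + cn$b_only +
                   cn$low_coverage + cn$concordant_ref, 200L)
  }
})

test_that("cohort denominators reproduce the per-base accounting", {
  led <- compare_callsets(
    tibble::tibble(sample_id = "S01", position = 100L),
    tibble::tibble(sample_id = "S01", position = 100L),
    depth_a = coverage_profile(rep(10L, 16569)),
    genome_length = 16569L, n_samples = 46L)
  expect_equal(led$total_bases, 762174L)           # 46 x 16,569
  er <- error_rates(
    led,
    tibble::tibble(sample_id = "S01", position = c(100L, 200L),
                   platform = c("a", "b"), confirmed = c(FALSE, TRUE)),
    exclude = tibble::tibble(start = 16184L, end = 16193L))
  expect_equal(er$report$denominator, rep(761714L, 2))  # 762,174 - 46 x 10
})

test_that("error rates reproduce the printed platform percentages", {
  led <- compare_callsets(
    tibble::tibble(sample_id = "S01", position = 1L),
    tibble::tibble(sample_id = "S01", position = 1L),
    depth_a = coverage_profile(rep(10L, 16569)),
    genome_length = 16569L, n_samples = 46L)
  disc <- dplyr::bind_rows(
    tibble::tibble(sample_id = "S01", position = 1000L + 1:24,
                   platform = "a", confirmed = FALSE),
    tibble::tibble(sample_id = "S01", position = 2000L + 1:10,
                   platform = "b", confirmed = FALSE))
  er <- error_rates(led, disc)
  expect_equal(round(er$report$percent, 4), c(0.0031, 0.0013))
  expect_equal(signif(er$test$p.value, 4), 0.02431)
  # region exclusion with a zero-width exclusion equals no exclusion
  er0 <- error_rates(led, disc,
                     exclude = tibble::tibble(start = integer(), end = integer()))
  expect_equal(er0$report, er$report)
})

test_that("poly-C exclusion flips the platform comparison as published", {
  led <- compare_callsets(
    tibble::tibble(sample_id = "S01", position = 1L),
    tibble::tibble(sample_id = "S01", position = 1L),
    depth_a = coverage_profile(rep(10L, 16569)),
    genome_length = 16569L, n_samples = 46L)
  # 22 of the 24 exome-only errors sit inside the poly-C tract
  disc <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("S%02d", 1:22),
                   position = rep(c(16184L, 16186L), 11),
                   platform = "a", confirmed = FALSE),
    tibble::tibble(sample_id = "S01", position = c(5000L, 6000L),
                   platform = "a", confirmed = FALSE),
    tibble::tibble(sample_id = "S01", position = 2000L + 1:10,
                   platform = "b", confirmed = FALSE))
  er <- error_rates(led, disc,
                    exclude = tibble::tibble(start = 16184L, end = 16193L))
  expect_equal(er$report$discordant_count, c(2L, 10L))
  expect_equal(round(er$report$percent, 4), c(0.0003, 0.0013))
  expect_equal(signif(er$test$p.value, 4), 0.03857)
})

test_that("zero unconfirmed discordances flag the test as undefined", {
  led <- compare_callsets(
    tibble::tibble(sample_id = "S1", position = 5L),
    tibble::tibble(sample_id = "S1", position = 5L),
    depth_a = coverage_profile(rep(10L, 100), genome_length = 100L),
    genome_length = 100L)
  expect_message(
    er <- error_rates(led, tibble::tibble(sample_id = character(),
                                          position = integer(),
                                          platform = character(),
                                          confirmed = logical())),
    "undefined")
  expect_null(er$test)
  expect_equal(er$report$rate, c(0, 0))
})

test_that("duplicate sites within one sample are refused", {
  prof <- coverage_profile(rep(10L, 100), genome_length = 100L)
  expect_error(compare_callsets(
    tibble::tibble(sample_id = c("S1", "S1"), position = c(5L, 5L)),
    tibble::tibble(sample_id = "S1", position = 5L),
    depth_a = prof, genome_length = 100L), "duplicate")
})

test_that("coverage-threshold QC reflects simulated truth exactly", {
  # uniform depths: a passing and a failing sample
  gold <- tibble::tibble(sample_id = c("hi", "hi", "lo", "lo"),
                         position = c(100L, 200L, 100L, 200L))
  profs <- list(hi = coverage_profile(rep(25L, 16569), sample_id = "hi"),
                lo = coverage_profile(rep(3L, 16569), sample_id = "lo"))
  rep_ <- coverage_threshold_report(gold, profs)
  expect_true(rep_$pass[rep_$sample_id == "hi"])
  expect_equal(rep_$frac_ge_min[rep_$sample_id == "hi"], 1)
  expect_equal(rep_$gold_sites_lost[rep_$sample_id == "hi"], 0L)
  expect_false(rep_$pass[rep_$sample_id == "lo"])
  expect_equal(rep_$gold_sites_lost[rep_$sample_id == "lo"], 2L)

  # simulated cohort: lost counts equal the truth-side tally
  cfg <- sim_config(seed = 31, n_samples = 3, baseline_depth = 12,
                    sample_sd = 0.4)
  sim <- simulate_cohort(cfg)
  rep2 <- coverage_threshold_report(sim$gold, sim$profiles)
  for (sid in names(sim$profiles)) {
    gp <- sim$gold$position[sim$gold$sample_id == sid]
    want <- sum(sim$profiles[[sid]]$depth[gp] < 5)
    expect_equal(rep2$gold_sites_lost[rep2$sample_id == sid], want)
  }
})
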