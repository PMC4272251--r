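th <- calling_thresholds()

test_that("threshold rules reproduce the documented calling decisions", {
  pu <- tibble::tibble(
    position = c(240L, 300L, 400L, 500L),
    ref = c("A", "C", "A", "T"),
    depth = c(17L, 4L, 10L, 20L),
    A = c(14L, 0L, 8L, 0L), C = c(0L, 3L, 0L, 0L),
    G = c(3L, 0L, 2L, 20L), T = c(0L, 1L, 0L, 0L))
  calls <- call_variants(pu, th)
  # 3 of 17 = 18% heteroplasmy with its exact interval
  expect_equal(calls$position, c(240L, 500L))
  expect_equal(calls$vaf[1], 3 / 17)
  expect_equal(round(100 * calls$ci_low[1]), 4)
  expect_equal(round(100 * calls$ci_high[1]), 43)
  # homoplasmic boundary: v = n = 20
  expect_equal(calls$vaf[2], 1)
  expect_equal(calls$ci_high[2], 1)
  led <- attr(calls, "ledger")
  expect_true(led$low_coverage[led$position == 300])   # n = 4 < 5
  expect_false(led$called[led$position == 400])        # v = 2 < 3
})

test_that("caller equals a brute-force threshold filter on random pileups", {
  for (seed in 1:6) {
    pu <- rand_pileup(120, seed)
    calls <- call_variants(pu, th)
    # oracle: direct filter over all (v, n, vaf) triples
    oracle <- do.call(rbind, lapply(seq_len(nrow(pu)), function(i) {
      if (pu$position[i] == 3107) return(NULL)
      cnt <- c(A = pu$A[i], C = pu$C[i], G = pu$G[i], T = pu$T[i])
      alts <- cnt[setdiff(names(cnt), pu$ref[i])]
      v <- max(alts)
      alt <- names(alts)[which.max(alts)]       # alphabetical tie-break
      n <- pu$depth[i]
      if (n >= 5 && v >= 3 && v / n >= 0.1) {
        data.frame(position = pu$position[i], alt = alt, v = v, n = n)
      } else NULL
    }))
    if (is.null(oracle)) {
      expect_equal(nrow(calls), 0)
    } else {
      expect_equal(calls$position, oracle$position)
      expect_equal(calls$alt, oracle$alt)
      expect_equal(calls$v, oracle$v)
      expect_equal(calls$n, oracle$n)
    }
  }
})

test_that("position 3107 and masked regions are excluded before calling", {
  pu <- tibble::tibble(position = c(3107L, 5000L, 5001L),
                       ref = "A", depth = 20L,
                       A = 10L, C = 0L, G = 10L, T = 0L)
  calls <- call_variants(pu, th, mask = tibble::tibble(start = 5001L, end = 5001L))
  expect_equal(calls$position, 5000L)
})

test_that("heteroplasmy classification uses the band and the background cap", {
  calls <- tibble::tibble(position = 1:4, ref = "A", alt = "G",
                          v = c(3L, 19L, 2L, 30L), n = c(17L, 20L, 40L, 60L),
                          vaf = c(3 / 17, 0.95, 0.05, 0.5),
                          ci_low = 0, ci_high = 1,
                          filters = NA_character_, tied_alt = FALSE)
  cls <- classify_heteroplasmy(calls, th)
  expect_equal(cls$het_class,
               c("heteroplasmic", "homoplasmic", "background", "heteroplasmic"))
})

test_that("recurrent positions are flagged across every carrier sample", {
  # 13 samples, all apparently heteroplasmic at the same position
  shared <- purrr::map_dfr(1:13, function(i)
    tibble::tibble(sample_id = sprintf("P%02d", i), position = 5899L,
                   ref = "A", alt = "G", v = 10L, n = 40L, vaf = 0.25,
                   ci_low = 0.1, ci_high = 0.4, filters = NA_character_,
                   tied_alt = FALSE))
  private <- tibble::tibble(sample_id = "P01", position = 8000L,
                            ref = "C", alt = "T", v = 12L, n = 30L, vaf = 0.4,
                            ci_low = 0.2, ci_high = 0.6,
                            filters = NA_character_, tied_alt = FALSE)
  polyc <- tibble::tibble(sample_id = "P02", position = 16186L,
                          ref = "C", alt = "T", v = 30L, n = 31L, vaf = 30 / 31,
                          ci_low = 0.8, ci_high = 1,
                          filters = NA_character_, tied_alt = FALSE)
  flagged <- flag_recurrent_artifacts(dplyr::bind_rows(shared, private, polyc),
                                      th, synthetic_rcrs())
  expect_true(all(flagged$recurrent_artifact[flagged$position == 5899]))
  expect_equal(sum(flagged$position == 5899), 13)
  expect_false(any(flagged$recurrent_artifact[flagged$position == 8000]))
  expect_true(all(flagged$polyC[flagged$position == 16186]))
  expect_match(flagged$filters[flagged$position == 16186], "polyC")
  arts <- attr(flagged, "artifact_sites")
  expect_equal(arts$position, 5899L)
  expect_equal(arts$n_samples, 13L)
})

test_that("heteroplasmy screening applies the strict mean-depth gate", {
  calls <- classify_heteroplasmy(
    tibble::tibble(position = 100L, ref = "A", alt = "G", v = 10L, n = 40L,
                   vaf = 0.25, ci_low = 0.1, ci_high = 0.4,
                   filters = NA_character_, tied_alt = FALSE), th)
  prof_hi <- coverage_profile(rep(31L, 16569), sample_id = "hi")
  prof_lo <- coverage_profile(rep(26L, 16569), sample_id = "lo")
  prof_lo$mean_depth <- 25.7
  expect_true(screen_sample_for_het(calls, prof_hi, th)$eligible)
  expect_false(screen_sample_for_het(calls, prof_lo, th)$eligible)
  expect_equal(nrow(screen_sample_for_het(calls, prof_hi, th)$candidates), 1)
  # flagged candidates drop out
  calls$filters <- "recurrent_artifact"
  expect_equal(nrow(screen_sample_for_het(calls, prof_hi, th)$candidates), 0)
})

test_that("simulated truth is recovered at the calling thresholds", {
  cfg <- sim_config(seed = 21, n_samples = 3, baseline_depth = 40,
                    sample_sd = 0, error_rate = 0)
  sim <- simulate_cohort(cfg)
  for (sid in names(sim$pileups)) {
    calls <- call_variants(sim$pileups[[sid]], th)
    truth <- sim$truth[sim$truth$sample_id == sid, ]
    must_call <- truth[truth$sim_v >= 3 & truth$sim_depth >= 5 &
                         truth$sim_v / truth$sim_depth >= 0.1, ]
    expect_true(all(must_call$position %in% calls$position))
    # with a zero error rate, every call sits at a programmed site
    expect_true(all(calls$position %in% truth$position))
  }
})

test_that("clean positions with background-level noise are never called", {
  cfg <- sim_config(seed = 22, n_samples = 2, baseline_depth = 40,
                    sample_sd = 0, error_rate = 1e-3)
  sim <- simulate_cohort(cfg)
  for (sid in names(sim$pileups)) {
    pu <- sim$pileups[[sid]]
    truth_pos <- sim$truth$position[sim$truth$sample_id == sid]
    clean <- pu[!pu$position %in% truth_pos & pu$ref != "N", ]
    err_reads <- clean$depth -
      purrr::map2_int(seq_len(nrow(clean)), clean$ref, function(i, r)
        as.integer(clean[[r]][i]))
    quiet <- clean$position[err_reads <= th$background_max_reads]
    calls <- call_variants(pu, th)
    expect_length(intersect(calls$position, quiet), 0)
  }
})

test_that("threshold constructor rejects inconsistent bands", {
  expect_error(calling_thresholds(min_vaf = 0.5, het_band = c(0.1, 0.9)))
  expect_error(calling_thresholds(het_band = c(0.9, 0.1)))
  expect_error(calling_thresholds(min_vaf = 0))
})
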