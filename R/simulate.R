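#' Simulation configuration for a synthetic mtDNA cohort
#'
#' Defines the statistical structure of a simulated off-target exome cohort:
#' smooth kit-specific per-base coverage shapes with a dip over the
#' light-strand replication origin, log-normal multiplicative depth noise,
#' binomial sampling of variant reads at programmed heteroplasmy fractions,
#' a base-error process elevated inside the poly-C tract, recurrent
#' cross-sample artifact positions, and Sanger-like gold-standard call sets
#' with a small per-base false-positive rate. All randomness flows from the
#' single `seed` through per-sample sub-seeds drawn once up front, so a
#' cohort can be extended without disturbing earlier samples.
#'
#' @param seed Master integer seed.
#' @param n_samples Number of samples (default 46, a realistic diagnostic
#'   cohort size).
#' @param reference A [reference_model] (default [synthetic_rcrs()]).
#' @param baseline_depth Mean per-base depth (fold) around which sample
#'   depths vary (default 30, the level at which heteroplasmy screening
#'   becomes informative).
#' @param kits Character vector of capture-kit labels recycled across
#'   samples; each kit gets its own smooth coverage shape.
#' @param smooth_scale Amplitude (log scale) of the smooth kit shape.
#' @param noise_sd Per-base log-normal depth noise (mean-one).
#' @param sample_sd Per-sample log-normal scale factor spread (mean-one);
#'   0 makes every sample share the baseline mean.
#' @param dips Tibble `start`, `end`, `multiplier` (in (0, 1]); defaults to
#'   a 0.2x dip over the packaged Ori-L region.
#' @param numt_peaks Optional tibble `start`, `end`, `multiplier` (> 1) for
#'   kit-style coverage inflation over nuclear-mitochondrial insert
#'   homology; none by default.
#' @param error_rate Per-read base error rate (default 1e-3).
#' @param polyC_multiplier Error-rate multiplier inside the poly-C tract
#'   (default 20).
#' @param n_homoplasmic Homoplasmic variants per sample (default 25,
#'   typical of an individual vs the reference).
#' @param n_heteroplasmic Private heteroplasmic sites per sample (default
#'   1), with true fractions drawn uniformly on `het_vaf_range`.
#' @param het_vaf_range True heteroplasmy range (default 0.1-0.9).
#' @param artifact_positions Recurrent artifact positions shared by every
#'   sample (default nine positions, emulating the structure of the
#'   recurrent false heteroplasmy calls; identities are fixture choices).
#' @param artifact_vaf_range Apparent fraction range at artifact positions.
#' @param gold_fp_rate Per-base false-positive rate of the gold-standard
#'   (Sanger-like) call sets (default 1.3e-5, i.e. 0.0013%).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 46L,
                       reference = synthetic_rcrs(),
                       baseline_depth = 30,
                       kits = c("kitA", "kitB", "kitC"),
                       smooth_scale = 0.4,
                       noise_sd = 0.3,
                       sample_sd = 0.5,
                       dips = NULL,
                       numt_peaks = NULL,
                       error_rate = 1e-3,
                       polyC_multiplier = 20,
                       n_homoplasmic = 25L,
                       n_heteroplasmic = 1L,
                       het_vaf_range = c(0.1, 0.9),
                       artifact_positions = c(302L, 310L, 316L, 513L, 567L,
                                              5899L, 16182L, 16183L, 16185L),
                       artifact_vaf_range = c(0.15, 0.5),
                       gold_fp_rate = 1.3e-5) {
  stopifnot(inherits(reference, "reference_model"))
  if (is.null(dips)) {
    oril <- reference$special_regions[reference$special_regions$label == "OriL", ]
    dips <- if (nrow(oril) > 0) {
      tibble::tibble(start = oril$start[1], end = oril$end[1], multiplier = 0.2)
    } else {
      tibble::tibble(start = integer(), end = integer(), multiplier = numeric())
    }
  }
  if (any(dips$multiplier <= 0 | dips$multiplier > 1)) {
    rlang::abort("dip multipliers must lie in (0, 1].")
  }
  if (error_rate < 0 || error_rate > 1 || gold_fp_rate < 0 || gold_fp_rate > 1) {
    rlang::abort("rates must lie in [0, 1].")
  }
  if (any(artifact_positions < 1 | artifact_positions > reference$length)) {
    rlang::abort("config error: artifact position outside the genome.")
  }
  structure(list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    reference = reference, baseline_depth = baseline_depth, kits = kits,
    smooth_scale = smooth_scale, noise_sd = noise_sd, sample_sd = sample_sd,
    dips = dips, numt_peaks = numt_peaks, error_rate = error_rate,
    polyC_multiplier = polyC_multiplier,
    n_homoplasmic = as.integer(n_homoplasmic),
    n_heteroplasmic = as.integer(n_heteroplasmic),
    het_vaf_range = het_vaf_range,
    artifact_positions = as.integer(artifact_positions),
    artifact_vaf_range = artifact_vaf_range,
    gold_fp_rate = gold_fp_rate
  ), class = "sim_config")
}

# smooth positive shape with mean 1 for one kit: a few random harmonics on
# the circle, exponentiated and normalized
kit_shape <- function(L, scale, n_harmonics = 4) {
  p <- seq_len(L) / L
  s <- numeric(L)
  for (h in seq_len(n_harmonics)) {
    s <- s + stats::rnorm(1, 0, scale / h) * sin(2 * pi * h * p) +
      stats::rnorm(1, 0, scale / h) * cos(2 * pi * h * p)
  }
  e <- exp(s)
  e / mean(e)
}

#' Simulate an off-target mtDNA cohort
#'
#' Draws, for every sample: a per-base Poisson depth around
#' `baseline_depth x kit shape x dip multiplier x` mean-one log-normal
#' noise; variant reads at each programmed site as
#' `Binomial(depth, vaf_eff)` where `vaf_eff` folds the base error into the
#' true fraction; error reads at clean positions at `error_rate` (elevated
#' `polyC_multiplier`-fold inside the poly-C tract), split uniformly among
#' the three non-reference bases. Gold-standard call sets contain every
#' homoplasmic and heteroplasmic truth site plus Sanger-like false
#' positives at `gold_fp_rate` per base. Identical seeds reproduce
#' identical cohorts.
#'
#' @param config A [sim_config()].
#' @return List with `pileups` (named list of pileup tibbles, one per
#'   sample), `truth` (tibble `sample_id`, `position`, `ref`, `alt`,
#'   `true_vaf`, `type`), `gold` (tibble `sample_id`, `position`, `ref`,
#'   `alt`), `profiles` (named list of [coverage_profile()]s), and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ref <- config$reference
  L <- ref$length
  ref_bases <- strsplit(ref$sequence, "")[[1]]
  callable <- which(ref_bases != "N")

  with_preserved_rng({
    set.seed(config$seed)
    kit_of <- rep_len(config$kits, config$n_samples)
    shapes <- purrr::map(unique(kit_of), function(k)
      kit_shape(L, config$smooth_scale))
    names(shapes) <- unique(kit_of)
    # arithmetic per-sample sub-seeds: independent of n_samples, so a cohort
    # can grow without disturbing the samples already drawn
    s0 <- as.double(config$seed %% 94906265L)
    sub_seeds <- as.integer((s0 * 94906249 + seq_len(config$n_samples) * 2654435) %%
                              (2^31 - 1))

    dip_mult <- rep(1, L)
    for (i in seq_len(nrow(config$dips))) {
      idx <- region_positions(config$dips$start[i], config$dips$end[i], L)
      dip_mult[idx] <- dip_mult[idx] * config$dips$multiplier[i]
    }
    if (!is.null(config$numt_peaks) && nrow(config$numt_peaks) > 0) {
      for (i in seq_len(nrow(config$numt_peaks))) {
        idx <- region_positions(config$numt_peaks$start[i],
                                config$numt_peaks$end[i], L)
        dip_mult[idx] <- dip_mult[idx] * config$numt_peaks$multiplier[i]
      }
    }
    pc <- ref$special_regions[ref$special_regions$label == "polyC", ]
    err_rate <- rep(config$error_rate, L)
    if (nrow(pc) > 0) {
      idx <- region_positions(pc$start[1], pc$end[1], L)
      err_rate[idx] <- pmin(0.5, err_rate[idx] * config$polyC_multiplier)
    }
    other_bases <- lapply(c(A = "A", C = "C", G = "G", T = "T"), function(b)
      setdiff(c("A", "C", "G", "T"), b))

    sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
    pileups <- vector("list", config$n_samples)
    profiles <- vector("list", config$n_samples)
    truth_rows <- vector("list", config$n_samples)
    gold_rows <- vector("list", config$n_samples)

    for (si in seq_len(config$n_samples)) {
      set.seed(sub_seeds[si])
      sid <- sample_ids[si]
      f_s <- if (config$sample_sd > 0) {
        stats::rlnorm(1, -config$sample_sd^2 / 2, config$sample_sd)
      } else 1
      noise <- if (config$noise_sd > 0) {
        stats::rlnorm(L, -config$noise_sd^2 / 2, config$noise_sd)
      } else rep(1, L)
      lambda <- config$baseline_depth * f_s * shapes[[kit_of[si]]] * dip_mult * noise
      depth <- stats::rpois(L, lambda)

      # programmed variants: homoplasmic + private heteroplasmic + shared artifacts
      avoid <- c(3107L, config$artifact_positions)
      hom_pos <- sample(setdiff(callable, avoid), config$n_homoplasmic)
      het_pos <- sample(setdiff(callable, c(avoid, hom_pos)),
                        config$n_heteroplasmic)
      het_vaf <- stats::runif(config$n_heteroplasmic,
                              config$het_vaf_range[1], config$het_vaf_range[2])
      art_vaf <- stats::runif(length(config$artifact_positions),
                              config$artifact_vaf_range[1],
                              config$artifact_vaf_range[2])
      var_pos <- c(hom_pos, het_pos, config$artifact_positions)
      var_vaf <- c(rep(1, length(hom_pos)), het_vaf, art_vaf)
      var_type <- c(rep("homoplasmic", length(hom_pos)),
                    rep("heteroplasmic", length(het_pos)),
                    rep("artifact", length(config$artifact_positions)))
      var_alt <- purrr::map_chr(var_pos, function(p)
        sample(other_bases[[ref_bases[p]]], 1))

      counts <- matrix(0L, nrow = L, ncol = 4,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
      ref_col <- match(ref_bases, c("A", "C", "G", "T"))
      # clean positions: error reads split among the three alternates
      n_err <- stats::rbinom(L, depth, err_rate)
      n_err[var_pos] <- 0L
      n_err[is.na(ref_col)] <- 0L
      err_idx <- which(n_err > 0)
      for (p in err_idx) {
        split3 <- stats::rmultinom(1, n_err[p], rep(1 / 3, 3))[, 1]
        counts[p, other_bases[[ref_bases[p]]]] <- as.integer(split3)
      }
      ref_reads <- depth - rowSums(counts)
      ok <- which(!is.na(ref_col))
      counts[cbind(ok, ref_col[ok])] <- as.integer(ref_reads[ok])
      # variant positions: v ~ Binomial(depth, vaf adjusted for error)
      vaf_eff <- var_vaf * (1 - err_rate[var_pos]) +
        (1 - var_vaf) * err_rate[var_pos] / 3
      v <- stats::rbinom(length(var_pos), depth[var_pos], vaf_eff)
      counts[var_pos, ] <- 0L
      counts[cbind(var_pos, match(var_alt, c("A", "C", "G", "T")))] <- as.integer(v)
      counts[cbind(var_pos, ref_col[var_pos])] <-
        as.integer(depth[var_pos] - v)

      usable <- rowSums(counts)
      pileups[[si]] <- tibble::tibble(
        position = seq_len(L), ref = ref_bases,
        depth = as.integer(usable),
        A = counts[, "A"], C = counts[, "C"],
        G = counts[, "G"], T = counts[, "T"])
      profiles[[si]] <- coverage_profile(as.integer(usable), L, sid)
      truth_rows[[si]] <- tibble::tibble(
        sample_id = sid, position = var_pos,
        ref = ref_bases[var_pos], alt = var_alt,
        true_vaf = var_vaf, type = var_type,
        sim_depth = depth[var_pos], sim_v = v)

      # Sanger-like gold standard: truth sites plus rare false positives
      real <- var_type != "artifact"
      n_fp <- stats::rbinom(1, L, config$gold_fp_rate)
      fp_pos <- if (n_fp > 0) {
        sample(setdiff(callable, var_pos), n_fp)
      } else integer(0)
      fp_alt <- purrr::map_chr(fp_pos, function(p)
        sample(other_bases[[ref_bases[p]]], 1))
      gold_rows[[si]] <- dplyr::bind_rows(
        tibble::tibble(sample_id = sid, position = var_pos[real],
                       ref = ref_bases[var_pos[real]], alt = var_alt[real],
                       is_fp = FALSE),
        tibble::tibble(sample_id = sid, position = fp_pos,
                       ref = ref_bases[fp_pos], alt = fp_alt,
                       is_fp = TRUE))
    }
    names(pileups) <- sample_ids
    names(profiles) <- sample_ids
    list(pileups = pileups,
         truth = dplyr::bind_rows(truth_rows),
         gold = dplyr::bind_rows(gold_rows),
         profiles = profiles,
         kit_of = stats::setNames(kit_of, sample_ids),
         config = config)
  })
}

#' Detection and interval-coverage rates across a heteroplasmy grid
#'
#' Programs heteroplasmic sites across a grid of true fractions and mean
#' depths, pushes the simulated pileup columns through the full caller
#' ([call_variants()]) and reports, per grid cell, the detection rate and
#' the fraction of detected sites whose exact 95% interval contains the
#' true fraction.
#'
#' @param true_vafs Numeric vector of programmed heteroplasmy fractions.
#' @param depths Numeric vector of mean read depths; per-site depth is
#'   Poisson around each value.
#' @param n_sites Replicate sites per grid cell (default 300).
#' @param thresholds A [calling_thresholds()] set.
#' @param seed Integer seed.
#' @param level Confidence level for the heteroplasmy interval.
#' @return Tibble: `true_vaf`, `mean_depth`, `n_sites`, `detected`,
#'   `detection_rate`, `ci_coverage` (NA when nothing was detected).
#' @export
recovery_experiment <- function(true_vafs = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9),
                                depths = c(10, 20, 30, 50, 100),
                                n_sites = 300L,
                                thresholds = calling_thresholds(),
                                seed = 1L, level = 0.95) {
  grid <- tidyr::expand_grid(true_vaf = true_vafs, mean_depth = depths)
  with_preserved_rng({
    set.seed(seed)
    rows <- purrr::pmap(grid, function(true_vaf, mean_depth) {
      n <- stats::rpois(n_sites, mean_depth)
      v <- stats::rbinom(n_sites, n, true_vaf)
      pu <- tibble::tibble(position = seq_len(n_sites), ref = "A",
                           depth = as.integer(n),
                           A = as.integer(n - v), C = 0L,
                           G = as.integer(v), T = 0L)
      calls <- call_variants(pu, thresholds, level = level)
      det <- nrow(calls)
      tibble::tibble(
        true_vaf = true_vaf, mean_depth = mean_depth,
        n_sites = n_sites, detected = det,
        detection_rate = det / n_sites,
        ci_coverage = if (det > 0) {
          mean(calls$ci_low <= true_vaf & true_vaf <= calls$ci_high)
        } else NA_real_)
    })
    dplyr::bind_rows(rows)
  })
}
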