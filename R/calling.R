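#' Calling thresholds
#'
#' The threshold set governing SNV calling and heteroplasmy screening:
#' a call requires total depth `n >= min_total_depth` (default 5), variant
#' reads `v >= min_variant_reads` (default 3) and variant allele fraction
#' `v/n >= min_vaf` (default 0.10). Heteroplasmy is classified inside the
#' `het_band` (10-90% by default); cohort-level heteroplasmy screening
#' requires a sample mean depth strictly above `het_screen_mean_depth`
#' (default 30); overall sample QC uses `qc_mean_depth` (default 20);
#' variant read counts at or below `background_max_reads` (default 2) are
#' treated as background error; positions heteroplasmic in at least
#' `recurrent_min_samples` samples (default 3) are flagged as recurrent
#' artifacts.
#'
#' @param min_total_depth,min_variant_reads,min_vaf Calling thresholds.
#' @param het_band Length-2 numeric, the heteroplasmy band as proportions.
#' @param het_screen_mean_depth,qc_mean_depth Mean-depth thresholds (fold).
#' @param background_max_reads,recurrent_min_samples Artifact thresholds.
#' @return A list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(min_total_depth = 5L,
                               min_variant_reads = 3L,
                               min_vaf = 0.10,
                               het_band = c(0.10, 0.90),
                               het_screen_mean_depth = 30,
                               qc_mean_depth = 20,
                               background_max_reads = 2L,
                               recurrent_min_samples = 3L) {
  if (!(min_vaf > 0 && min_vaf < 1)) rlang::abort("`min_vaf` must be in (0, 1).")
  if (length(het_band) != 2 || het_band[1] > het_band[2] ||
      het_band[1] <= 0 || het_band[2] >= 1 || min_vaf > het_band[1]) {
    rlang::abort("need 0 < min_vaf <= het_band[1] <= het_band[2] < 1.")
  }
  structure(list(
    min_total_depth = as.integer(min_total_depth),
    min_variant_reads = as.integer(min_variant_reads),
    min_vaf = min_vaf,
    het_band = het_band,
    het_screen_mean_depth = het_screen_mean_depth,
    qc_mean_depth = qc_mean_depth,
    background_max_reads = as.integer(background_max_reads),
    recurrent_min_samples = as.integer(recurrent_min_samples)
  ), class = "calling_thresholds")
}

#' Call SNVs from pileup columns
#'
#' For each position the top non-reference base (ties broken alphabetically
#' and logged) is the candidate alternate allele. A call is emitted iff
#' `n >= min_total_depth`, `v >= min_variant_reads` and
#' `v/n >= min_vaf`; each call carries the exact binomial 95% confidence
#' interval for the heteroplasmy fraction from [clopper_pearson()].
#' Position 3107 (reference placeholder) and any masked positions are
#' excluded before calling. Absence of a call is a value, not an error: the
#' per-position site ledger (attribute `ledger`) records every column with
#' its depth and a `low_coverage` flag.
#'
#' @param pileup Tibble from [read_pileup()] (`position`, `ref`, `depth`,
#'   `A`, `C`, `G`, `T`).
#' @param thresholds A [calling_thresholds()] set.
#' @param mask Optional tibble of 1-based inclusive regions (`start`,
#'   `end`) to exclude, e.g. from [read_bed_regions()].
#' @param level Confidence level for the heteroplasmy interval.
#' @return Tibble of calls: `position`, `ref`, `alt`, `v`, `n`, `vaf`,
#'   `ci_low`, `ci_high`, `filters`, `tied_alt`; attributes `ledger`
#'   (site-level tibble with `low_coverage`) and `secondary` (logged
#'   non-top alternate alleles with >= 1 read).
#' @export
call_variants <- function(pileup, thresholds = calling_thresholds(),
                          mask = NULL, level = 0.95) {
  stopifnot(inherits(thresholds, "calling_thresholds"))
  pu <- tibble::as_tibble(pileup)
  excluded <- pu$position == 3107L
  if (!is.null(mask) && nrow(mask) > 0) {
    for (i in seq_len(nrow(mask))) {
      excluded <- excluded | (pu$position >= mask$start[i] & pu$position <= mask$end[i])
    }
  }
  pu <- pu[!excluded, , drop = FALSE]
  cnt <- as.matrix(pu[, c("A", "C", "G", "T")])
  storage.mode(cnt) <- "integer"
  bases <- colnames(cnt)
  n <- as.integer(pu$depth)
  # zero out the reference column, then take the top remaining count;
  # which.max on the count matrix breaks ties alphabetically (column order)
  alt_cnt <- cnt
  ref_idx <- match(pu$ref, bases)
  ok_ref <- !is.na(ref_idx)
  alt_cnt[cbind(seq_len(nrow(cnt))[ok_ref], ref_idx[ok_ref])] <- -1L
  top_idx <- max.col(alt_cnt, ties.method = "first")
  v <- alt_cnt[cbind(seq_along(top_idx), top_idx)]
  v[v < 0L] <- 0L
  alt <- bases[top_idx]
  tied <- rowSums(alt_cnt == v & v > 0L) > 1L
  vaf <- ifelse(n > 0, v / n, 0)
  called <- n >= thresholds$min_total_depth &
    v >= thresholds$min_variant_reads &
    vaf >= thresholds$min_vaf
  ledger <- tibble::tibble(
    position = pu$position, ref = pu$ref, n = n,
    called = called,
    low_coverage = n < thresholds$min_total_depth
  )
  idx <- which(called)
  if (length(idx) > 0) {
    ci <- clopper_pearson(v[idx], n[idx], level = level)
    calls <- tibble::tibble(
      position = pu$position[idx], ref = pu$ref[idx], alt = alt[idx],
      v = as.integer(v[idx]), n = n[idx], vaf = vaf[idx],
      ci_low = ci$conf.low, ci_high = ci$conf.high,
      filters = NA_character_, tied_alt = tied[idx]
    )
  } else {
    calls <- tibble::tibble(position = integer(), ref = character(),
                            alt = character(), v = integer(), n = integer(),
                            vaf = numeric(), ci_low = numeric(),
                            ci_high = numeric(), filters = character(),
                            tied_alt = logical())
  }
  # secondary alleles (non-top alternates with reads) are logged, not called
  sec <- which(rowSums(alt_cnt > 0L) > 1L)
  secondary <- if (length(sec) > 0) {
    purrr::map_dfr(sec, function(i) {
      others <- setdiff(which(alt_cnt[i, ] > 0L), top_idx[i])
      tibble::tibble(position = pu$position[i], alt = bases[others],
                     v = as.integer(alt_cnt[i, others]))
    })
  } else {
    tibble::tibble(position = integer(), alt = character(), v = integer())
  }
  structure(calls, ledger = ledger, secondary = secondary)
}

#' Classify calls as homoplasmic, heteroplasmic or background
#'
#' Background iff the variant read count is at or below
#' `background_max_reads`; heteroplasmic iff the point estimate v/n lies
#' inside the heteroplasmy band (and not background); homoplasmic
#' otherwise. The point estimate, not the confidence interval, is the
#' classifier; the interval expresses uncertainty.
#'
#' @param calls Call tibble from [call_variants()].
#' @param thresholds A [calling_thresholds()] set.
#' @return `calls` with an added `het_class` column.
#' @export
classify_heteroplasmy <- function(calls, thresholds = calling_thresholds()) {
  stopifnot(inherits(thresholds, "calling_thresholds"))
  dplyr::mutate(tibble::as_tibble(calls),
    het_class = dplyr::case_when(
      v <= thresholds$background_max_reads ~ "background",
      vaf >= thresholds$het_band[1] & vaf <= thresholds$het_band[2] ~ "heteroplasmic",
      TRUE ~ "homoplasmic"
    ))
}

#' Flag recurrent cross-sample artifacts and poly-C calls
#'
#' A position classified heteroplasmic in at least `recurrent_min_samples`
#' samples is flagged `recurrent_artifact` in every sample carrying it:
#' genuine heteroplasmy is essentially private to an individual, so the
#' same apparently-heteroplasmic position recurring across unrelated
#' samples marks a systematic false call. Positions inside the poly-C tract
#' are flagged `polyC` unconditionally.
#'
#' @param cohort_calls Tibble of calls from >= 2 samples with a `sample_id`
#'   column (bind per-sample [call_variants()] outputs); must carry
#'   `het_class` (see [classify_heteroplasmy()]; added here if absent).
#' @param thresholds A [calling_thresholds()] set.
#' @param ref_model A [reference_model] supplying the poly-C region.
#' @return `cohort_calls` with `recurrent_artifact` and `polyC` logical
#'   columns and an updated `filters` string; attribute `artifact_sites`
#'   lists the flagged positions with their sample counts.
#' @export
flag_recurrent_artifacts <- function(cohort_calls,
                                     thresholds = calling_thresholds(),
                                     ref_model = synthetic_rcrs()) {
  calls <- tibble::as_tibble(cohort_calls)
  if (!"sample_id" %in% names(calls)) {
    rlang::abort("cohort_calls needs a `sample_id` column.")
  }
  if (dplyr::n_distinct(calls$sample_id) < 2) {
    rlang::abort("recurrent-artifact flagging needs calls from >= 2 samples.")
  }
  if (!"het_class" %in% names(calls)) {
    calls <- classify_heteroplasmy(calls, thresholds)
  }
  het_counts <- calls |>
    dplyr::filter(.data$het_class == "heteroplasmic") |>
    dplyr::distinct(.data$sample_id, .data$position) |>
    dplyr::count(.data$position, name = "n_samples")
  rec_pos <- het_counts$position[het_counts$n_samples >= thresholds$recurrent_min_samples]
  pc <- ref_model$special_regions[ref_model$special_regions$label == "polyC", ]
  calls <- calls |>
    dplyr::mutate(
      recurrent_artifact = .data$position %in% rec_pos,
      polyC = in_region(.data$position, pc$start[1], pc$end[1], ref_model$length),
      filters = purrr::pmap_chr(
        list(.data$filters, .data$recurrent_artifact, .data$polyC),
        function(f, r, p) {
          if (is.na(f %||% NA_character_)) f <- ""
          flags <- setdiff(strsplit(f, ";", fixed = TRUE)[[1]], "")
          if (r) flags <- union(flags, "recurrent_artifact")
          if (p) flags <- union(flags, "polyC")
          if (length(flags) == 0) NA_character_ else paste(flags, collapse = ";")
        }))
  structure(calls,
            artifact_sites = het_counts[het_counts$position %in% rec_pos, ])
}

#' Screen one sample for reportable heteroplasmic variants
#'
#' A sample is eligible for heteroplasmy screening iff its mean per-base
#' depth is strictly greater than `het_screen_mean_depth` (default 30-fold);
#' its candidate list is the heteroplasmic, unflagged calls.
#'
#' @param calls Classified (and artifact-flagged) call tibble for one
#'   sample.
#' @param coverage_profile A [coverage_profile()] for the same sample.
#' @param thresholds A [calling_thresholds()] set.
#' @return A list: `eligible` (logical), `mean_depth`, `candidates` tibble.
#' @export
screen_sample_for_het <- function(calls, coverage_profile,
                                  thresholds = calling_thresholds()) {
  stopifnot(inherits(coverage_profile, "coverage_profile"))
  calls <- tibble::as_tibble(calls)
  if (!"het_class" %in% names(calls)) {
    calls <- classify_heteroplasmy(calls, thresholds)
  }
  eligible <- coverage_profile$mean_depth > thresholds$het_screen_mean_depth
  unflagged <- is.na(calls$filters) | calls$filters == ""
  candidates <- calls[eligible & calls$het_class == "heteroplasmic" & unflagged, ]
  list(eligible = eligible,
       mean_depth = coverage_profile$mean_depth,
       candidates = candidates)
}
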