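#' Base-wise comparison of two call sets across a cohort
#'
#' Classifies every (sample, base) of the genome into exactly one category:
#' `codetected` (both platforms called a variant), `a_only`, `b_only`,
#' `low_coverage` (a site detected only by platform B where platform A's
#' read depth was below `min_depth`, so A never had the chance to call it),
#' or `concordant_ref`. Platform A is the one with per-base depth available
#' (the exome-derived set); platform B is the gold-standard set (e.g.
#' Sanger). The per-category counts partition
#' `total_bases = n_samples x genome_length`.
#'
#' @param set_a,set_b Call sets: tibbles with `sample_id` and `position`
#'   (one row per called site; duplicates within a sample are an error).
#' @param depth_a Per-base depth for platform A: a named list of
#'   [coverage_profile()]s keyed by sample id, or a single profile reused
#'   for all samples.
#' @param genome_length Genome length L (default 16,569).
#' @param n_samples Number of samples (default: number of distinct sample
#'   ids across both sets).
#' @param min_depth Depth below which platform A could not call (default 5).
#' @return Object of class `comparison_ledger`: per-sample category
#'   `counts`, site-level `sites` tibble for the non-reference categories,
#'   `total_bases`, and the parameters. `tidy()` returns the counts;
#'   `glance()` the cohort totals.
#' @export
compare_callsets <- function(set_a, set_b, depth_a,
                             genome_length = 16569L, n_samples = NULL,
                             min_depth = 5L) {
  set_a <- tibble::as_tibble(set_a)
  set_b <- tibble::as_tibble(set_b)
  for (s in list(set_a, set_b)) {
    if (!all(c("sample_id", "position") %in% names(s))) {
      rlang::abort("call sets need `sample_id` and `position` columns.")
    }
    if (anyDuplicated(s[, c("sample_id", "position")])) {
      rlang::abort("duplicate site within one sample in a call set.")
    }
  }
  samples <- sort(unique(c(set_a$sample_id, set_b$sample_id)))
  n_samples <- n_samples %||% length(samples)
  if (n_samples < length(samples)) {
    rlang::abort("n_samples smaller than the number of sample ids seen.")
  }
  get_depth <- function(sid, pos) {
    prof <- if (inherits(depth_a, "coverage_profile")) depth_a else depth_a[[sid]]
    if (is.null(prof)) rlang::abort(sprintf("no depth profile for sample %s.", sid))
    prof$depth[pos]
  }
  per_sample <- purrr::map(samples, function(sid) {
    pa <- set_a$position[set_a$sample_id == sid]
    pb <- set_b$position[set_b$sample_id == sid]
    co <- intersect(pa, pb)
    a_only <- setdiff(pa, pb)
    b_only_all <- setdiff(pb, pa)
    lowcov <- b_only_all[get_depth(sid, b_only_all) < min_depth]
    b_only <- setdiff(b_only_all, lowcov)
    sites <- dplyr::bind_rows(
      tibble::tibble(position = co, category = "codetected"),
      tibble::tibble(position = a_only, category = "a_only"),
      tibble::tibble(position = b_only, category = "b_only"),
      tibble::tibble(position = lowcov, category = "low_coverage"))
    sites$sample_id <- rep(sid, nrow(sites))
    n_co <- length(co); n_a <- length(a_only)
    n_b <- length(b_only); n_low <- length(lowcov)
    counts <- tibble::tibble(
      sample_id = sid,
      codetected = n_co, a_only = n_a, b_only = n_b, low_coverage = n_low,
      concordant_ref = genome_length - n_co - n_a - n_b - n_low)
    list(sites = sites, counts = counts)
  })
  counts <- dplyr::bind_rows(purrr::map(per_sample, "counts"))
  # samples beyond those with any call are all-reference
  extra <- n_samples - length(samples)
  structure(
    list(counts = counts,
         sites = dplyr::bind_rows(purrr::map(per_sample, "sites")),
         n_samples = n_samples,
         n_silent_samples = extra,
         genome_length = genome_length,
         total_bases = n_samples * genome_length,
         min_depth = min_depth),
    class = "comparison_ledger")
}

#' @export
print.comparison_ledger <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<comparison_ledger> %d samples x %d bp = %s bases\n",
              x$n_samples, x$genome_length, format(x$total_bases, big.mark = ",")))
  cat(sprintf("codetected %d | a_only %d | b_only %d | low_coverage %d\n",
              g$codetected, g$a_only, g$b_only, g$low_coverage))
  invisible(x)
}

#' @rdname compare_callsets
#' @param x A `comparison_ledger`.
#' @param ... Unused.
#' @method tidy comparison_ledger
#' @export
tidy.comparison_ledger <- function(x, ...) x$counts

#' @rdname compare_callsets
#' @method glance comparison_ledger
#' @export
glance.comparison_ledger <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    total_bases = x$total_bases,
    codetected = sum(x$counts$codetected),
    a_only = sum(x$counts$a_only),
    b_only = sum(x$counts$b_only),
    low_coverage = sum(x$counts$low_coverage),
    concordant_ref = sum(x$counts$concordant_ref) +
      x$n_silent_samples * x$genome_length)
}

#' Per-base error rates and the exact rate-ratio test between platforms
#'
#' Counts each platform's unconfirmed discordant base calls (discordant
#' sites that failed replicate confirmation) over the per-base denominator
#' `total_bases`, optionally excluding regions (e.g. the poly-C tract) from
#' both the numerators and the denominator: excluding a w-base region
#' removes `n_samples x w` bases. The two rates are compared with
#' [poisson_ratio_test()].
#'
#' @param ledger A [compare_callsets()] ledger (supplies the denominator).
#' @param discordances Tibble of replicate-checked discordant sites:
#'   `sample_id`, `position`, `platform` (`"a"` or `"b"`, the platform
#'   whose exclusive call was re-tested), `confirmed` (logical; FALSE means
#'   the call failed confirmation and counts as that platform's error).
#' @param exclude Optional region tibble (`start`, `end`) to drop.
#' @return List: `report` (tibble with one row per platform:
#'   `discordant_count`, `denominator`, `rate`, `percent`) and `test` (a
#'   `rate_ratio_test`, or `NULL` with a message when there are no
#'   unconfirmed discordances).
#' @export
error_rates <- function(ledger, discordances, exclude = NULL) {
  stopifnot(inherits(ledger, "comparison_ledger"))
  d <- tibble::as_tibble(discordances)
  need <- c("sample_id", "position", "platform", "confirmed")
  if (!all(need %in% names(d))) {
    rlang::abort(paste("discordances must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(d$platform %in% c("a", "b"))) {
    rlang::abort("platform must be 'a' or 'b'.")
  }
  excluded_width <- 0L
  if (!is.null(exclude) && nrow(exclude) > 0) {
    excluded_width <- sum(region_width(exclude$start, exclude$end,
                                       ledger$genome_length))
    inside <- rep(FALSE, nrow(d))
    for (i in seq_len(nrow(exclude))) {
      inside <- inside | in_region(d$position, exclude$start[i],
                                   exclude$end[i], ledger$genome_length)
    }
    d <- d[!inside, , drop = FALSE]
  }
  denominator <- ledger$total_bases - ledger$n_samples * excluded_width
  if (denominator <= 0) rlang::abort("empty denominator after exclusion.")
  unconf <- d[!d$confirmed, , drop = FALSE]
  count_a <- sum(unconf$platform == "a")
  count_b <- sum(unconf$platform == "b")
  report <- tibble::tibble(
    platform = c("a", "b"),
    discordant_count = c(count_a, count_b),
    denominator = denominator,
    rate = c(count_a, count_b) / denominator,
    percent = 100 * c(count_a, count_b) / denominator)
  test <- NULL
  if (count_a + count_b >= 1) {
    test <- poisson_ratio_test(count_a, count_b, denominator, denominator)
  } else {
    rlang::inform("no unconfirmed discordances: rate-ratio test undefined.")
  }
  list(report = report, test = test)
}

#' Per-sample coverage-threshold QC report
#'
#' Summarises, per sample, whether the mean per-base depth reaches the QC
#' threshold (default 20-fold) that the concordance analysis supports as
#' sufficient for detecting the vast majority of mtDNA SNVs, and how many
#' gold-standard sites fall below the per-base calling depth.
#'
#' @param gold_set Gold-standard call set: tibble `sample_id`, `position`.
#' @param profiles Named list of [coverage_profile()]s keyed by sample id.
#' @param mean_threshold Mean-depth QC threshold (default 20).
#' @param min_depth Per-base calling depth (default 5).
#' @return Tibble: `sample_id`, `mean_depth`, `frac_ge_min`, `pass`,
#'   `gold_sites`, `gold_sites_lost`.
#' @export
coverage_threshold_report <- function(gold_set, profiles,
                                      mean_threshold = 20, min_depth = 5L) {
  gold_set <- tibble::as_tibble(gold_set)
  rows <- purrr::imap(profiles, function(prof, sid) {
    gp <- gold_set$position[gold_set$sample_id == sid]
    tibble::tibble(
      sample_id = sid,
      mean_depth = prof$mean_depth,
      frac_ge_min = mean(prof$depth >= min_depth),
      pass = prof$mean_depth >= mean_threshold,
      gold_sites = length(gp),
      gold_sites_lost = sum(prof$depth[gp] < min_depth))
  })
  dplyr::bind_rows(rows)
}
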