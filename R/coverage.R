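#' Per-base coverage profile
#'
#' Builds the dense per-base read-depth vector for one sample over the
#' whole mitochondrial genome; positions absent from the pileup have depth
#' 0 and are included in the mean (the per-mtDNA-base mean counts uncovered
#' bases). Fractions of the genome covered to at least 5-, 20- and 30-fold
#' are always reported.
#'
#' @param pileup Tibble with `position` and `depth` columns (e.g. from
#'   [read_pileup()]), or an integer depth vector of length
#'   `genome_length`.
#' @param genome_length Genome length L (default 16,569).
#' @param sample_id Sample label.
#' @return Object of class `coverage_profile`: `sample_id`, `depth`
#'   (length-L integer vector), `mean_depth`, `fraction_at_least` (named
#'   at 5/20/30). `glance()` returns a one-row summary tibble;
#'   `tidy()` returns the per-base tibble.
#' @export
coverage_profile <- function(pileup, genome_length = 16569L,
                             sample_id = "sample") {
  if (is.numeric(pileup) && is.null(dim(pileup))) {
    depth <- as.integer(pileup)
    if (length(depth) != genome_length) {
      rlang::abort("depth vector length must equal genome_length.")
    }
  } else {
    pu <- tibble::as_tibble(pileup)
    if (anyDuplicated(pu$position)) {
      rlang::abort(sprintf("duplicate position %d in pileup.",
                           pu$position[duplicated(pu$position)][1]))
    }
    if (any(pu$position < 1 | pu$position > genome_length)) {
      rlang::abort("pileup position out of genome bounds.")
    }
    depth <- integer(genome_length)
    depth[pu$position] <- as.integer(pu$depth)
  }
  structure(
    list(sample_id = sample_id, depth = depth,
         genome_length = genome_length,
         mean_depth = sum(depth) / genome_length,
         fraction_at_least = c(
           "5" = mean(depth >= 5), "20" = mean(depth >= 20),
           "30" = mean(depth >= 30))),
    class = "coverage_profile")
}

#' @rdname coverage_profile
#' @param x A `coverage_profile`.
#' @param ... Unused.
#' @method glance coverage_profile
#' @export
glance.coverage_profile <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id,
                 mean_depth = x$mean_depth,
                 frac_ge_5 = unname(x$fraction_at_least["5"]),
                 frac_ge_20 = unname(x$fraction_at_least["20"]),
                 frac_ge_30 = unname(x$fraction_at_least["30"]))
}

#' @rdname coverage_profile
#' @method tidy coverage_profile
#' @export
tidy.coverage_profile <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id,
                 position = seq_len(x$genome_length),
                 depth = x$depth)
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: mean depth %.1f-fold, %.1f%% of %d bases >= 5x\n",
              x$sample_id, x$mean_depth, 100 * x$fraction_at_least["5"],
              x$genome_length))
  invisible(x)
}

#' Fraction of the genome covered to at least a threshold depth
#'
#' @param profile A [coverage_profile()].
#' @param threshold Depth threshold(s) (fold).
#' @return Numeric vector of proportions; non-increasing in the threshold,
#'   and 1 at threshold 0.
#' @export
fraction_at_least <- function(profile, threshold) {
  stopifnot(inherits(profile, "coverage_profile"))
  vapply(threshold, function(t) mean(profile$depth >= t), numeric(1))
}

#' Correlate mean off-target depth with relative mtDNA copy number
#'
#' Joins per-sample mean read depth with a qPCR-derived relative copy
#' number table and reports the squared Pearson correlation per requested
#' subgroup (tissue, capture kit, aligner), via [pearson_r2()]. Outlier
#' exclusion is an explicit filter: samples exceeding `max_mean_depth` or
#' `max_copy_number` are removed before correlating (never automatically).
#' Subgroups with fewer than 3 matched samples are skipped with a notice.
#'
#' @param profiles List of [coverage_profile()]s, or a tibble with
#'   `sample_id` and `mean_depth`.
#' @param copy_table Tibble: `sample_id`, `copy_number` (> 0), and
#'   optionally `tissue`, `kit`, `aligner`.
#' @param by Character vector of grouping columns among
#'   `c("tissue","kit","aligner")`; `NULL` for the pooled correlation only.
#' @param max_mean_depth,max_copy_number Exclusion cutoffs (default `Inf`).
#' @return Tibble: one row per subgroup (plus a pooled `"all"` row) with
#'   `r_squared`, `p_value`, `n`; skipped subgroups are reported in the
#'   `skipped` attribute.
#' @export
correlate_copy_number <- function(profiles, copy_table, by = NULL,
                                  max_mean_depth = Inf,
                                  max_copy_number = Inf) {
  md <- if (is.data.frame(profiles)) {
    tibble::as_tibble(profiles)
  } else {
    dplyr::bind_rows(purrr::map(profiles, glance))[, c("sample_id", "mean_depth")]
  }
  copy_table <- tibble::as_tibble(copy_table)
  if (any(copy_table$copy_number <= 0)) {
    rlang::abort("copy numbers must be > 0.")
  }
  joined <- dplyr::inner_join(md, copy_table, by = "sample_id") |>
    dplyr::filter(.data$mean_depth <= max_mean_depth,
                  .data$copy_number <= max_copy_number)
  groups <- list(all = joined)
  if (!is.null(by)) {
    missing_cols <- setdiff(by, names(joined))
    if (length(missing_cols) > 0) {
      rlang::abort(paste("grouping columns absent from copy_table:",
                         paste(missing_cols, collapse = ", ")))
    }
    sub <- joined |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_split()
    names(sub) <- purrr::map_chr(sub, function(g)
      paste(unlist(g[1, by]), collapse = "/"))
    groups <- c(groups, sub)
  }
  skipped <- character(0)
  rows <- purrr::imap(groups, function(g, label) {
    if (nrow(g) < 3 || stats::sd(g$mean_depth) == 0 || stats::sd(g$copy_number) == 0) {
      skipped <<- c(skipped, label)
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(subgroup = label),
                     pearson_r2(g$copy_number, g$mean_depth))
  })
  out <- dplyr::bind_rows(rows)
  if (length(skipped) > 0) {
    rlang::inform(paste("skipped subgroups with < 3 usable samples:",
                        paste(skipped, collapse = ", ")))
  }
  structure(out, skipped = skipped)
}
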