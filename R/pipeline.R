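#' Run the full off-target mtDNA analysis pipeline
#'
#' Orchestrates the downstream analysis chain for a cohort of per-sample
#' pileups: SNV calling with heteroplasmy intervals, heteroplasmy
#' classification, cohort-level recurrent-artifact and poly-C flagging,
#' variant annotation, per-sample coverage QC, and — when gold-standard
#' call sets are supplied — the base-wise concordance ledger and
#' coverage-threshold report. All outputs are written as plain-text VCF and
#' TSV under `out_dir`, alongside a manifest recording every effective
#' parameter value; a rerun on identical inputs produces identical outputs.
#'
#' @param pileups Named list of pileup tibbles (see [read_pileup()]), or a
#'   named character vector of pileup file paths, keyed by sample id.
#' @param ref_model A [reference_model].
#' @param thresholds A [calling_thresholds()] set.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param gold_set Optional gold-standard call set tibble (`sample_id`,
#'   `position`, `ref`, `alt`).
#' @param mask Optional region tibble (`start`, `end`) excluded from
#'   calling.
#' @return List: `calls` (cohort call tibble with flags and annotation),
#'   `artifact_sites`, `qc` (per-sample coverage summary), `screen`
#'   (per-sample heteroplasmy screen), and when `gold_set` is given,
#'   `ledger`, `threshold_report`.
#' @export
run_pipeline <- function(pileups, ref_model = synthetic_rcrs(),
                         thresholds = calling_thresholds(),
                         out_dir = NULL, gold_set = NULL, mask = NULL) {
  if (is.character(pileups)) {
    missing_files <- pileups[!file.exists(pileups)]
    if (length(missing_files) > 0) {
      rlang::abort(sprintf("pileup file not found: %s", missing_files[1]))
    }
    paths <- pileups
    pileups <- purrr::map(paths, read_pileup, genome_length = ref_model$length)
    names(pileups) <- names(paths) %||% basename(paths)
  }
  if (is.null(names(pileups)) || any(!nzchar(names(pileups)))) {
    rlang::abort("pileups must be named by sample id.")
  }
  sample_ids <- names(pileups)

  per_sample <- purrr::imap(pileups, function(pu, sid) {
    calls <- call_variants(pu, thresholds, mask = mask)
    calls <- classify_heteroplasmy(calls, thresholds)
    prof <- coverage_profile(pu[, c("position", "depth")],
                             genome_length = ref_model$length, sample_id = sid)
    list(calls = dplyr::mutate(calls, sample_id = sid, .before = 1),
         profile = prof)
  })
  profiles <- purrr::map(per_sample, "profile")
  cohort <- dplyr::bind_rows(purrr::map(per_sample, "calls"))
  artifact_sites <- tibble::tibble(position = integer(), n_samples = integer())
  if (length(sample_ids) >= 2 && nrow(cohort) > 0) {
    cohort <- flag_recurrent_artifacts(cohort, thresholds, ref_model)
    artifact_sites <- attr(cohort, "artifact_sites")
  }
  if (nrow(cohort) > 0) {
    ann <- annotate_variant(ref_model, cohort$position, cohort$ref, cohort$alt)
    cohort <- dplyr::bind_cols(
      cohort, ann[, c("gene", "feature_class", "consequence", "in_polyC")])
  }
  qc <- dplyr::bind_rows(purrr::map(profiles, glance)) |>
    dplyr::mutate(pass_qc = .data$mean_depth >= thresholds$qc_mean_depth)
  screen <- purrr::map(sample_ids, function(sid) {
    s <- screen_sample_for_het(cohort[cohort$sample_id == sid, ],
                               profiles[[sid]], thresholds)
    tibble::tibble(sample_id = sid, eligible = s$eligible,
                   mean_depth = s$mean_depth,
                   n_candidates = nrow(s$candidates))
  }) |> dplyr::bind_rows()

  out <- list(calls = cohort, artifact_sites = artifact_sites,
              qc = qc, screen = screen, profiles = profiles)

  if (!is.null(gold_set)) {
    set_a <- cohort[, c("sample_id", "position")]
    out$ledger <- compare_callsets(set_a, gold_set[, c("sample_id", "position")],
                                   profiles, genome_length = ref_model$length,
                                   min_depth = thresholds$min_total_depth)
    out$threshold_report <- coverage_threshold_report(
      gold_set, profiles, mean_threshold = thresholds$qc_mean_depth,
      min_depth = thresholds$min_total_depth)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in sample_ids) {
      sc <- cohort[cohort$sample_id == sid,
                   c("position", "ref", "alt", "v", "n", "vaf",
                     "ci_low", "ci_high", "filters")]
      write_vcf(sc[order(sc$position), ], ref_model,
                file.path(out_dir, paste0(sid, ".vcf")), sample_id = sid)
    }
    readr::write_tsv(cohort, file.path(out_dir, "cohort_calls.tsv"))
    readr::write_tsv(qc, file.path(out_dir, "coverage_qc.tsv"))
    readr::write_tsv(screen, file.path(out_dir, "het_screen.tsv"))
    if (nrow(artifact_sites) > 0) {
      readr::write_tsv(artifact_sites, file.path(out_dir, "artifact_sites.tsv"))
    }
    if (!is.null(out$ledger)) {
      readr::write_tsv(tidy(out$ledger), file.path(out_dir, "concordance_counts.tsv"))
      readr::write_tsv(out$threshold_report, file.path(out_dir, "coverage_threshold_report.tsv"))
    }
    manifest <- c(
      sprintf("tool\tmitohet %s", as.character(utils::packageVersion("mitohet"))),
      sprintf("reference\t%s", ref_model$name),
      sprintf("n_samples\t%d", length(sample_ids)),
      purrr::imap_chr(
        thresholds[],
        function(v, k) sprintf("threshold.%s\t%s", k, paste(v, collapse = ","))))
    readr::write_lines(manifest, file.path(out_dir, "manifest.tsv"))
  }
  invisible(out)
}
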