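#' Exact binomial interval width across read depths
#'
#' Plots the exact 95% confidence interval for the heteroplasmy fraction at
#' every variant allele count `v` from 1 to n - 1, for each total read
#' depth `n`: the intervals shrink as depth grows, so the deeper the
#' off-target coverage the closer the estimated heteroplasmy is likely to
#' be to the true level.
#'
#' @param depths Total read depths to show (default 10, 20, 30, 50).
#' @param level Confidence level (default 0.95).
#' @return A ggplot object.
#' @export
plot_ci_width <- function(depths = c(10, 20, 30, 50), level = 0.95) {
  df <- dplyr::bind_rows(purrr::map(depths, function(n)
    clopper_pearson(seq_len(n - 1), n, level)))
  df$depth <- factor(df$n, levels = sort(depths))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$conf.low)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$conf.high)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$depth), labeller = "label_both") +
    ggplot2::labs(x = "estimated heteroplasmy (v/n)",
                  y = sprintf("%.0f%% exact binomial interval", 100 * level)) +
    ggplot2::theme_minimal()
}

#' @rdname coverage_profile
#' @param object A `coverage_profile`.
#' @param window Smoothing window (bases) for the displayed depth.
#' @method autoplot coverage_profile
#' @export
autoplot.coverage_profile <- function(object, window = 101L, ...) {
  d <- tidy(object)
  if (window > 1) {
    k <- rep(1 / window, window)
    d$depth <- as.numeric(stats::filter(d$depth, k, circular = TRUE))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(title = object$sample_id,
                  x = "mtDNA position", y = "read depth (fold)") +
    ggplot2::theme_minimal()
}

#' Heteroplasmy estimates with exact intervals along the genome
#'
#' @param calls Classified call tibble (see [classify_heteroplasmy()]).
#' @return A ggplot object: v/n point estimates with exact 95% interval
#'   bars, coloured by heteroplasmy class.
#' @export
plot_heteroplasmy <- function(calls) {
  calls <- tibble::as_tibble(calls)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$position, y = .data$vaf,
                                      colour = .data$het_class)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             size = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "mtDNA position", y = "heteroplasmy (v/n)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
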