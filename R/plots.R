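#' Plot the score distribution by group
#'
#' Histogram of per-sample scores for the two cohorts, the usual way to
#' eyeball the separation between patient and comparison groups.
#'
#' @param data Data frame with columns `prs` and `group` (e.g. scores
#'   joined to phenotypes, or a [run_pipeline()] result's `scores` merged
#'   with its `phenotypes`).
#' @param binwidth Histogram bin width on the score scale (default 0.1).
#' @return A ggplot object.
#' @export
plot_prs_distribution <- function(data, binwidth = 0.1) {
  stopifnot(all(c("prs", "group") %in% names(data)))
  ggplot2::ggplot(filter(data, !is.na(.data$prs)),
                  ggplot2::aes(x = .data$prs, fill = .data$group)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, colour = "grey30") +
    ggplot2::labs(x = "LDL-C SNP score", y = "individuals",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios from a logistic fit
#'
#' @param object An `ldl_logit` object.
#' @param conf.level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A ggplot object (odds ratios with Wald CIs on a log scale;
#'   the intercept is omitted).
#' @export
autoplot.ldl_logit <- function(object, conf.level = 0.95, ...) {
  td <- filter(tidy(object, conf.level = conf.level),
               .data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$odds.ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
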