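#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline labs
#'   theme_minimal geom_errorbar geom_vline geom_col facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Manhattan plot of a single-variant association scan
#'
#' @param object A `pqtl_assoc`.
#' @param threshold Optional significance threshold drawn as a line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pqtl_assoc <- function(object, threshold = NULL, ...) {
  df <- dplyr::mutate(object, logp = -log10(p))
  p <- ggplot(df, aes(x = pos, y = logp, colour = chrom)) +
    geom_point(size = 0.8, show.legend = FALSE) +
    labs(x = "position (bp)", y = expression(-log[10](p))) +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = -log10(threshold),
                        linetype = "dashed", colour = "red")
  }
  p
}

#' Forest plot of Mendelian randomization results
#'
#' @param results `mr_result` tibble from [mr_screen()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_mr_forest <- function(results, ...) {
  df <- dplyr::mutate(results,
                      pair = paste(protein, outcome, sep = " → "))
  ggplot(df, aes(x = estimate, y = pair)) +
    geom_point() +
    geom_errorbar(aes(xmin = estimate - 1.96 * se,
                      xmax = estimate + 1.96 * se), width = 0.2) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "causal estimate (per SD protein)", y = NULL) +
    theme_minimal()
}

#' Bar plot of validation r-squared across score models
#'
#' @param evaluation Output of [evaluate_scores()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_score_performance <- function(evaluation, ...) {
  df <- dplyr::mutate(evaluation,
                      label = sprintf("p<%.1e", p_threshold))
  ggplot(df, aes(x = label, y = r2, fill = maf_rule)) +
    geom_col(position = "dodge") +
    facet_wrap(~protein) +
    labs(x = "p-value threshold", y = expression(r^2)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
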