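# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot genotype estimates from a fit
#'
#' Histogram of the accession BLUEs (fixed genotype) or BLUPs (random).
#'
#' @param object An `rp_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rp_fit
#' @export
autoplot.rp_fit <- function(object, bins = 40, ...) {
  lab <- if (object$spec$genotype == "fixed") "BLUE" else "BLUP"
  ggplot2::ggplot(object$genotype_effects,
                  ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = sprintf("Accession %s%s", lab,
                              if (!is.null(object$trait))
                                paste0(" (", object$trait, ")") else ""),
                  y = "Accessions") +
    ggplot2::theme_minimal()
}

#' Plot an outlier report
#'
#' MAD-rescaled standardized residuals by year, flagged records highlighted.
#'
#' @param object An `rp_outlier_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rp_outlier_report
#' @export
autoplot.rp_outlier_report <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$harvest_year,
                               y = .data$rescaled_residual,
                               colour = .data$holm_flag)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "Flagged") +
    ggplot2::labs(x = "Harvest year", y = "MAD-rescaled residual") +
    ggplot2::theme_minimal()
}

#' Plot a bias study
#'
#' Boxplots of the per-run relative biases and BLUE-regression statistics.
#'
#' @param object An `rp_bias_study`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rp_bias_study
#' @export
autoplot.rp_bias_study <- function(object, ...) {
  long <- object$runs |>
    dplyr::filter(.data$converged) |>
    tidyr::pivot_longer(c("rel_bias_G", "rel_bias_e", "intercept",
                          "slope", "r2"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$statistic, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(title = sprintf("Scenario %s", object$scenario),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-year coefficients of variation
#'
#' @param object An `rp_year_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rp_year_cv
#' @export
autoplot.rp_year_cv <- function(object, ...) {
  ggplot2::ggplot(object$per_year,
                  ggplot2::aes(x = .data$harvest_year, y = .data$cv)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_cv, linetype = 2) +
    ggplot2::labs(x = "Harvest year", y = "Residual CV") +
    ggplot2::theme_minimal()
}
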