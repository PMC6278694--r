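# tidy()/glance() methods so fits and reports drop into tidyverse workflows.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-model fit
#'
#' @param x An `rp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated effect: `term` ("genotype" or
#'   "year"), `level`, `estimate`, `type` ("BLUE", "BLUP" or "fixed").
#' @method tidy rp_fit
#' @export
tidy.rp_fit <- function(x, ...) {
  geno <- x$genotype_effects |>
    dplyr::transmute(term = "genotype", level = .data$accession_id,
                     estimate = .data$estimate, type = .data$type)
  yr <- x$year_effects |>
    dplyr::transmute(term = "year", level = as.character(.data$harvest_year),
                     estimate = .data$estimate, type = .data$type)
  dplyr::bind_rows(geno, yr)
}

#' One-row summary of a mixed-model fit
#'
#' @param x An `rp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variance components, average number of test
#'   years, REML log-likelihood, convergence and sizes.
#' @method glance rp_fit
#' @export
glance.rp_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_G = x$varcomp$sigma2_G,
    sigma2_Y = x$varcomp$sigma2_Y,
    sigma2_e_bar = x$varcomp$sigma2_e_bar,
    E_bar = x$E_bar,
    reml_loglik = x$reml_loglik,
    converged = x$converged,
    n_iter = x$n_iter,
    n_records = x$n_records,
    n_genotypes = x$n_genotypes,
    n_years = x$n_years)
}

#' Tidy an outlier report
#'
#' @param x An `rp_outlier_report`.
#' @param ... Unused.
#' @return The per-record score tibble (standardized and MAD-rescaled
#'   residuals, p-value, Holm flag).
#' @method tidy rp_outlier_report
#' @export
tidy.rp_outlier_report <- function(x, ...) x$scores

#' One-row summary of an outlier report
#'
#' @param x An `rp_outlier_report`.
#' @param ... Unused.
#' @return A one-row tibble: records in, flagged, kept, alpha, degeneracy.
#' @method glance rp_outlier_report
#' @export
glance.rp_outlier_report <- function(x, ...) {
  tibble::tibble(n_records = nrow(x$scores), n_flagged = x$n_flagged,
                 n_kept = nrow(x$enhanced), alpha = x$alpha,
                 degenerate = x$degenerate)
}

#' Tidy a bias study
#'
#' @param x An `rp_bias_study`.
#' @param ... Unused.
#' @return The per-run tibble of bias statistics.
#' @method tidy rp_bias_study
#' @export
tidy.rp_bias_study <- function(x, ...) x$runs

#' One-row summary of a bias study
#'
#' @param x An `rp_bias_study`.
#' @param ... Unused.
#' @return A one-row tibble of means over converged runs plus failure count.
#' @method glance rp_bias_study
#' @export
glance.rp_bias_study <- function(x, ...) {
  s <- stats::setNames(x$summary$mean, paste0("mean_", x$summary$statistic))
  dplyr::bind_cols(tibble::as_tibble(as.list(s)),
                   tibble::tibble(n_runs = nrow(x$runs),
                                  n_failed = x$n_failed,
                                  scenario = x$scenario))
}
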