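# Two-step outlier curation: fit the fixed-genotype model, score records by
# MAD-rescaled standardized residuals, flag with a Bonferroni-Holm test at
# family-wise level alpha, remove the flags, refit once on the enhanced data.

#' Standardize conditional residuals by their year-stratum error SD
#'
#' Each record's conditional residual is divided by the fitted error standard
#' deviation of its stratum, so records from noisy years are not over-flagged
#' relative to quiet ones.
#'
#' @param fit An `rp_fit` from the fixed-genotype model with per-year error
#'   variances ([spec_blue()]).
#' @param studentize Divide by the standard deviation of the conditional
#'   residual itself (stratum error SD corrected for leverage) instead of
#'   the plain stratum error SD. Off by default: the conventional scores
#'   divide by the stratum SD only.
#' @return Numeric vector aligned with `fit$residuals`. Strata whose variance
#'   sits at the numerical floor produce a warning and capped values.
#' @export
standardize_residuals <- function(fit, studentize = FALSE) {
  stopifnot(inherits(fit, "rp_fit"))
  sd_e <- sqrt(fit$residuals$sigma2_e)
  if (studentize) {
    # records that the fixed effects fit exactly (leverage ~ 1, e.g. the only
    # plot of an accession) carry no information about outlyingness: score 0
    exact <- fit$residuals$resid_sd^2 < 1e-8 * fit$residuals$sigma2_e
    sd_e <- ifelse(exact, Inf, fit$residuals$resid_sd)
  }
  floored <- fit$varcomp$boundary[paste0("sigma2_e.", fit$residuals$stratum)]
  floored[is.na(floored)] <- FALSE
  z <- fit$residuals$residual / sd_e
  if (any(floored)) {
    warning("error variance at the numerical floor in stratum/strata: ",
            paste(unique(fit$residuals$stratum[floored]), collapse = ", "),
            "; standardized residuals there are capped", call. = FALSE)
    cap <- 1e6
    z[floored] <- pmin(pmax(z[floored], -cap), cap)
  }
  z
}

#' Rescale scores by the median absolute deviation
#'
#' Centers at the median and divides by 1.4826 times the median absolute
#' deviation (the constant that makes the MAD consistent for a Gaussian SD),
#' giving a robust z-score that gross outliers cannot inflate.
#'
#' @param z Numeric vector (length >= 2), on the standardized-residual scale
#'   (so meaningful spreads are of order 1).
#' @return Rescaled vector. When the MAD is (numerically) zero no record can
#'   be scored: all zeros are returned with attribute `degenerate = TRUE`, so
#'   downstream flagging flags nothing. Spreads below `1e-8` — eight orders
#'   of magnitude under an error SD — are treated as zero, which keeps
#'   floating-point noise on noiseless data from being scored as structure.
#' @export
madr_rescale <- function(z) {
  stopifnot(length(z) >= 2)
  med <- stats::median(z)
  mad_raw <- stats::median(abs(z - med))
  if (mad_raw <= 1e-8) {
    out <- rep(0, length(z))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (z - med) / (1.4826 * mad_raw)
  attr(out, "degenerate") <- FALSE
  out
}

#' Bonferroni-Holm flags at family-wise level alpha
#'
#' Step-down Holm procedure: flags exactly the hypotheses rejected at
#' family-wise error rate `alpha`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param alpha Family-wise level (default 0.05).
#' @return Logical vector of flags (empty input gives an empty vector).
#' @export
holm_flag <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(logical(0))
  stopifnot(all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  stats::p.adjust(p, method = "holm") <= alpha
}

#' Detect outliers and build the enhanced dataset
#'
#' One detection pass — fit the fixed-genotype model, standardize residuals
#' by the per-year error SD, rescale by the MAD, convert to two-sided
#' standard-normal p-values, flag with Bonferroni-Holm at level `alpha` —
#' followed by removal of the flagged plots and a single refit on the
#' enhanced data. Flagged records are removed, never corrected.
#'
#' @param dataset A [historical_dataset()].
#' @param alpha Family-wise significance level (default 0.05).
#' @param drop_years_below_n Optional integer: drop whole years with fewer
#'   records than this before fitting (the manual remedy for years so sparse
#'   that the model cannot converge); `NULL` keeps all years and lets sparse
#'   years share a pooled error variance via `min_year_n`.
#' @param studentize Passed to [standardize_residuals()].
#' @param ... Passed to [fit_mixed()] (e.g. `min_year_n` through a custom
#'   `spec`, `method`, tolerances).
#' @param spec Model spec for both fits; default [spec_blue()].
#' @return An object of class `rp_outlier_report`: `scores` (per-record
#'   tibble with standardized and rescaled residuals, p-value, flag),
#'   `alpha`, `n_flagged`, `enhanced` (the dataset minus flagged records),
#'   `fit_initial`, `fit_enhanced` (identical to `fit_initial` when nothing
#'   was flagged), `dropped_years`, and `degenerate` (TRUE when the MAD was
#'   zero and nothing could be scored).
#' @export
detect_and_enhance <- function(dataset, alpha = 0.05, spec = spec_blue(),
                               drop_years_below_n = NULL, studentize = FALSE,
                               ...) {
  stopifnot(inherits(dataset, "historical_dataset"))
  dropped_years <- integer(0)
  if (!is.null(drop_years_below_n)) {
    counts <- table(dataset$harvest_year)
    dropped_years <- as.integer(names(counts)[counts < drop_years_below_n])
    if (length(dropped_years) > 0) {
      dataset <- rebuild_dataset(
        dplyr::filter(tibble::as_tibble(dataset),
                      !.data$harvest_year %in% dropped_years),
        dataset)
    }
  }
  fit0 <- fit_mixed(dataset, spec = spec, ...)
  z <- standardize_residuals(fit0, studentize = studentize)
  r <- madr_rescale(z)
  degenerate <- isTRUE(attr(r, "degenerate"))
  p <- 2 * stats::pnorm(-abs(r))
  flag <- if (degenerate) rep(FALSE, length(p)) else holm_flag(p, alpha)

  scores <- tibble::tibble(
    accession_id = fit0$residuals$accession_id,
    harvest_year = fit0$residuals$harvest_year,
    replicate_index = fit0$residuals$replicate_index,
    residual = fit0$residuals$residual,
    standardized_residual = z,
    rescaled_residual = as.numeric(r),
    p_value = p,
    holm_flag = flag)

  keep <- tibble::as_tibble(dataset)[!flag, , drop = FALSE]
  enhanced <- rebuild_dataset(keep, dataset)
  fit1 <- if (any(flag)) fit_mixed(enhanced, spec = spec, ...) else fit0

  structure(list(scores = scores, alpha = alpha,
                 n_flagged = sum(flag), degenerate = degenerate,
                 enhanced = enhanced, dropped_years = dropped_years,
                 fit_initial = fit0, fit_enhanced = fit1),
            class = "rp_outlier_report")
}

#' @export
print.rp_outlier_report <- function(x, ...) {
  cat(sprintf(
    "<rp_outlier_report> %d of %d records flagged at alpha = %g%s\n",
    x$n_flagged, nrow(x$scores), x$alpha,
    if (x$degenerate) " (degenerate spread: nothing scored)" else ""))
  if (length(x$dropped_years) > 0) {
    cat("  years dropped before fitting:",
        paste(x$dropped_years, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the per-record outlier audit table
#'
#' @param report An `rp_outlier_report`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_outlier_audit <- function(report, path) {
  stopifnot(inherits(report, "rp_outlier_report"))
  out <- report$scores |>
    dplyr::arrange(.data$accession_id, .data$harvest_year,
                   .data$replicate_index)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
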