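# Quantitative-genetic summaries of a curated dataset: entry-mean
# heritability, per-year coefficients of variation, year-pair correlations
# with a minimum-overlap rule, and origin frequency tables.

#' Entry-mean heritability
#'
#' Computes `h2 = sigma2_G / (sigma2_G + sigma2_e_bar / E_bar)`, the
#' repeatability of accession means when each accession is tested in
#' `E_bar` years on average with average error variance `sigma2_e_bar`.
#'
#' @param sigma2_G Genetic variance (> 0).
#' @param sigma2_e_bar Average of the per-year error variances (>= 0).
#' @param E_bar Average number of distinct years in which accessions were
#'   tested (>= 1).
#' @return A one-row tibble: `h2`, `sigma2_G`, `sigma2_e_bar`, `E_bar`.
#' @export
#' @examples
#' heritability(27.62, 16.08, 4.37)$h2 # 0.88 at 2 dp
heritability <- function(sigma2_G, sigma2_e_bar, E_bar) {
  stopifnot(sigma2_G > 0, sigma2_e_bar >= 0)
  if (any(E_bar < 1)) stop("E_bar must be >= 1", call. = FALSE)
  tibble::tibble(h2 = sigma2_G / (sigma2_G + sigma2_e_bar / E_bar),
                 sigma2_G = sigma2_G, sigma2_e_bar = sigma2_e_bar,
                 E_bar = E_bar)
}

#' Heritability from a random-genotype fit
#'
#' @param fit An `rp_fit` with genotype random (see [spec_varcomp()]).
#' @return As [heritability()], using the fit's genetic variance, average
#'   per-year error variance and average number of test years.
#' @export
heritability_from_fit <- function(fit) {
  stopifnot(inherits(fit, "rp_fit"))
  if (fit$spec$genotype != "random") {
    stop("heritability needs the genotype variance: refit with spec_varcomp()",
         call. = FALSE)
  }
  heritability(fit$varcomp$sigma2_G, fit$varcomp$sigma2_e_bar, fit$E_bar)
}

#' Per-year coefficient of variation
#'
#' From the variant with genotype random and year fixed ([spec_yearcv()]),
#' the CV of a year is the fitted error SD of that year divided by the
#' estimated year mean (population mean plus fixed year effect). Using the
#' year *mean* in the denominator, not the centred effect, keeps the CV on
#' the familiar relative-dispersion scale.
#'
#' @param fit An `rp_fit` from [spec_yearcv()].
#' @return An object of class `rp_year_cv`: `per_year` tibble
#'   (`harvest_year`, `sigma2_e`, `year_mean`, `cv`) plus summary fields
#'   `mean_cv`, `sd_cv`, `min_cv`, `max_cv`. A non-positive estimated year
#'   mean yields `NA` for that year with a warning.
#' @export
year_cv <- function(fit) {
  stopifnot(inherits(fit, "rp_fit"))
  if (!(fit$spec$genotype == "random" && fit$spec$year == "fixed")) {
    stop("year CV needs genotype random and year fixed: use spec_yearcv()",
         call. = FALSE)
  }
  per_year <- tibble::tibble(
    harvest_year = fit$year_effects$harvest_year,
    sigma2_e = unname(
      fit$varcomp$sigma2_e_by_year[as.character(fit$year_effects$harvest_year)]),
    year_mean = fit$mu_hat + fit$year_effects$estimate)
  per_year$cv <- sqrt(per_year$sigma2_e) / per_year$year_mean
  bad <- per_year$year_mean <= 0
  if (any(bad)) {
    warning("non-positive estimated year mean in year(s) ",
            paste(per_year$harvest_year[bad], collapse = ", "),
            "; their CV is undefined", call. = FALSE)
    per_year$cv[bad] <- NA_real_
  }
  cv <- per_year$cv[!is.na(per_year$cv)]
  structure(list(per_year = per_year,
                 mean_cv = mean(cv), sd_cv = stats::sd(cv),
                 min_cv = min(cv), max_cv = max(cv)),
            class = "rp_year_cv")
}

#' @export
print.rp_year_cv <- function(x, ...) {
  cat(sprintf("<rp_year_cv> %d years: mean %.3f +/- %.3f, range %.3f-%.3f\n",
              nrow(x$per_year), x$mean_cv, x$sd_cv, x$min_cv, x$max_cv))
  invisible(x)
}

#' Pearson correlations between pairs of years
#'
#' For every unordered pair of years sharing at least `min_overlap`
#' accessions with records in both years, the Pearson correlation of the
#' paired accession values. Within-year replicate plots are averaged per
#' accession first, so the correlation is between accession-level values.
#'
#' @param dataset A [historical_dataset()] (typically the enhanced data).
#' @param min_overlap Minimum number of shared accessions for a pair to
#'   qualify (default 50).
#' @return A list: `mean_r` (`NA` with a message when no pair qualifies),
#'   `n_pairs`, and `pairs`, a tibble `year1`, `year2`, `n_overlap`, `r`.
#' @export
year_pair_correlations <- function(dataset, min_overlap = 50) {
  acc_year <- tibble::as_tibble(dataset) |>
    dplyr::group_by(.data$accession_id, .data$harvest_year) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  years <- sort(unique(acc_year$harvest_year))
  by_year <- split(acc_year[c("accession_id", "value")], acc_year$harvest_year)
  combos <- if (length(years) >= 2) utils::combn(years, 2) else
    matrix(integer(0), nrow = 2)
  rows <- purrr::map(seq_len(ncol(combos)), function(i) {
    y1 <- combos[1, i]; y2 <- combos[2, i]
    a <- by_year[[as.character(y1)]]
    b <- by_year[[as.character(y2)]]
    common <- intersect(a$accession_id, b$accession_id)
    if (length(common) < min_overlap) return(NULL)
    r <- stats::cor(a$value[match(common, a$accession_id)],
                    b$value[match(common, b$accession_id)])
    tibble::tibble(year1 = y1, year2 = y2,
                   n_overlap = length(common), r = r)
  })
  pairs <- dplyr::bind_rows(rows)
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(year1 = integer(), year2 = integer(),
                            n_overlap = integer(), r = numeric())
    return(list(mean_r = NA_real_, n_pairs = 0L, pairs = pairs,
                no_qualifying_pairs = TRUE))
  }
  list(mean_r = mean(pairs$r), n_pairs = nrow(pairs), pairs = pairs,
       no_qualifying_pairs = FALSE)
}

#' Frequency table of accession origins
#'
#' Counts accessions by origin string (exact grouping, no geocoding),
#' descending, with origins below a rank cutoff collapsed into an
#' "Others (k origins)" row and a Total row appended.
#'
#' @param study A study tibble (see [read_study()]); the `country` column is
#'   tabulated, or `comment` when `use_comment_groups = TRUE` and a comment
#'   group is present for a row.
#' @param rank_cutoff Number of individually listed origins (default 22).
#' @param use_comment_groups Replace the country by the comment-column group
#'   (e.g. regrouped Germany / Soviet Union labels) where one is given?
#' @return A tibble `origin`, `n`, `percentage` (percentages of the total,
#'   1 dp).
#' @export
origin_table <- function(study, rank_cutoff = 22, use_comment_groups = FALSE) {
  if (nrow(study) == 0) {
    return(tibble::tibble(origin = character(), n = integer(),
                          percentage = numeric()))
  }
  origin <- study$country
  if (use_comment_groups && "comment" %in% names(study)) {
    grp <- study$comment
    has <- !is.na(grp) & grp != ""
    origin[has] <- grp[has]
  }
  origin[is.na(origin) | origin == ""] <- "Unknown"
  tab <- tibble::tibble(origin = origin) |>
    dplyr::count(.data$origin, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$origin)
  total <- sum(tab$n)
  if (nrow(tab) > rank_cutoff) {
    head_tab <- tab[seq_len(rank_cutoff), ]
    k <- nrow(tab) - rank_cutoff
    tail_row <- tibble::tibble(
      origin = sprintf("Others (%d origins)", k),
      n = total - sum(head_tab$n))
    tab <- dplyr::bind_rows(head_tab, tail_row)
  }
  tab$percentage <- round(100 * tab$n / total, 1)
  dplyr::bind_rows(tab, tibble::tibble(origin = "Total", n = total,
                                       percentage = 100))
}
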