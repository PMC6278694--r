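# Resampling studies: bias of variance components and BLUEs under three
# missing-data scenarios applied to a balanced accession x year grid, and the
# split-half precision of BLUEs.
#
# Random number policy: one master seed; run i draws from a seed derived by a
# fixed counter scheme, so runs are independent and individually reproducible.

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * as.numeric(i)) %% 2147483629)
}

#' Extract a balanced accession x year grid
#'
#' Keeps the accessions that have at least one record in every listed year,
#' averaging within-year replicate plots, so the result is a complete grid.
#'
#' @param dataset A [historical_dataset()].
#' @param years Years defining the grid (must all occur in the data).
#' @return An object of class `rp_balanced`: a tibble `accession_id`,
#'   `harvest_year`, `value` with attributes `accessions`, `years`, `trait`,
#'   `habit`.
#' @export
extract_balanced <- function(dataset, years) {
  years <- sort(as.integer(years))
  present <- unique(dataset$harvest_year)
  missing_years <- setdiff(years, present)
  if (length(missing_years) > 0) {
    stop("year(s) absent from the data: ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  cells <- tibble::as_tibble(dataset) |>
    dplyr::filter(.data$harvest_year %in% years) |>
    dplyr::group_by(.data$accession_id, .data$harvest_year) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  complete <- cells |>
    dplyr::count(.data$accession_id) |>
    dplyr::filter(.data$n == length(years))
  if (nrow(complete) == 0) {
    stop("no accession has records in every requested year", call. = FALSE)
  }
  grid <- cells |>
    dplyr::filter(.data$accession_id %in% complete$accession_id) |>
    dplyr::arrange(.data$accession_id, .data$harvest_year)
  out <- tibble::new_tibble(grid, class = "rp_balanced")
  attr(out, "accessions") <- sort(complete$accession_id)
  attr(out, "years") <- years
  attr(out, "trait") <- dataset_trait(dataset)
  attr(out, "habit") <- dataset_habit(dataset)
  out
}

balanced_to_dataset <- function(bal, rows = NULL) {
  rec <- if (is.null(rows)) tibble::as_tibble(bal) else tibble::as_tibble(rows)
  historical_dataset(rec[, c("accession_id", "harvest_year", "value")],
                     trait = attr(bal, "trait") %||% "FT",
                     habit = attr(bal, "habit") %||% "spring")
}

#' Subsample a balanced grid under a missing-data scenario
#'
#' Three scenarios remove years per accession from a complete grid:
#' * `"S1_random"` — each accession independently keeps `n_years_kept`
#'   randomly chosen years (ignorable missingness);
#' * `"S2_random_clusters"` — accessions are partitioned uniformly at random
#'   into `n_groups` clusters and every member of a cluster keeps the same
#'   randomly chosen `n_years_kept` years (block missingness, as produced by
#'   regeneration cohorts);
#' * `"S3_origin_groups"` — as S2, but the clusters are the provided origin
#'   groups.
#'
#' @param bal An [extract_balanced()] grid.
#' @param scenario One of `"S1_random"`, `"S2_random_clusters"`,
#'   `"S3_origin_groups"`.
#' @param n_years_kept Years kept per accession (default 3).
#' @param n_groups Number of random clusters for S2 (default 10).
#' @param groups Named character vector or tibble (`accession_id`, `group`)
#'   giving origin groups; required for S3.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `rp_scenario_sample`: `kept` tibble of retained
#'   records, `scenario`, `seed`, `n_points`, and the cluster assignment
#'   (`clusters`) for S2/S3.
#' @export
sample_scenario <- function(bal, scenario = c("S1_random",
                                              "S2_random_clusters",
                                              "S3_origin_groups"),
                            n_years_kept = 3, n_groups = 10, groups = NULL,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  years <- attr(bal, "years")
  accessions <- attr(bal, "accessions")
  A <- length(accessions)
  Y <- length(years)
  stopifnot(n_years_kept >= 1, n_years_kept <= Y)
  set.seed(seed)
  clusters <- NULL
  if (scenario == "S1_random") {
    year_sets <- lapply(seq_len(A), function(i) sort(sample(years, n_years_kept)))
    names(year_sets) <- accessions
  } else {
    if (scenario == "S2_random_clusters") {
      if (n_groups > A) stop("more clusters than accessions", call. = FALSE)
      assignment <- sample(rep_len(seq_len(n_groups), A))
      clusters <- tibble::tibble(accession_id = accessions,
                                 group = as.character(assignment))
    } else {
      if (is.null(groups)) {
        stop("scenario S3_origin_groups requires `groups`", call. = FALSE)
      }
      if (is.data.frame(groups)) {
        clusters <- tibble::tibble(accession_id = groups$accession_id,
                                   group = as.character(groups$group))
      } else {
        clusters <- tibble::tibble(accession_id = names(groups),
                                   group = as.character(groups))
      }
      missing_acc <- setdiff(accessions, clusters$accession_id)
      if (length(missing_acc) > 0) {
        stop("groups missing for accession(s): ",
             paste(utils::head(missing_acc, 5), collapse = ", "),
             call. = FALSE)
      }
      clusters <- clusters[clusters$accession_id %in% accessions, ]
    }
    labs <- sort(unique(clusters$group))
    set_by_group <- lapply(labs, function(g) sort(sample(years, n_years_kept)))
    names(set_by_group) <- labs
    year_sets <- set_by_group[clusters$group[match(accessions,
                                                   clusters$accession_id)]]
    names(year_sets) <- accessions
  }
  keep_tbl <- tibble::tibble(
    accession_id = rep(accessions, each = n_years_kept),
    harvest_year = as.integer(unlist(year_sets, use.names = FALSE)))
  kept <- dplyr::inner_join(tibble::as_tibble(bal), keep_tbl,
                            by = c("accession_id", "harvest_year"))
  structure(list(kept = kept, scenario = scenario, seed = seed,
                 n_points = nrow(kept), n_years_kept = n_years_kept,
                 clusters = clusters),
            class = "rp_scenario_sample")
}

#' Bias study under a missing-data scenario
#'
#' Fits the random-genotype model and the fixed-genotype (BLUE) model on the
#' balanced grid, then repeatedly subsamples the grid under `scenario`,
#' refits both models, and measures (i) the relative bias
#' `(d_hat - d) / d` of the genetic and average error variances against the
#' balanced-grid values and (ii) the intercept, slope and R-squared of the
#' regression of subsample BLUEs on balanced-grid BLUEs.
#'
#' @inheritParams sample_scenario
#' @param runs Number of subsampling runs (default 100).
#' @param seed Master seed; run `i` uses a seed derived from it.
#' @param min_year_n Passed to the model specs (the balanced designs here are
#'   small and complete, so per-year variances remain estimable).
#' @return An object of class `rp_bias_study`: `runs` tibble (one row per
#'   run: `rel_bias_G`, `rel_bias_e`, `intercept`, `slope`, `r2`,
#'   `converged`), `summary` (means and SDs over converged runs), `balanced`
#'   reference values, and `n_failed`.
#' @export
bias_study <- function(bal, scenario = "S1_random", runs = 100, seed = 1L,
                       n_years_kept = 3, n_groups = 10, groups = NULL,
                       min_year_n = 3) {
  ds_bal <- balanced_to_dataset(bal)
  fit_vc <- fit_mixed(ds_bal, spec_varcomp(min_year_n = min_year_n))
  fit_blue <- fit_mixed(ds_bal, spec_blue(min_year_n = min_year_n))
  d_G <- fit_vc$varcomp$sigma2_G
  d_e <- fit_vc$varcomp$sigma2_e_bar
  blue_bal <- blues(fit_blue)

  one_run <- function(i) {
    samp <- sample_scenario(bal, scenario, n_years_kept = n_years_kept,
                            n_groups = n_groups, groups = groups,
                            seed = derive_seed(seed, i))
    ds <- balanced_to_dataset(bal, samp$kept)
    res <- tryCatch({
      f_vc <- fit_mixed(ds, spec_varcomp(min_year_n = min_year_n))
      f_bl <- fit_mixed(ds, spec_blue(min_year_n = min_year_n))
      b <- dplyr::inner_join(blues(f_bl), blue_bal, by = "accession_id",
                             suffix = c("_sub", "_bal"))
      reg <- stats::lm(BLUE_sub ~ BLUE_bal, data = b)
      tibble::tibble(
        run = i,
        rel_bias_G = (f_vc$varcomp$sigma2_G - d_G) / d_G,
        rel_bias_e = (f_vc$varcomp$sigma2_e_bar - d_e) / d_e,
        intercept = unname(stats::coef(reg)[1]),
        slope = unname(stats::coef(reg)[2]),
        r2 = summary(reg)$r.squared,
        converged = f_vc$converged && f_bl$converged)
    }, error = function(e) {
      tibble::tibble(run = i, rel_bias_G = NA_real_, rel_bias_e = NA_real_,
                     intercept = NA_real_, slope = NA_real_, r2 = NA_real_,
                     converged = FALSE)
    })
    res
  }
  runs_tbl <- purrr::map_dfr(seq_len(runs), one_run)
  ok <- runs_tbl$converged
  summarise_ok <- function(v) c(mean = mean(v[ok]), sd = stats::sd(v[ok]))
  structure(list(
    runs = runs_tbl,
    scenario = scenario,
    n_failed = sum(!ok),
    balanced = list(sigma2_G = d_G, sigma2_e_bar = d_e, blues = blue_bal),
    summary = tibble::tibble(
      statistic = c("rel_bias_G", "rel_bias_e", "intercept", "slope", "r2"),
      mean = vapply(runs_tbl[, c("rel_bias_G", "rel_bias_e", "intercept",
                                 "slope", "r2")],
                    function(v) mean(v[ok]), numeric(1)),
      sd = vapply(runs_tbl[, c("rel_bias_G", "rel_bias_e", "intercept",
                               "slope", "r2")],
                  function(v) stats::sd(v[ok]), numeric(1)))),
    class = "rp_bias_study")
}

#' @export
print.rp_bias_study <- function(x, ...) {
  cat(sprintf("<rp_bias_study> scenario %s: %d runs (%d failed)\n",
              x$scenario, nrow(x$runs), x$n_failed))
  print(x$summary)
  invisible(x)
}

#' Split-half precision of BLUEs
#'
#' Repeatedly splits the records (plots) into two equally sized halves at
#' random, fits the BLUE model in each half, and correlates the BLUEs of the
#' accessions present in both halves. Accessions whose only record lands in
#' one half drop out of that run's correlation.
#'
#' @param dataset A [historical_dataset()] (typically the enhanced data).
#' @param runs Number of random splits (default 100).
#' @param seed Master seed; run `i` uses a derived seed.
#' @param min_year_n Error-variance pooling threshold for the half fits
#'   (halves are sparser than the full data).
#' @return A list: `mean_r`, `mean_n_common`, `n_failed`, and `per_run`
#'   tibble (`run`, `r`, `n_common`, `ok`).
#' @export
split_half_precision <- function(dataset, runs = 100, seed = 1L,
                                 min_year_n = 3) {
  n <- nrow(dataset)
  stopifnot(n >= 4)
  one_run <- function(i) {
    set.seed(derive_seed(seed, i))
    idx <- sample.int(n, floor(n / 2))
    half1 <- tibble::as_tibble(dataset)[idx, ]
    half2 <- tibble::as_tibble(dataset)[-idx, ]
    res <- tryCatch({
      f1 <- fit_mixed(rebuild_dataset(half1, dataset),
                      spec_blue(min_year_n = min_year_n))
      f2 <- fit_mixed(rebuild_dataset(half2, dataset),
                      spec_blue(min_year_n = min_year_n))
      b <- dplyr::inner_join(blues(f1), blues(f2), by = "accession_id",
                             suffix = c("_1", "_2"))
      tibble::tibble(run = i, r = stats::cor(b$BLUE_1, b$BLUE_2),
                     n_common = nrow(b), ok = TRUE)
    }, error = function(e) {
      tibble::tibble(run = i, r = NA_real_, n_common = NA_integer_,
                     ok = FALSE)
    })
    res
  }
  per_run <- purrr::map_dfr(seq_len(runs), one_run)
  list(mean_r = mean(per_run$r[per_run$ok]),
       mean_n_common = mean(per_run$n_common[per_run$ok]),
       n_failed = sum(!per_run$ok),
       per_run = per_run)
}
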