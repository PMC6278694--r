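# Generator for unbalanced historical-style phenotype data with known ground
# truth: additive genotype and year effects, per-year error variances,
# block-structured or random missingness, occasional duplicate plots, and
# optional gross-outlier contamination.

#' Simulation parameters
#'
#' Defaults are an "FT-spring-like" preset: grand mean 60 days, genetic
#' variance 27, year variance 49 and per-year error variances drawn uniformly
#' in \[9, 25\] — magnitudes typical of flowering time in a large spring
#' barley collection. About 1% of accession-year cells carry a second plot,
#' matching how often accessions are multiplied twice in a year during
#' regeneration.
#'
#' @param n_genotypes,n_years Grid dimensions.
#' @param mu Grand mean (trait units).
#' @param sigma2_G,sigma2_Y Genotype and year variances (trait units^2).
#' @param sigma2_e_range Length-2 range from which each year's error variance
#'   is drawn uniformly.
#' @param missingness `"random"` (i.i.d. cell occupancy), `"cohort_blocks"`
#'   (entry cohorts regenerated every `regen_interval` years — the structure
#'   room-temperature seed storage imposed) or `"origin_blocks"` (cohorts
#'   follow origin labels).
#' @param occupancy Probability a cell is observed under random missingness.
#' @param dup_rate Fraction of observed accession-year cells receiving a
#'   second plot (default 0.01).
#' @param outlier_rate Fraction of records contaminated by a gross error.
#' @param outlier_shift_sd Size of the contamination shift in units of the
#'   record's error SD (added to the value).
#' @param origin_labels Optional character vector of origin labels to sample
#'   from with a long-tailed distribution; default builds ~30 labels.
#' @param regen_interval,cohort_width Block-missingness controls: years
#'   between regenerations and entry-year spacing between cohorts.
#' @param trait,habit Metadata for the generated dataset.
#' @param seed Default seed used by [simulate_dataset()].
#' @return A list of class `rp_sim_params`.
#' @export
sim_params <- function(n_genotypes = 100, n_years = 8, mu = 60,
                       sigma2_G = 27, sigma2_Y = 49,
                       sigma2_e_range = c(9, 25),
                       missingness = c("random", "cohort_blocks",
                                       "origin_blocks"),
                       occupancy = 0.5, dup_rate = 0.01,
                       outlier_rate = 0, outlier_shift_sd = 10,
                       origin_labels = NULL,
                       regen_interval = 3, cohort_width = 1,
                       trait = "FT", habit = "spring", seed = 1L) {
  missingness <- match.arg(missingness)
  stopifnot(n_genotypes >= 2, n_years >= 1,
            sigma2_G >= 0, sigma2_Y >= 0,
            length(sigma2_e_range) == 2, all(sigma2_e_range >= 0),
            sigma2_e_range[1] <= sigma2_e_range[2],
            occupancy > 0, occupancy <= 1,
            dup_rate >= 0, dup_rate < 1,
            outlier_rate >= 0, outlier_rate < 1,
            regen_interval >= 1, cohort_width >= 1)
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_years = as.integer(n_years), mu = mu,
                 sigma2_G = sigma2_G, sigma2_Y = sigma2_Y,
                 sigma2_e_range = sigma2_e_range,
                 missingness = missingness, occupancy = occupancy,
                 dup_rate = dup_rate, outlier_rate = outlier_rate,
                 outlier_shift_sd = outlier_shift_sd,
                 origin_labels = origin_labels,
                 regen_interval = as.integer(regen_interval),
                 cohort_width = as.integer(cohort_width),
                 trait = trait, habit = habit, seed = seed),
            class = "rp_sim_params")
}

#' Cohort-block occupancy mask
#'
#' Assigns genotypes to entry cohorts and observes each genotype every
#' `regen_interval` years from its entry year, reproducing the non-random
#' block missingness of periodic seed regeneration. Years are indexed
#' 1..`n_years`; cohort `c` enters in year `((c - 1) * cohort_width) mod
#' n_years + 1`.
#'
#' @param n_genotypes,n_years Mask dimensions.
#' @param cohort_width Offset in entry years between consecutive cohorts.
#' @param regen_interval Years between successive regenerations
#'   (1 = observed every year).
#' @param n_cohorts Number of cohorts (default: enough that cohort entry
#'   years wrap once around the year range).
#' @param assignment Optional integer vector (length `n_genotypes`) of cohort
#'   memberships; default splits genotypes into consecutive equal blocks.
#' @return Logical `n_genotypes` x `n_years` matrix, TRUE = observed.
#' @export
#' @examples
#' m <- cohort_mask(1, 9, regen_interval = 3)
#' which(m[1, ]) # years 1, 4, 7
cohort_mask <- function(n_genotypes, n_years, cohort_width = 1,
                        regen_interval = 3, n_cohorts = NULL,
                        assignment = NULL) {
  stopifnot(regen_interval >= 1, cohort_width >= 1)
  if (is.null(n_cohorts)) {
    n_cohorts <- max(1L, ceiling(n_years / cohort_width))
  }
  if (is.null(assignment)) {
    assignment <- rep_len(rep(seq_len(n_cohorts),
                              each = ceiling(n_genotypes / n_cohorts)),
                          n_genotypes)
  }
  entry <- ((assignment - 1L) * cohort_width) %% n_years + 1L
  mask <- matrix(FALSE, n_genotypes, n_years)
  for (i in seq_len(n_genotypes)) {
    mask[i, seq(entry[i], n_years, by = regen_interval)] <- TRUE
  }
  mask
}

default_origin_labels <- function() {
  c("Ethiopia", "Germany", "Turkey", "Unknown", "Soviet Union", "India",
    "United States of America", "Nepal", "China", "Greece", "Japan", "Iran",
    "Italy", "Israel", "Pakistan", "Austria", "Afghanistan", "Libya",
    "Slovak Republic", "French Republic", "Sweden", "Poland",
    paste0("Origin", 23:40))
}

#' Simulate a historical-style dataset with known truth
#'
#' Generates plot values `mu + g_i + u_y + e`, with genotype effects
#' `g ~ N(0, sigma2_G)`, year effects `u ~ N(0, sigma2_Y)` and errors
#' `e ~ N(0, sigma2_e[y])` where each year's error variance is drawn
#' uniformly from `sigma2_e_range`. The missingness pattern, duplicate
#' plots and contamination follow the parameters; every genotype is
#' guaranteed at least one record (its mask row is redrawn when empty,
#' bounded retries).
#'
#' @param params An [sim_params()] object.
#' @param seed Overrides `params$seed`.
#' @return A list with `dataset` (a [historical_dataset()] with a study table
#'   attached) and `truth`: genotype effects, year effects and error
#'   variances, per-record errors, outlier flags and shifts, origins, params
#'   and seed. The truth is sufficient to recompute every generated value.
#' @export
simulate_dataset <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "rp_sim_params"))
  seed <- if (is.null(seed)) params$seed else seed
  set.seed(seed)
  nG <- params$n_genotypes
  nY <- params$n_years
  acc <- sprintf("ACC%05d", seq_len(nG))
  years <- 1951L + seq_len(nY) - 1L

  g <- stats::rnorm(nG, 0, sqrt(params$sigma2_G))
  u <- stats::rnorm(nY, 0, sqrt(params$sigma2_Y))
  s2e <- stats::runif(nY, params$sigma2_e_range[1], params$sigma2_e_range[2])

  origins <- if (is.null(params$origin_labels)) default_origin_labels() else
    params$origin_labels
  # long-tailed categorical: probability ~ 1/rank
  pr <- (1 / seq_along(origins)) / sum(1 / seq_along(origins))
  origin_of <- sample(origins, nG, replace = TRUE, prob = pr)

  mask <- switch(params$missingness,
    random = matrix(stats::runif(nG * nY) < params$occupancy, nG, nY),
    cohort_blocks = cohort_mask(nG, nY, params$cohort_width,
                                params$regen_interval,
                                assignment = sample.int(
                                  max(1L, ceiling(nY / params$cohort_width)),
                                  nG, replace = TRUE)),
    origin_blocks = {
      labs <- sort(unique(origin_of))
      entry_of_lab <- stats::setNames(sample.int(nY, length(labs),
                                                 replace = TRUE), labs)
      m <- matrix(FALSE, nG, nY)
      for (i in seq_len(nG)) {
        m[i, seq(entry_of_lab[[origin_of[i]]], nY,
                 by = params$regen_interval)] <- TRUE
      }
      m
    })
  # every genotype needs data; redraw empty rows (random missingness only)
  for (i in which(rowSums(mask) == 0)) {
    tries <- 0
    while (sum(mask[i, ]) == 0) {
      tries <- tries + 1
      if (tries > 100) {
        mask[i, sample.int(nY, 1)] <- TRUE
        break
      }
      if (params$missingness == "random") {
        mask[i, ] <- stats::runif(nY) < params$occupancy
      } else {
        mask[i, sample.int(nY, 1)] <- TRUE
      }
    }
  }

  obs <- which(mask, arr.ind = TRUE)
  cells <- tibble::tibble(gi = obs[, 1], yi = obs[, 2])
  n_dup <- round(params$dup_rate * nrow(cells))
  dup_cells <- if (n_dup > 0) cells[sample.int(nrow(cells), n_dup), ] else
    cells[0, ]
  plots <- dplyr::bind_rows(
    dplyr::mutate(cells, replicate_index = 1L),
    dplyr::mutate(dup_cells, replicate_index = 2L)) |>
    dplyr::arrange(.data$gi, .data$yi, .data$replicate_index)

  err <- stats::rnorm(nrow(plots), 0, sqrt(s2e[plots$yi]))
  n_out <- round(params$outlier_rate * nrow(plots))
  out_idx <- if (n_out > 0) sample.int(nrow(plots), n_out) else integer(0)
  shift <- numeric(nrow(plots))
  shift[out_idx] <- params$outlier_shift_sd * sqrt(s2e[plots$yi[out_idx]])

  value <- params$mu + g[plots$gi] + u[plots$yi] + err + shift
  records <- tibble::tibble(
    accession_id = acc[plots$gi],
    harvest_year = years[plots$yi],
    value = value,
    replicate_index = plots$replicate_index)

  study <- tibble::tibble(
    accession_id = acc,
    accession_number = sprintf("HOR %d", seq_len(nG)),
    sowing_date = NA_character_,
    harvest_year = years[apply(mask, 1, function(r) which(r)[1])],
    country = origin_of,
    comment = NA_character_)

  dataset <- historical_dataset(records, trait = params$trait,
                                habit = params$habit, study = study)
  truth <- list(
    seed = seed,
    params = params,
    mu = params$mu,
    genotype_effects = tibble::tibble(accession_id = acc, effect = g,
                                      origin = origin_of),
    year_effects = tibble::tibble(harvest_year = years, effect = u,
                                  sigma2_e = s2e),
    records = dplyr::mutate(records, error = err, outlier = shift != 0,
                            shift = shift))
  list(dataset = dataset, truth = truth)
}

#' Write a simulated dataset as study/assay files plus a truth sidecar
#'
#' @param sim Result of [simulate_dataset()].
#' @param out_dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  trait <- dataset_trait(sim$dataset)
  habit <- dataset_habit(sim$dataset)
  cap_habit <- if (habit == "spring") "Spring" else "Winter"
  study_path <- file.path(out_dir, sprintf("s_%s_Barley.txt", cap_habit))
  assay_path <- file.path(out_dir,
                          sprintf("a_Historical.Data_%s.txt", cap_habit))
  truth_path <- file.path(out_dir, sprintf("truth.%s.txt", trait))
  write_study(dataset_study(sim$dataset), study_path)
  write_assay(sim$dataset, assay_path)
  readr::write_tsv(sim$truth$records, truth_path, na = "", progress = FALSE)
  invisible(c(study = study_path, assay = assay_path, truth = truth_path))
}
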