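# Single entry point wiring the stages into the curation workflow:
# simulate -> curate -> fit-blues -> summarize -> validate. Each command
# writes its outputs plus a plain-text manifest under output_dir; everything
# is deterministic given the seeds echoed in the manifest. A thin shell
# wrapper over run_pipeline() ships in inst/scripts/regenphen.R.

#' Pipeline configuration
#'
#' Defaults match the workflow's standard constants: family-wise level 0.05
#' for outlier flagging, 50 overlapping accessions for year-pair
#' correlations, 100 resampling runs.
#'
#' @param trait,habit Trait code and growth habit.
#' @param study_path,assay_path Input files for file-based commands; either
#'   these or `dataset` must be given for non-simulate commands.
#' @param dataset Optional in-memory [historical_dataset()] (overrides the
#'   paths).
#' @param alpha Outlier significance level.
#' @param min_year_n Error-variance pooling threshold.
#' @param drop_years_below_n Optional hard year-exclusion threshold.
#' @param min_overlap Year-pair correlation overlap rule.
#' @param runs Resampling runs.
#' @param master_seed Master seed for all randomised stages.
#' @param balanced_years Years defining the balanced grid for the bias study
#'   (`validate`); default: all years in which every retained accession was
#'   tested is not required — years are chosen as those with the most
#'   accessions such that a non-empty grid exists.
#' @param scenario Missing-data scenario for the bias study.
#' @param n_years_kept,n_groups Scenario controls.
#' @param sim [sim_params()] for the simulate command.
#' @param output_dir Where outputs and the manifest are written.
#' @return A list of class `rp_config`.
#' @export
pipeline_config <- function(trait = "FT", habit = "spring",
                            study_path = NULL, assay_path = NULL,
                            dataset = NULL,
                            alpha = 0.05, min_year_n = 3,
                            drop_years_below_n = NULL,
                            min_overlap = 50, runs = 100, master_seed = 1L,
                            balanced_years = NULL,
                            scenario = "S1_random",
                            n_years_kept = 3, n_groups = 10,
                            sim = sim_params(),
                            output_dir = tempfile("regenphen")) {
  structure(list(trait = trait, habit = habit, study_path = study_path,
                 assay_path = assay_path, dataset = dataset, alpha = alpha,
                 min_year_n = min_year_n,
                 drop_years_below_n = drop_years_below_n,
                 min_overlap = min_overlap, runs = runs,
                 master_seed = as.integer(master_seed),
                 balanced_years = balanced_years, scenario = scenario,
                 n_years_kept = n_years_kept, n_groups = n_groups,
                 sim = sim, output_dir = output_dir),
            class = "rp_config")
}

load_config_dataset <- function(config) {
  if (!is.null(config$dataset)) return(config$dataset)
  if (is.null(config$assay_path)) {
    stop("config needs either `dataset` or `assay_path`", call. = FALSE)
  }
  study <- if (!is.null(config$study_path)) read_study(config$study_path)
  read_assay(config$assay_path, trait = config$trait, habit = config$habit,
             study = study)
}

write_manifest <- function(path, entries) {
  lines <- vapply(names(entries),
                  function(k) paste0(k, "=", paste(entries[[k]],
                                                   collapse = ",")),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run one pipeline command
#'
#' Commands:
#' * `simulate` — generate a synthetic dataset from `config$sim` and write
#'   study/assay/truth files;
#' * `curate` — outlier detection on the input data; writes the per-record
#'   audit table and `Data.corrected.<trait>.txt`;
#' * `fit-blues` — fit the BLUE model and write `BLUEs.<trait>.txt`;
#' * `summarize` — variance components, heritability, per-year CVs,
#'   year-pair correlations and the origin table;
#' * `validate` — split-half precision and the missing-data bias study.
#'
#' Every command writes `manifest_<command>.txt` (config echo, seeds, record
#' counts, convergence flags) into `config$output_dir`.
#'
#' @param command One of `"simulate"`, `"curate"`, `"fit-blues"`,
#'   `"summarize"`, `"validate"`.
#' @param config A [pipeline_config()].
#' @return A list with the stage's results and `files` (written paths),
#'   invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "curate", "fit-blues",
                                     "summarize", "validate"),
                         config = pipeline_config()) {
  command <- match.arg(command)
  stopifnot(inherits(config, "rp_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(command = command, trait = config$trait,
                   habit = config$habit, master_seed = config$master_seed)
  manifest_path <- file.path(out_dir,
                             paste0("manifest_", command, ".txt"))

  if (command == "simulate") {
    sim <- simulate_dataset(config$sim, seed = config$master_seed)
    files <- write_simulation(sim, out_dir)
    manifest <- c(manifest, list(
      n_records = nrow(sim$dataset),
      n_accessions = dplyr::n_distinct(sim$dataset$accession_id),
      n_years = dplyr::n_distinct(sim$dataset$harvest_year),
      n_true_outliers = sum(sim$truth$records$outlier),
      files = unname(files)))
    write_manifest(manifest_path, manifest)
    return(invisible(list(sim = sim, files = c(files,
                                               manifest = manifest_path))))
  }

  dataset <- load_config_dataset(config)

  if (command == "curate") {
    report <- detect_and_enhance(dataset, alpha = config$alpha,
                                 spec = spec_blue(min_year_n =
                                                    config$min_year_n),
                                 drop_years_below_n =
                                   config$drop_years_below_n)
    audit_path <- file.path(out_dir,
                            sprintf("outlier.audit.%s.txt", config$trait))
    write_outlier_audit(report, audit_path)
    files <- write_curation_outputs(report$fit_enhanced, report, out_dir)
    manifest <- c(manifest, list(
      alpha = config$alpha,
      n_records_in = nrow(dataset),
      n_flagged = report$n_flagged,
      n_records_kept = nrow(report$enhanced),
      dropped_years = report$dropped_years,
      fit_initial_converged = report$fit_initial$converged,
      fit_enhanced_converged = report$fit_enhanced$converged,
      files = c(audit_path, unname(files))))
    write_manifest(manifest_path, manifest)
    return(invisible(list(report = report,
                          files = c(audit = audit_path, files,
                                    manifest = manifest_path))))
  }

  if (command == "fit-blues") {
    fit <- fit_mixed(dataset, spec_blue(min_year_n = config$min_year_n))
    blue_tbl <- blues(fit) |> dplyr::arrange(.data$accession_id)
    names(blue_tbl) <- c("accession_id", "BLUE")
    path <- file.path(out_dir, sprintf("BLUEs.%s.txt", config$trait))
    readr::write_tsv(blue_tbl, path, progress = FALSE)
    manifest <- c(manifest, list(n_records = nrow(dataset),
                                 converged = fit$converged,
                                 n_iter = fit$n_iter, files = path))
    write_manifest(manifest_path, manifest)
    return(invisible(list(fit = fit, files = c(blues = path,
                                               manifest = manifest_path))))
  }

  if (command == "summarize") {
    fit_vc <- fit_mixed(dataset, spec_varcomp(min_year_n = config$min_year_n))
    h2 <- heritability_from_fit(fit_vc)
    fit_cv <- fit_mixed(dataset, spec_yearcv(min_year_n = config$min_year_n))
    cv <- year_cv(fit_cv)
    ypc <- year_pair_correlations(dataset, min_overlap = config$min_overlap)
    study <- dataset_study(dataset)
    org <- if (!is.null(study)) origin_table(study)
    files <- character(0)
    p <- file.path(out_dir, sprintf("heritability.%s.txt", config$trait))
    readr::write_tsv(h2, p, progress = FALSE); files <- c(files, p)
    p <- file.path(out_dir, sprintf("year.cv.%s.txt", config$trait))
    readr::write_tsv(cv$per_year, p, progress = FALSE); files <- c(files, p)
    p <- file.path(out_dir, sprintf("year.pairs.%s.txt", config$trait))
    readr::write_tsv(ypc$pairs, p, progress = FALSE); files <- c(files, p)
    if (!is.null(org)) {
      p <- file.path(out_dir, "origin.table.txt")
      readr::write_tsv(org, p, progress = FALSE); files <- c(files, p)
    }
    manifest <- c(manifest, list(
      n_records = nrow(dataset), h2 = round(h2$h2, 4),
      E_bar = round(fit_vc$E_bar, 4), mean_cv = round(cv$mean_cv, 5),
      mean_r = round(ypc$mean_r, 4), n_pairs = ypc$n_pairs,
      vc_converged = fit_vc$converged, cv_converged = fit_cv$converged,
      files = files))
    write_manifest(manifest_path, manifest)
    return(invisible(list(heritability = h2, year_cv = cv,
                          year_pairs = ypc, origin = org,
                          fit_varcomp = fit_vc,
                          files = c(files, manifest = manifest_path))))
  }

  # validate
  prec <- split_half_precision(dataset, runs = config$runs,
                               seed = config$master_seed,
                               min_year_n = config$min_year_n)
  years <- config$balanced_years
  if (is.null(years)) years <- sort(unique(dataset$harvest_year))
  bal <- extract_balanced(dataset, years)
  bias <- bias_study(bal, scenario = config$scenario, runs = config$runs,
                     seed = config$master_seed,
                     n_years_kept = min(config$n_years_kept, length(years)),
                     n_groups = config$n_groups,
                     min_year_n = config$min_year_n)
  files <- character(0)
  p <- file.path(out_dir, sprintf("precision.%s.txt", config$trait))
  readr::write_tsv(prec$per_run, p, progress = FALSE); files <- c(files, p)
  p <- file.path(out_dir, sprintf("bias.%s.%s.txt", config$scenario,
                                  config$trait))
  readr::write_tsv(bias$runs, p, progress = FALSE); files <- c(files, p)
  manifest <- c(manifest, list(
    runs = config$runs, scenario = config$scenario,
    mean_precision_r = round(prec$mean_r, 4),
    mean_n_common = round(prec$mean_n_common, 1),
    precision_failed = prec$n_failed,
    bias_failed = bias$n_failed,
    balanced_accessions = length(attr(bal, "accessions")),
    balanced_years = attr(bal, "years"),
    files = files))
  write_manifest(manifest_path, manifest)
  invisible(list(precision = prec, bias = bias,
                 files = c(files, manifest = manifest_path)))
}
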