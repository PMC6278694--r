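# Readers and writers for the tab-delimited study/assay layout used by
# genebank phenotype deposits (ISA-Tab style: plain TSV with a header line).
# Header names vary between deposits, so both readers run incoming names
# through a configurable alias map before matching.

# canonical name -> accepted aliases (compared after normalisation:
# lower case, spaces/dots/hyphens collapsed to underscores)
.default_aliases <- list(
  accession_id     = c("accession_id", "accessionid", "accession"),
  accession_number = c("accession_number", "accessionnumber", "accenumb"),
  sowing_date      = c("sowing_date", "sowingdate"),
  harvest_year     = c("harvest_year", "harvestyear", "year"),
  country          = c("country", "origin", "country_of_origin"),
  comment          = c("comment", "comments", "remark"),
  value            = c("value", "trait_value", "ft", "ph", "tgw", "phenotype")
)

normalize_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ .\\-]+", "_", x)
}

map_columns <- function(header, aliases) {
  norm <- normalize_header(header)
  out <- rep(NA_character_, length(header))
  for (canonical in names(aliases)) {
    hit <- which(norm %in% normalize_header(aliases[[canonical]]) & is.na(out))
    if (length(hit) > 0) out[hit[1]] <- canonical
  }
  out
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE,
                  show_col_types = FALSE)
}

parse_year_column <- function(x, path) {
  year <- suppressWarnings(as.integer(x))
  bad <- which(is.na(year) | year != suppressWarnings(as.numeric(x)))
  if (length(bad) > 0) {
    stop(sprintf("%s: unparseable harvest_year %s on data line(s) %s",
                 basename(path), dQuote(x[bad[1]]),
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  year
}

#' Read a study file
#'
#' Study files carry one row per accession-related entry with identifier and
#' origin metadata. Column headers are matched case-insensitively through an
#' alias map; unknown columns are preserved untouched.
#'
#' @param path Path to a tab-delimited study file.
#' @param aliases Alias map: a named list, canonical column name ->
#'   character vector of accepted header spellings.
#' @param year_bounds Optional length-2 integer vector; when given,
#'   harvest years outside the interval raise an error.
#' @return A tibble with canonical columns `accession_id`, `accession_number`,
#'   `sowing_date`, `harvest_year`, `country`, `comment` (absent optional
#'   columns are filled with `NA`) followed by any unrecognised columns, rows
#'   in file order. Dates are kept as text with a parsed `(day, month, year)`
#'   attached in columns `sowing_day`, `sowing_month`, `sowing_year` when the
#'   "day.month.year" pattern parses.
#' @export
read_study <- function(path, aliases = .default_aliases, year_bounds = NULL) {
  raw <- read_tsv_strict(path)
  mapping <- map_columns(names(raw), aliases)
  if (!"accession_id" %in% mapping) {
    stop(basename(path), ": missing mandatory column accession_id",
         call. = FALSE)
  }
  if (!"harvest_year" %in% mapping) {
    stop(basename(path), ": missing mandatory column harvest_year",
         call. = FALSE)
  }
  known <- !is.na(mapping)
  names(raw)[known] <- mapping[known]
  if (nrow(raw) == 0) {
    out <- tibble::tibble(accession_id = character(), accession_number = character(),
                          sowing_date = character(), harvest_year = integer(),
                          country = character(), comment = character())
    return(out)
  }
  raw$harvest_year <- parse_year_column(raw$harvest_year, path)
  if (!is.null(year_bounds)) {
    bad <- raw$harvest_year < year_bounds[1] | raw$harvest_year > year_bounds[2]
    if (any(bad)) {
      stop(sprintf("%s: harvest_year outside [%d, %d] on data line(s) %s",
                   basename(path), year_bounds[1], year_bounds[2],
                   paste(utils::head(which(bad), 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (any(raw$accession_id == "")) {
    stop(basename(path), ": empty accession_id", call. = FALSE)
  }
  for (opt in c("accession_number", "sowing_date", "country", "comment")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  }
  canonical <- c("accession_id", "accession_number", "sowing_date",
                 "harvest_year", "country", "comment")
  out <- raw[, c(canonical, setdiff(names(raw), canonical))]
  # day.month.year parsed alongside the text; no calendar arithmetic is done
  parts <- strsplit(ifelse(is.na(out$sowing_date), "", out$sowing_date),
                    ".", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 3L
  out$sowing_day <- ifelse(ok, suppressWarnings(
    as.integer(vapply(parts, function(p) p[1][1], ""))), NA_integer_)
  out$sowing_month <- ifelse(ok, suppressWarnings(
    as.integer(vapply(parts, function(p) p[2][1], ""))), NA_integer_)
  out$sowing_year <- ifelse(ok, suppressWarnings(
    as.integer(vapply(parts, function(p) p[3][1], ""))), NA_integer_)
  tibble::as_tibble(out)
}

#' Write a study table
#'
#' Inverse of [read_study()] for canonical tables: writes the canonical
#' columns plus any extras, tab-delimited with a header line.
#'
#' @param study A study tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  drop <- c("sowing_day", "sowing_month", "sowing_year")
  out <- study[, setdiff(names(study), drop)]
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read an assay file of plot-level phenotype records
#'
#' Each data line is one plot. Replicate indices are assigned by order of
#' appearance within (accession, year): the ~1% of accessions multiplied more
#' than once in a year yield indices 1, 2, ... Values that are missing or
#' non-positive are rejected into a report attached to the result, never
#' silently dropped; values that fail to parse as numbers (including decimal
#' commas) are an error naming the line.
#'
#' @param path Path to a tab-delimited assay file with columns for accession,
#'   harvest year and trait value (alias map as in [read_study()]).
#' @param trait,habit Trait code and growth habit of the file (one file holds
#'   one trait for one habit).
#' @param study Optional study tibble to attach.
#' @param aliases Alias map, as in [read_study()].
#' @return A [historical_dataset()]. Attribute `rejections` is a tibble
#'   (line, accession_id, harvest_year, value, reason) of rejected rows, so
#'   rows in = records kept + rejections.
#' @export
read_assay <- function(path, trait, habit, study = NULL,
                       aliases = .default_aliases) {
  raw <- read_tsv_strict(path)
  mapping <- map_columns(names(raw), aliases)
  for (col in c("accession_id", "harvest_year", "value")) {
    if (!col %in% mapping) {
      stop(basename(path), ": missing mandatory column ", col, call. = FALSE)
    }
  }
  known <- !is.na(mapping)
  names(raw)[known] <- mapping[known]
  if (nrow(raw) == 0) {
    ds <- historical_dataset(
      tibble::tibble(accession_id = character(), harvest_year = integer(),
                     value = numeric()),
      trait = trait, habit = habit, study = study)
    attr(ds, "rejections") <- tibble::tibble(
      line = integer(), accession_id = character(), harvest_year = integer(),
      value = character(), reason = character())
    return(ds)
  }
  raw$harvest_year <- parse_year_column(raw$harvest_year, path)

  val_chr <- trimws(raw$value)
  if (any(grepl("^-?[0-9]+,[0-9]+$", val_chr))) {
    stop(basename(path), ": decimal comma found in trait values; ",
         "expected '.' as decimal separator", call. = FALSE)
  }
  missing_val <- val_chr == "" | toupper(val_chr) == "NA"
  num <- suppressWarnings(as.numeric(val_chr))
  unparseable <- !missing_val & is.na(num)
  if (any(unparseable)) {
    stop(sprintf("%s: non-numeric trait value %s on data line(s) %s",
                 basename(path), dQuote(val_chr[which(unparseable)[1]]),
                 paste(utils::head(which(unparseable), 5), collapse = ", ")),
         call. = FALSE)
  }
  nonpos <- !missing_val & (num <= 0 | !is.finite(num))
  reject <- missing_val | nonpos
  rejections <- tibble::tibble(
    line = which(reject),
    accession_id = raw$accession_id[reject],
    harvest_year = raw$harvest_year[reject],
    value = val_chr[reject],
    reason = ifelse(missing_val[reject], "missing", "non-positive"))

  kept <- tibble::tibble(
    accession_id = raw$accession_id[!reject],
    harvest_year = raw$harvest_year[!reject],
    value = num[!reject])
  dup <- duplicated(kept)
  if (any(dup)) {
    warning(basename(path), ": ", sum(dup),
            " exact duplicate row(s) retained as distinct plots",
            call. = FALSE)
  }
  ds <- historical_dataset(kept, trait = trait, habit = habit, study = study)
  if (nrow(rejections) > 0) {
    message(basename(path), ": rejected ", nrow(rejections),
            " record(s); see attr(x, 'rejections')")
  }
  attr(ds, "rejections") <- rejections
  ds
}

#' Write an assay file
#'
#' @param dataset A `historical_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay <- function(dataset, path) {
  out <- tibble::as_tibble(dataset)[, c("accession_id", "harvest_year",
                                        "value", "replicate_index")]
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write curation outputs in the deposited layout
#'
#' Writes `Data.corrected.<trait>.txt` (the enhanced records, outliers
#' removed) and `BLUEs.<trait>.txt` (one row per accession: `accession_id`,
#' `BLUE`), both tab-delimited with a header and rows sorted by accession id
#' (then year, replicate) so re-runs are byte-identical.
#'
#' @param fit The BLUE-model fit on the enhanced data (see
#'   [detect_and_enhance()]); genotype effects must be fixed.
#' @param report The [detect_and_enhance()] report whose `enhanced` dataset
#'   the fit was computed on.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_curation_outputs <- function(fit, report, out_dir) {
  stopifnot(inherits(report, "rp_outlier_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  trait <- dataset_trait(report$enhanced)
  if (nrow(report$enhanced) != nrow(fit$residuals)) {
    stop("fit and report refer to different datasets", call. = FALSE)
  }
  corrected <- tibble::as_tibble(report$enhanced) |>
    dplyr::arrange(.data$accession_id, .data$harvest_year,
                   .data$replicate_index)
  corrected_path <- file.path(out_dir, sprintf("Data.corrected.%s.txt", trait))
  readr::write_tsv(
    corrected[, c("accession_id", "harvest_year", "value", "replicate_index")],
    corrected_path, progress = FALSE)

  blue_tbl <- blues(fit) |> dplyr::arrange(.data$accession_id)
  names(blue_tbl) <- c("accession_id", "BLUE")
  blues_path <- file.path(out_dir, sprintf("BLUEs.%s.txt", trait))
  readr::write_tsv(blue_tbl, blues_path, progress = FALSE)
  invisible(c(corrected = corrected_path, blues = blues_path))
}
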