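#' Construct a historical phenotype dataset
#'
#' A historical dataset holds plot-level phenotype records for one trait and
#' one growth habit. Growth habits are never pooled: flowering time is counted
#' from different reference dates for winter and spring material, and all
#' downstream models are fitted per trait x habit.
#'
#' @param records A data frame with columns `accession_id` (character),
#'   `harvest_year` (integer), `value` (numeric) and optionally
#'   `replicate_index` (integer, assigned by order of appearance when absent).
#'   Multiple rows for one accession in one year are distinct plots.
#' @param trait One of `"FT"` (flowering time, days), `"PH"` (plant height,
#'   cm), `"TGW"` (thousand grain weight, g).
#' @param habit One of `"spring"`, `"winter"`.
#' @param study Optional study table (one row per accession) as returned by
#'   [read_study()], carrying origin and identifier metadata.
#'
#' @return A tibble of records with class `historical_dataset` and attributes
#'   `trait`, `habit` and `study`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   accession_id = c("A1", "A1", "A2"),
#'   harvest_year = c(1970L, 1971L, 1970L),
#'   value = c(61, 63, 58)
#' )
#' historical_dataset(rec, trait = "FT", habit = "spring")
historical_dataset <- function(records, trait, habit, study = NULL) {
  trait <- match.arg(trait, c("FT", "PH", "TGW"))
  habit <- match.arg(habit, c("spring", "winter"))
  records <- tibble::as_tibble(records)
  required <- c("accession_id", "harvest_year", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records$accession_id <- as.character(records$accession_id)
  records$harvest_year <- as.integer(records$harvest_year)
  records$value <- as.numeric(records$value)
  if (!"replicate_index" %in% names(records)) {
    records <- records |>
      dplyr::group_by(.data$accession_id, .data$harvest_year) |>
      dplyr::mutate(replicate_index = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  records$replicate_index <- as.integer(records$replicate_index)
  records <- records[, c("accession_id", "harvest_year", "value",
                         setdiff(names(records),
                                 c("accession_id", "harvest_year", "value")))]
  out <- tibble::new_tibble(records, class = "historical_dataset")
  attr(out, "trait") <- trait
  attr(out, "habit") <- habit
  attr(out, "study") <- study
  validate_dataset(out)
  out
}

#' Validate the invariants of a historical dataset
#'
#' Checks that values are finite and strictly positive and that
#' (accession, year, replicate) keys are unique. Called by the constructor;
#' exported so readers and generators can re-check after manipulation.
#'
#' @param x A `historical_dataset`.
#' @return `x`, invisibly, or an error describing the violated invariant.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "historical_dataset"))
  if (nrow(x) > 0) {
    bad <- !is.finite(x$value) | x$value <= 0
    if (any(bad)) {
      stop("non-finite or non-positive trait values in rows: ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
    }
    if (any(x$accession_id == "" | is.na(x$accession_id))) {
      stop("empty accession_id", call. = FALSE)
    }
    key <- paste(x$accession_id, x$harvest_year, x$replicate_index, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (accession_id, harvest_year, replicate_index) keys",
           call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.historical_dataset <- function(x, ...) {
  cat(sprintf(
    "<historical_dataset> trait=%s habit=%s: %d records, %d accessions, %d years\n",
    dataset_trait(x), dataset_habit(x), nrow(x),
    dplyr::n_distinct(x$accession_id), dplyr::n_distinct(x$harvest_year)))
  NextMethod()
}

#' Dataset metadata accessors
#'
#' @param x A `historical_dataset`.
#' @return The trait code, habit, or study tibble (`NULL` when absent).
#' @export
dataset_trait <- function(x) attr(x, "trait", exact = TRUE)

#' @rdname dataset_trait
#' @export
dataset_habit <- function(x) attr(x, "habit", exact = TRUE)

#' @rdname dataset_trait
#' @export
dataset_study <- function(x) attr(x, "study", exact = TRUE)

# Rebuild a historical_dataset from a plain tibble of records, inheriting
# trait/habit/study from a template dataset. Used after filtering/subsetting,
# since dplyr verbs drop custom attributes.
rebuild_dataset <- function(records, template) {
  historical_dataset(
    tibble::as_tibble(records)[, c("accession_id", "harvest_year", "value",
                                   "replicate_index")],
    trait = dataset_trait(template),
    habit = dataset_habit(template),
    study = dataset_study(template)
  )
}
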