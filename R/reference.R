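#' Published variance components for the IPK barley collection
#'
#' Reference table of published variance-component estimates (genotypic,
#' year and average error variances), average numbers of test environments
#' and heritabilities for flowering time, plant height and thousand grain
#' weight of the IPK spring and winter barley collections, before
#' ("historical") and after ("enhanced") outlier curation. Useful for
#' checking the heritability arithmetic and for choosing realistic
#' simulation magnitudes.
#'
#' @return A tibble with columns `trait`, `habit`, `dataset`
#'   (historical/enhanced), `sigma2_G`, `sigma2_Y`, `sigma2_e`, `E`, `h2`.
#' @export
barley_reference_varcomp <- function() {
  path <- system.file("extdata", "barley_varcomp_reference.tsv",
                      package = "regenphen", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    trait = readr::col_character(),
                    habit = readr::col_character(),
                    dataset = readr::col_character(),
                    .default = readr::col_double()))
}
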