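#' Published desert-survey example tables
#'
#' Two small tables from a global desert soil survey of AM fungi, shipped as
#' plain TSV under `inst/extdata` and used in worked examples and tests:
#'
#' * `desert_survey_z()` — the published randomization-test Z values for six
#'   desert sites against three taxon-pool scales (global, continent,
#'   biogeographic realm).
#' * `desert_site_env()` — site climate and soil chemistry: mean annual
#'   temperature (°C), mean annual precipitation (mm), pH, available P
#'   (mg/100 g), total N (%) and organic C (%).
#'
#' @return A tibble.
#' @export
desert_survey_z <- function() {
  tibble::as_tibble(utils::read.delim(
    system.file("extdata", "desert_survey_z.tsv", package = "desertam"),
    stringsAsFactors = FALSE))
}

#' @rdname desert_survey_z
#' @export
desert_site_env <- function() {
  tibble::as_tibble(utils::read.delim(
    system.file("extdata", "desert_sites.tsv", package = "desertam"),
    stringsAsFactors = FALSE))
}
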