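# Packaged transcriptions of the published azoxystrobin soil experiment:
# PEC grid, microbial counts, enzyme activities, resistance and resilience
# indices, soil characterisation. Values are stored exactly as printed
# (3-4 decimals); summary rows (means, Pearson r with significance stars)
# are kept separately because several of them derive from replicate-level
# data that was never published and cannot be recomputed from the body cells.

.fixture_units <- list(
  pec = c(value = "mg azoxystrobin / kg soil DM"),
  microbial_counts = c(
    organotrophic_bacteria = "log10 CFU / kg soil DM",
    actinomycetes          = "log10 CFU / kg soil DM",
    fungi                  = "log10 CFU / kg soil DM"),
  enzyme_activity = c(
    dehydrogenases       = "umol TPF / kg DM / h",
    catalase             = "mol O2 / kg DM / h",
    urease               = "mmol N-NH4 / kg DM / h",
    acid_phosphatase     = "mmol PNP / kg DM / h",
    alkaline_phosphatase = "mmol PNP / kg DM / h"),
  resistance = c(value = "dimensionless (RS index)"),
  resilience = c(value = "dimensionless (RL index)"),
  soil_metadata = NULL
)

#' Names of the packaged fixtures
#'
#' @return Character vector of valid [load_fixture()] names.
#' @export
fixture_names <- function() {
  c("pec", "microbial_counts", "enzyme_activity", "resistance",
    "resilience", "soil_metadata")
}

#' Load a packaged transcription of the published experiment tables
#'
#' Available fixtures: `"pec"` (predicted environmental concentrations of
#' azoxystrobin, 4 doses x 3 times), `"microbial_counts"` (log10 CFU of
#' organotrophic bacteria, actinomycetes and fungi, 5 doses x 3 times),
#' `"enzyme_activity"` (5 enzymes, 5 doses x 3 times), `"resistance"`
#' (RS index, 5 enzymes, 4 doses x 3 times), `"resilience"` (RL index at
#' day 90, 5 enzymes x 4 doses) and `"soil_metadata"` (soil
#' characterisation, key-value).
#'
#' Except for `soil_metadata`, the returned tibble has columns
#' `dose`, `time`, `variable` (absent for `pec`, whose single variable is
#' the concentration) and `value`, plus attributes:
#' \describe{
#'   \item{`units`}{named character vector of measurement units,}
#'   \item{`summary`}{the printed mean and Pearson-r rows (with their
#'     significance stars at p = 0.01) as a tibble, or `NULL`,}
#'   \item{`note`}{transcription caveats, e.g. the PEC row printed under
#'     the mislabelled dose.}
#' }
#'
#' @param name One of [fixture_names()].
#' @return A tibble; see Details.
#' @examples
#' ea <- load_fixture("enzyme_activity")
#' subset(ea, dose == 0 & time == 30 & variable == "dehydrogenases")
#' attr(load_fixture("pec"), "note")
#' @export
load_fixture <- function(name) {
  if (length(name) != 1L || !name %in% fixture_names()) {
    stop_soilx("catalog_error",
               paste0("unknown fixture \"", paste(name, collapse = ","),
                      "\"; valid names: ",
                      paste(fixture_names(), collapse = ", ")))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "soilecotox",
                      mustWork = TRUE)
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  spath <- system.file("extdata", paste0(name, "_summary.csv"),
                       package = "soilecotox")
  if (nzchar(spath)) {
    attr(out, "summary") <- tibble::as_tibble(read.csv(spath, stringsAsFactors = FALSE))
  }
  attr(out, "units") <- .fixture_units[[name]]
  if (name == "pec") {
    attr(out, "note") <- paste(
      "The source prints the third dose row as 11.50 mg/kg; it is stored",
      "under 11.25 mg/kg, consistent with every other table and with the",
      "printed concentrations (exactly half of the 22.50 mg/kg row).")
  }
  out
}
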