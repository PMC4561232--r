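#' Read a tidy long-format experiment table
#'
#' Reads a CSV of one measurement per row with the columns
#' `dose` (mg a.i. per kg soil dry matter), `time` (days since treatment),
#' `replicate` (identifier), `variable` (e.g. enzyme name or microbial
#' group) and `value`. The file is validated against the experiment-table
#' invariants: doses non-negative, times positive, values finite, and
#' `(dose, time, replicate, variable)` unique. Row order is preserved.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator, one header
#'   row).
#' @param schema Optional named character vector declaring the expected
#'   variables and their units, e.g. `c(urease = "mmol N-NH4 / kg DM / h")`.
#'   When supplied, variables absent from the declaration are rejected and
#'   the units are attached to the result as the `units` attribute.
#' @return A tibble with columns `dose`, `time`, `replicate`, `variable`,
#'   `value` (and a `units` attribute when `schema` was given).
#' @seealso [write_long_table()], [load_fixture()]
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_long_table(
#'   tibble::tibble(dose = 0, time = 30, replicate = "r1",
#'                  variable = "urease", value = 0.175),
#'   path)
#' read_long_table(path)
#' @export
read_long_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop_soilx("io_error", paste0("file does not exist: ", path))
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("dose", "time", "replicate", "variable", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_soilx("schema_error",
               paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw[required])
  for (col in c("dose", "time", "value")) {
    num <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(num) & !is.na(out[[col]]) & nzchar(out[[col]]))
    if (length(bad)) {
      stop_soilx("parse_error",
                 paste0("non-numeric '", col, "' at row ", bad[1],
                        ": \"", out[[col]][bad[1]], "\""))
    }
    out[[col]] <- num
  }
  validate_long_table(out, schema = schema)
}

#' Write a tidy long-format experiment table
#'
#' @param x A data frame as produced by [read_long_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly. Writing then re-reading a valid table is the
#'   identity on the stored decimal representations.
#' @export
write_long_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared invariant checks; also used on in-memory tables.
validate_long_table <- function(x, schema = NULL) {
  if (any(!is.finite(x$value))) {
    stop_soilx("validation_error",
               paste0("non-finite value at row ", which(!is.finite(x$value))[1]))
  }
  if (any(x$dose < 0)) {
    stop_soilx("validation_error",
               paste0("negative dose at row ", which(x$dose < 0)[1]))
  }
  if (any(x$time <= 0)) {
    stop_soilx("validation_error",
               paste0("non-positive time at row ", which(x$time <= 0)[1]))
  }
  key <- paste(x$dose, x$time, x$replicate, x$variable, sep = "\r")
  if (anyDuplicated(key)) {
    stop_soilx("integrity_error",
               paste0("duplicate (dose, time, replicate, variable) key at row ",
                      which(duplicated(key))[1]))
  }
  if (!is.null(schema)) {
    unknown <- setdiff(unique(x$variable), names(schema))
    if (length(unknown)) {
      stop_soilx("schema_error",
                 paste0("variable(s) not declared in schema: ",
                        paste(unknown, collapse = ", ")))
    }
    attr(x, "units") <- schema
  }
  x
}
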