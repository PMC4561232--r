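# Key-value text serialization of synthetic_config objects.
# Format: one `key = value` per line, `#` comments, vectors comma-separated,
# per-variable parameters as dotted keys (e.g. imax.urease = 0.32,
# enzyme_baselines.urease = 0.175,0.165,0.136 aligned with `times`).

#' Write a synthetic experiment configuration to a text file
#'
#' @param config A [synthetic_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_synthetic_config()]
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  num <- function(x) paste(format(x, trim = TRUE, scientific = FALSE), collapse = ",")
  lines <- c(
    "# soilecotox synthetic experiment configuration",
    paste0("doses = ", num(config$doses)),
    paste0("times = ", num(config$times)),
    paste0("n_replicates = ", config$n_replicates),
    paste0("n_replicates_counts = ", config$n_replicates_counts),
    vapply(names(config$enzyme_baselines), function(nm) {
      paste0("enzyme_baselines.", nm, " = ",
             num(config$enzyme_baselines[[nm]][as.character(config$times)]))
    }, character(1)),
    vapply(names(config$imax), function(nm)
      paste0("imax.", nm, " = ", num(config$imax[[nm]])), character(1)),
    vapply(names(config$k50), function(nm)
      paste0("k50.", nm, " = ", num(config$k50[[nm]])), character(1)),
    paste0("sigma = ", num(config$sigma)),
    vapply(names(config$count_baselines), function(nm) {
      paste0("count_baselines.", nm, " = ",
             num(config$count_baselines[[nm]][as.character(config$times)]))
    }, character(1)),
    vapply(names(config$beta), function(nm)
      paste0("beta.", nm, " = ", num(config$beta[[nm]])), character(1)),
    paste0("d_ref = ", num(config$d_ref)),
    paste0("sigma_counts = ", num(config$sigma_counts)),
    paste0("n_colonies = ", num(config$n_colonies)),
    paste0("window = ", num(config$window)),
    paste0("fast = ", num(config$fast)),
    paste0("slow = ", num(config$slow)),
    paste0("w0 = ", num(config$w0)),
    paste0("w_dose_scale = ", num(config$w_dose_scale)),
    paste0("seed = ", config$seed))
  writeLines(lines, path)
  invisible(path)
}

#' Read a synthetic experiment configuration from a text file
#'
#' Parses the key-value format of [write_synthetic_config()] and
#' revalidates through [synthetic_config()], so schema violations are
#' reported with the offending key.
#'
#' @param path Path to a configuration file.
#' @return A [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  if (!file.exists(path)) stop_soilx("io_error", paste0("no such config file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad)) {
    stop_soilx("config_error", paste0("unparseable config line: \"", lines[bad[1]], "\""))
  }
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- lapply(kv, function(m) {
    v <- suppressWarnings(as.numeric(strsplit(m[3], ",")[[1]]))
    if (anyNA(v)) stop_soilx("config_error",
                             paste0("non-numeric value for key \"", m[2], "\""))
    v
  })
  names(vals) <- keys
  scalar_keys <- c("n_replicates", "n_replicates_counts", "sigma", "d_ref",
                   "sigma_counts", "n_colonies", "window", "w0",
                   "w_dose_scale", "seed")
  args <- list()
  for (k in c("doses", "times", "fast", "slow", scalar_keys)) {
    if (k %in% keys) args[[k]] <- vals[[k]]
  }
  grab <- function(prefix) {
    sel <- keys[startsWith(keys, paste0(prefix, "."))]
    if (!length(sel)) return(NULL)
    setNames(lapply(sel, function(k) vals[[k]]), sub("^[^.]+\\.", "", sel))
  }
  times_chr <- as.character(args$times %||% c(30, 60, 90))
  eb <- grab("enzyme_baselines")
  if (!is.null(eb)) args$enzyme_baselines <- lapply(eb, function(v) setNames(v, times_chr))
  cb <- grab("count_baselines")
  if (!is.null(cb)) args$count_baselines <- lapply(cb, function(v) setNames(v, times_chr))
  for (nm in c("imax", "k50", "beta")) {
    g <- grab(nm)
    if (!is.null(g)) args[[nm]] <- unlist(g)
  }
  unknown <- setdiff(keys, c("doses", "times", "fast", "slow", scalar_keys,
                             keys[grepl("^(enzyme_baselines|count_baselines|imax|k50|beta)\\.", keys)]))
  if (length(unknown)) {
    stop_soilx("config_error", paste0("unknown config key(s): ",
                                      paste(unknown, collapse = ", ")))
  }
  do.call(synthetic_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
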