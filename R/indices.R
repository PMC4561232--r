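# Biological indices: colony development (CD) and ecophysiological (EP)
# biodiversity indices of culturable microorganisms, and the Orwin-Wardle
# resistance (RS) and resilience (RL) indices of soil parameters.

#' Colony development index (CD)
#'
#' Weighted sum of the daily colony-emergence fractions,
#' `CD = 100 * sum(p_d / d)` over observation days `d = 1..window`, where
#' `p_d` is the fraction of all colonies that first appeared on day `d`.
#' High values (toward 100) indicate dominance of fast-appearing
#' r-strategists, low values (toward `100/window`) of slow K-strategists.
#' The index is computed on proportions, so it is invariant to the total
#' number of colonies counted.
#'
#' @param counts Non-negative vector of new-colony counts per observation
#'   day; length must equal `window`.
#' @param window Length of the observation window in days (default 10, the
#'   conventional protocol).
#' @return CD, a number in `[100/window, 100]`.
#' @examples
#' colony_development_index(c(100, rep(0, 9)))  # all day 1 -> 100
#' colony_development_index(rep(10, 10))        # uniform -> 10 * sum(1/d)
#' @export
colony_development_index <- function(counts, window = 10) {
  p <- emergence_proportions(counts, window)
  100 * sum(p / seq_len(window))
}

#' Ecophysiological diversity index (EP)
#'
#' Shannon-type evenness of the daily colony-emergence fractions,
#' `EP = -sum(p_d * log(p_d, base))`, with zero-count days contributing 0.
#' With `base = 10` and a 10-day window, EP lies in `[0, 1]`: 0 when all
#' colonies appear on a single day, 1 when emergence is uniform over the
#' window. A drop in EP signals loss of ecophysiological diversity, e.g.
#' elimination of stressor-susceptible groups.
#'
#' @inheritParams colony_development_index
#' @param base Logarithm base; 10 by convention so the uniform 10-day
#'   profile scores exactly 1.
#' @return EP, in `[0, log(window, base)]`.
#' @examples
#' ecophysiological_index(c(0, 0, 40, rep(0, 7)))  # 0
#' ecophysiological_index(rep(10, 10))             # 1
#' @export
ecophysiological_index <- function(counts, window = 10, base = 10) {
  p <- emergence_proportions(counts, window)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

emergence_proportions <- function(counts, window) {
  if (length(counts) != window) {
    stop_soilx("validation_error",
               paste0("emergence profile must have exactly ", window,
                      " daily counts, got ", length(counts)))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_soilx("validation_error", "daily counts must be finite and non-negative")
  }
  total <- sum(counts)
  if (total <= 0) {
    stop_soilx("undefined_index",
               "all-zero emergence profile: index undefined (no colonies)")
  }
  counts / total
}

#' Soil resistance index (RS)
#'
#' Orwin-Wardle resistance of a soil parameter to a disturbance:
#' `RS = 1 - 2|D0| / (C0 + |D0|)` with `D0 = C0 - P0`, where `C0` is the
#' parameter value in undisturbed (control) soil and `P0` in disturbed
#' soil, both at the same time. RS is 1 when the disturbance had no effect,
#' 0 when the parameter was fully suppressed (`P0 = 0`), and tends to -1 as
#' the disturbed value diverges; it is symmetric in the sign of the change.
#'
#' @param c0 Control parameter value (> 0).
#' @param p0 Disturbed parameter value at the same time.
#' @return RS, in `(-1, 1]`. Vectorized over `c0`/`p0`.
#' @examples
#' resistance_index(5, 5)     # 1: unchanged
#' resistance_index(5, 0)     # 0: complete suppression
#' resistance_index(5.310, 5.087)
#' @export
resistance_index <- function(c0, p0) {
  if (any(!is.finite(c0)) || any(c0 <= 0)) {
    stop_soilx("domain_error", "control value C0 must be finite and > 0")
  }
  d0 <- abs(c0 - p0)
  1 - 2 * d0 / (c0 + d0)
}

#' Soil resilience index (RL)
#'
#' Orwin-Wardle resilience, the degree to which a disturbed parameter has
#' returned toward the control by a follow-up time:
#' `RL = 2|D0| / (|D0| + |Dx|) - 1`, where `D0 = C0 - P0` is the
#' control-disturbed difference at the baseline time and `Dx = Cx - Px` at
#' the follow-up time. RL is 1 on full recovery (`Dx = 0`), 0 when the
#' disturbance is unchanged in magnitude, and negative when it grew.
#'
#' Degenerate cases: with no disturbance at either time (`D0 = Dx = 0`)
#' the index is undefined and returned as `NA` with a warning; with
#' `D0 = 0` but `Dx != 0` (a disturbance that only emerged later) the
#' formula's limit -1 is returned, also with a warning.
#'
#' @param c0,p0 Control and disturbed values at the baseline time.
#' @param cx,px Control and disturbed values at the follow-up time.
#' @return RL, in `[-1, 1]` (or `NA` where undefined). Vectorized.
#' @examples
#' resilience_index(5, 4, 5, 5)    # 1: full recovery
#' resilience_index(5, 4, 5, 2)    # -0.5: disturbance tripled
#' @export
resilience_index <- function(c0, p0, cx, px) {
  d0 <- abs(c0 - p0)
  dx <- abs(cx - px)
  out <- 2 * d0 / (d0 + dx) - 1
  none <- d0 == 0 & dx == 0
  late <- d0 == 0 & dx > 0
  if (any(none)) {
    warn("RL undefined where no disturbance at either time; returning NA",
         class = "soilecotox_undefined_resilience")
    out[none] <- NA_real_
  }
  if (any(late)) {
    warn("D0 = 0 but Dx != 0: disturbance emerged after baseline; RL = -1",
         class = "soilecotox_late_disturbance")
  }
  out
}

#' Signed treatment effect relative to the control
#'
#' Looks up the treated and control (dose 0) mean values of a variable at a
#' given time and reports the signed difference, in the variable's unit
#' (log10 CFU for counts, activity units for enzymes).
#'
#' @param table Long means table with columns `dose`, `time`, `variable`,
#'   `value`, e.g. `load_fixture("microbial_counts")`.
#' @param variable Variable name to look up.
#' @param dose Treatment dose (mg/kg).
#' @param time Sampling time (days).
#' @return A one-row tibble with `control`, `treated`,
#'   `delta` (= treated - control) and `direction`
#'   (`"increase"`, `"reduction"` or `"none"`).
#' @examples
#' effect_delta(load_fixture("microbial_counts"), "fungi", 22.50, 90)
#' @export
effect_delta <- function(table, variable, dose, time) {
  sel <- function(d) {
    v <- table$value[table$variable == variable & table$dose == d &
                       table$time == time]
    if (length(v) != 1L) {
      stop_soilx("lookup_error",
                 paste0("expected exactly one value for (", variable, ", dose ",
                        d, ", day ", time, "), found ", length(v)))
    }
    v
  }
  control <- sel(0)
  treated <- sel(dose)
  delta <- treated - control
  tibble::tibble(
    variable = variable, dose = dose, time = time,
    control = control, treated = treated, delta = delta,
    direction = if (delta > 0) "increase" else if (delta < 0) "reduction" else "none")
}

#' Group summaries and ranking of index values
#'
#' Arithmetic means, extremes and a descending ranking of index values
#' (RS, RL, CD, EP, ...) per group, as used for statements like
#' "dehydrogenases (0.874) > alkaline phosphatase (0.810) > ...".
#'
#' @param data Tibble containing a `value` column.
#' @param by Character vector of grouping column names.
#' @return A tibble with one row per group: the grouping columns, `n`,
#'   `mean`, `min`, `max` and `rank` (1 = largest mean; ties broken by
#'   group label order). Rows are ordered by rank. The global extremes over
#'   all values are attached as attributes `global_min`/`global_max`.
#'   Groups that exist as factor levels but contain no observations are
#'   reported with `NA`, never 0.
#' @examples
#' rs <- load_fixture("resistance")
#' summarize_index(rs, by = "variable")
#' @export
summarize_index <- function(data, by) {
  if (nrow(data) == 0) stop_soilx("validation_error", "empty index collection")
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .drop = FALSE) |>
    dplyr::summarize(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      .groups = "drop")
  # empty groups: mean() over nothing is NaN, min/max +-Inf -> report NA
  out$mean[out$n == 0] <- NA_real_
  out$min[!is.finite(out$min)] <- NA_real_
  out$max[!is.finite(out$max)] <- NA_real_
  label <- do.call(paste, c(out[by], sep = " / "))
  ord <- order(-replace(out$mean, is.na(out$mean), -Inf), label)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  attr(out, "global_min") <- suppressWarnings(min(data$value, na.rm = TRUE))
  attr(out, "global_max") <- suppressWarnings(max(data$value, na.rm = TRUE))
  out
}
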