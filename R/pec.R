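# Predicted environmental concentration (PEC) model. The printed PEC grid
# is consistent with dose-proportional, shared first-order decay:
#   PEC(dose, t) = f * dose * exp(-k * t)
# with the initial-fraction f and rate k common to all doses. On the log
# scale this is a straight line in t with offset log(dose), so the fit is
# an ordinary least-squares regression of log(PEC) - log(dose) on t.

#' Fit the shared first-order PEC dissipation model
#'
#' Least-squares fit of `log(PEC) = log(f * dose) - k * t` with `f`
#' (dimensionless initial concentration fraction) and `k` (first-order
#' rate, 1/day) shared across doses. The half-life follows as
#' `DT50 = log(2) / k`.
#'
#' @param table Tibble with columns `dose` (mg/kg), `time` (days) and
#'   `value` (concentration, mg/kg); e.g. `load_fixture("pec")`. Rows with
#'   `dose == 0` are ignored (the model predicts 0 there exactly).
#' @param weights Optional observation weights on the log scale.
#' @return An object of class `"pec_fit"`: a list with elements `f`, `k`,
#'   `dt50`, `rmse_log` (root-mean-square log residual), `residuals_log`,
#'   `n` and the fitted `lm` object (`fit`).
#' @examples
#' fit <- fit_pec(load_fixture("pec"))
#' fit$dt50
#' @export
fit_pec <- function(table, weights = NULL) {
  d <- table[table$dose > 0, , drop = FALSE]
  if (nrow(d) == 0) stop_soilx("domain_error", "need at least one non-zero dose")
  if (any(d$value <= 0)) {
    stop_soilx("domain_error", "all concentrations must be > 0 to fit on the log scale")
  }
  if (length(unique(d$time)) < 2) {
    stop_soilx("underdetermined_error",
               "need at least 2 distinct times to identify the decay rate")
  }
  y <- log(d$value) - log(d$dose)
  fit <- if (is.null(weights)) lm(y ~ d$time) else lm(y ~ d$time, weights = weights)
  k <- -unname(coef(fit)[2])
  f <- exp(unname(coef(fit)[1]))
  if (k <= 0) warn("fitted rate k <= 0: concentrations do not decay",
                   class = "soilecotox_nondecaying")
  res <- unname(stats::residuals(fit))
  structure(list(f = f, k = k, dt50 = log(2) / k,
                 rmse_log = sqrt(mean(res^2)), residuals_log = res,
                 n = nrow(d), fit = fit),
            class = "pec_fit")
}

#' @export
print.pec_fit <- function(x, ...) {
  cat("Shared first-order PEC model: PEC(dose, t) = f * dose * exp(-k t)\n")
  cat(sprintf("  f    = %.6g (initial fraction)\n", x$f))
  cat(sprintf("  k    = %.6g / day\n", x$k))
  cat(sprintf("  DT50 = %.4g days\n", x$dt50))
  cat(sprintf("  RMSE(log residuals) = %.4g on n = %d cells\n", x$rmse_log, x$n))
  invisible(x)
}

#' Predict PEC from fitted decay parameters
#'
#' @param params A `"pec_fit"` object, or a list with elements `f` and `k`.
#' @param dose Dose(s), mg/kg (>= 0; dose 0 predicts 0).
#' @param time Time(s) since application, days (>= 0).
#' @return Predicted concentration(s), mg/kg; linear in dose, log-linear in
#'   time, with `predict_pec(p, d, t + p$dt50) == predict_pec(p, d, t) / 2`.
#' @examples
#' fit <- fit_pec(load_fixture("pec"))
#' predict_pec(fit, 22.50, 30)
#' @export
predict_pec <- function(params, dose, time) {
  if (any(dose < 0) || any(time < 0)) {
    stop_soilx("domain_error", "dose and time must be non-negative")
  }
  params$f * dose * exp(-params$k * time)
}

#' Internal-consistency checks of a printed PEC grid
#'
#' Two properties of the shared dose-proportional first-order model are
#' checked against a concentration grid: (i) dose-linearity, i.e.
#' `value / dose` is constant within each time column; (ii) shared decay,
#' i.e. each consecutive-time ratio `value(t2) / value(t1)` within a dose
#' row matches the fitted `exp(-k (t2 - t1))`.
#'
#' The checks are precision-aware: a printed cell only carries its
#' quantization step `ulp` (e.g. 1e-4 for 4-decimal tables) — and these
#' tables demonstrably truncate rather than round some cells, so the
#' printed-value error can reach a full ulp. For small concentrations the
#' induced relative uncertainty exceeds any tight tolerance, making the
#' check at that tolerance meaningless. Each comparison is therefore
#' tested against `max(tol, full-ulp propagated bound)`; the `bound_type`
#' column records which one applied. The dose-linearity reference per time
#' column is the median of `value / dose`, robust against
#' quantization-limited cells.
#'
#' @param table PEC grid (`dose`, `time`, `value`).
#' @param tol Relative tolerance for cells whose printed precision supports
#'   it (default 0.005, i.e. 0.5%).
#' @param ulp Quantization step of the printed values (default `1e-4`,
#'   4 decimals).
#' @return Tibble of individual checks with columns `check`
#'   (`"dose_linearity"` or `"decay_ratio"`), `dose`, `time`, `observed`,
#'   `expected`, `rel_dev`, `bound`, `bound_type` (`"tolerance"` or
#'   `"quantization"`) and `pass`.
#' @examples
#' chk <- pec_consistency(load_fixture("pec"))
#' all(chk$pass)
#' @export
pec_consistency <- function(table, tol = 0.005, ulp = 1e-4) {
  d <- table[table$dose > 0, , drop = FALSE]
  fit <- fit_pec(d)
  rows <- list()
  # (i) dose-linearity: value/dose vs the per-time-column median of value/dose
  for (t in sort(unique(d$time))) {
    sl <- d[d$time == t, ]
    norm <- sl$value / sl$dose
    expd <- stats::median(norm)
    for (i in seq_len(nrow(sl))) {
      quant <- ulp / sl$value[i]  # full-ulp relative uncertainty (truncation)
      bound <- max(tol, quant)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        check = "dose_linearity", dose = sl$dose[i], time = t,
        observed = norm[i], expected = expd,
        rel_dev = abs(norm[i] / expd - 1),
        bound = bound,
        bound_type = if (quant > tol) "quantization" else "tolerance",
        pass = abs(norm[i] / expd - 1) <= bound)
    }
  }
  # (ii) shared decay: consecutive-time ratios within each dose row
  times <- sort(unique(d$time))
  for (dose in sort(unique(d$dose))) {
    for (j in seq_len(length(times) - 1L)) {
      v1 <- d$value[d$dose == dose & d$time == times[j]]
      v2 <- d$value[d$dose == dose & d$time == times[j + 1L]]
      obs <- v2 / v1
      expd <- exp(-fit$k * (times[j + 1L] - times[j]))
      quant <- ulp * (1 / v1 + 1 / v2)
      bound <- max(tol, quant)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        check = "decay_ratio", dose = dose, time = times[j + 1L],
        observed = obs, expected = expd, rel_dev = abs(obs / expd - 1),
        bound = bound,
        bound_type = if (quant > tol) "quantization" else "tolerance",
        pass = abs(obs / expd - 1) <= bound)
    }
  }
  dplyr::bind_rows(rows)
}
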