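#' Estimate the exponential-phase growth rate of an OD600 curve
#'
#' The slope of log2(OD) against time during exponential growth is the growth
#' rate in doublings per hour. Plate-reader curves saturate, so a naive
#' log-linear fit over an arbitrary stretch underestimates the rate; this
#' estimator therefore proceeds in three steps:
#'
#' 1. if the whole positive-OD curve is log-linear (pure exponential, or
#'    perfectly flat), return that exact slope;
#' 2. otherwise fit a three-parameter logistic
#'    `OD(t) = Asym / (1 + exp((xmid - t)/scal))` by Levenberg–Marquardt least
#'    squares and report its exponential-phase rate `1 / (scal * log(2))`;
#' 3. if the logistic fit does not converge, fall back to the slope of the
#'    contiguous log-linear window (>= `min_points` readings) with the
#'    highest R-squared.
#'
#' @param curve Data frame with columns `time_hr` (strictly increasing) and
#'   `od` (non-negative OD600 readings).
#' @param min_points Minimum number of readings (and minimum window width for
#'   the fallback scan); default 6.
#'
#' @return A `growth_fit` object: list with `rate` (doublings/hr), `window`
#'   (indices of the readings that informed the rate), `r_squared` (of the
#'   fit on its window), `n_points` and `method` (`"loglinear"`,
#'   `"logistic"`, or `"window"`). Supports [tidy()] and [glance()].
#' @export
#' @examples
#' curve <- data.frame(time_hr = seq(0, 8, 0.5), od = 0.1 * 2^(0.5 * seq(0, 8, 0.5)))
#' growth_rate(curve)$rate
growth_rate <- function(curve, min_points = 6) {
  if (!all(c("time_hr", "od") %in% names(curve))) {
    abort("`curve` must have columns `time_hr` and `od`.")
  }
  t <- curve$time_hr
  od <- curve$od
  if (any(diff(t) <= 0)) abort("time points must be strictly increasing.")
  if (any(od < 0)) abort("OD readings must be >= 0.")
  n <- length(t)
  if (n < min_points) abort(sprintf("need at least %d points for rate fitting.", min_points))

  # 1. whole curve already log-linear (exact exponential or flat)?
  if (all(od > 0)) {
    full <- loglinear_fit(t, od, seq_len(n))
    if (full$max_abs_resid < 1e-8) {
      return(structure(list(rate = full$slope, window = seq_len(n),
                            r_squared = if (full$syy == 0) 1 else full$r2,
                            n_points = n, method = "loglinear"),
                       class = "growth_fit"))
    }
  }

  # 2. logistic fit
  lg <- fit_logistic_rate(t, od)
  if (!is.null(lg)) {
    return(structure(lg, class = "growth_fit"))
  }

  # 3. best-R2 contiguous window fallback
  best <- NULL
  for (start in seq_len(n - min_points + 1L)) {
    for (end in seq(start + min_points - 1L, n)) {
      idx <- start:end
      if (any(od[idx] <= 0)) next
      f <- loglinear_fit(t, od, idx)
      if (is.null(best) || f$r2 > best$r_squared + 1e-12) {
        best <- list(rate = f$slope, window = idx, r_squared = f$r2,
                     n_points = length(idx), method = "window")
      }
    }
  }
  if (is.null(best)) {
    abort("no candidate window with positive OD readings; cannot fit a rate.")
  }
  structure(best, class = "growth_fit")
}

loglinear_fit <- function(t, od, idx) {
  x <- t[idx]
  y <- log2(od[idx])
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  resid <- y - mean(y) - slope * (x - mean(x))
  list(slope = slope, syy = syy,
       r2 = if (syy == 0) 0 else sxy^2 / (sxx * syy),
       max_abs_resid = max(abs(resid)))
}

fit_logistic_rate <- function(t, od) {
  start <- list(Asym = max(od) * 1.05,
                xmid = t[which.min(abs(od - max(od) / 2))],
                scal = (max(t) - min(t)) / 8)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    od ~ Asym / (1 + exp((xmid - time_hr) / scal)),
    data = data.frame(time_hr = t, od = od),
    start = start, lower = c(1e-6, -1e3, 1e-4),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- coef(fit)
  resid <- od - predict(fit)
  sst <- sum((od - mean(od))^2)
  window <- which(t <= cf[["xmid"]]) # rising (exponential) phase
  if (length(window) == 0) window <- seq_along(t)
  list(rate = 1 / (cf[["scal"]] * log(2)),
       window = window,
       r_squared = if (sst == 0) 1 else 1 - sum(resid^2) / sst,
       n_points = length(t), method = "logistic")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> rate %.4f doublings/hr (window %d-%d, R2 %.3f)\n",
              x$rate, min(x$window), max(x$window), x$r_squared))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = "rate", estimate = x$rate)
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(rate = x$rate, r_squared = x$r_squared, n_points = x$n_points,
         window_start = min(x$window), window_end = max(x$window))
}

#' Percent growth-rate inhibition of a treated culture
#'
#' `100 * (1 - rate_treated / rate_control)`: 0% for equal rates, 100% for a
#' completely arrested culture.
#'
#' @param treated,control Growth rates (doublings/hr), both >= 0; `control`
#'   must be positive. `growth_fit` objects are accepted.
#' @return Percent inhibition (can be negative if the treated culture grew
#'   faster).
#' @export
percent_inhibition <- function(treated, control) {
  if (inherits(treated, "growth_fit")) treated <- treated$rate
  if (inherits(control, "growth_fit")) control <- control$rate
  if (treated < 0 || control < 0) abort("rates must be >= 0.")
  if (control == 0) abort("control rate is 0; inhibition undefined.")
  100 * (1 - treated / control)
}

#' Fit rates for a dose ladder and select doses in an inhibition band
#'
#' Screens are run at sub-lethal doses so that both healthy and mildly
#' impaired mutants stay measurable; the conventional target is a 10–20%
#' reduction in wild-type growth rate. This helper fits a rate per dose,
#' computes percent inhibition relative to the zero-dose control, and flags
#' the doses whose inhibition falls inside the band.
#'
#' @param curves Long tibble from [simulate_growth_curves()] or equivalent:
#'   columns `dose`, `time_hr`, `od`. The control is the dose labelled `"0"`
#'   (or the numerically smallest dose if no zero is present, with a warning).
#' @param band Numeric `c(low, high)` percent-inhibition band, default
#'   `c(10, 20)`.
#' @param min_points Passed to [growth_rate()].
#'
#' @return A tibble with one row per dose: `dose`, `rate`, `r_squared`,
#'   `inhibition_pct`, `selected`. An empty selection is valid and triggers a
#'   warning, not an error.
#' @export
select_dose <- function(curves, band = c(10, 20), min_points = 6) {
  if (length(band) != 2 || band[1] >= band[2]) {
    abort("`band` must be c(low, high) with low < high.")
  }
  doses <- unique(curves$dose)
  fits <- map(doses, function(d) growth_rate(curves[curves$dose == d, ], min_points))
  rates <- map_dbl(fits, "rate")
  ctrl_idx <- which(doses == "0" | suppressWarnings(as.numeric(doses)) == 0)
  if (length(ctrl_idx) == 0) {
    warn("no zero-dose control found; using the smallest dose as control.")
    ctrl_idx <- order(suppressWarnings(as.numeric(doses)))[1]
  }
  ctrl_rate <- rates[ctrl_idx[1]]
  out <- tibble(
    dose = doses,
    rate = rates,
    r_squared = map_dbl(fits, "r_squared"),
    inhibition_pct = map_dbl(rates, percent_inhibition, control = ctrl_rate),
    selected = FALSE
  )
  out$selected <- out$inhibition_pct >= band[1] & out$inhibition_pct <= band[2]
  out <- arrange(out, suppressWarnings(as.numeric(.data$dose)))
  if (!any(out$selected)) {
    warn("no dose falls inside the requested inhibition band.")
  }
  out
}
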