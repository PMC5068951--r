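#' Simulate OD600 microculture growth curves across doses
#'
#' Generates logistic growth curves sampled every 30 minutes for 16 hours, the
#' standard plate-reader setup for dose-finding before a pooled screen. The
#' exponential-phase rate at each dose is `control_rate * (1 - inhibition)`,
#' so a 0.15 inhibition yields 85% of the control doubling rate; inhibition 1
#' leaves the culture flat at the inoculum density. Gaussian measurement noise
#' is added to each OD reading.
#'
#' @param inhibitions Named numeric vector mapping dose label to fractional
#'   growth-rate inhibition in [0, 1] (include a 0 entry for the control).
#' @param control_rate Uninhibited exponential-phase rate, doublings/hr.
#' @param od0 Inoculum OD600.
#' @param carrying_capacity Stationary-phase OD600 plateau.
#' @param noise_sd Standard deviation of additive Gaussian OD noise (>= 0).
#' @param interval_hr,duration_hr Sampling interval and total duration.
#' @param seed Integer seed for the noise.
#'
#' @return A tibble with columns `dose`, `time_hr`, `od` (long format, ready
#'   for [growth_rate()] per dose).
#' @export
simulate_growth_curves <- function(inhibitions, control_rate = 0.5,
                                   od0 = 0.1, carrying_capacity = 1.5,
                                   noise_sd = 0, interval_hr = 0.5,
                                   duration_hr = 16, seed = 1) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (any(inhibitions < 0 | inhibitions > 1)) {
    abort("inhibitions must lie in [0, 1].")
  }
  if (is.null(names(inhibitions))) names(inhibitions) <- as.character(inhibitions)
  t <- seq(0, duration_hr, by = interval_hr)
  curves <- imap(inhibitions, function(inh, dose) {
    r <- control_rate * (1 - inh) # doublings/hr
    od <- if (r <= 0) {
      rep(od0, length(t))
    } else {
      # logistic growth, exponential-phase doubling rate r
      carrying_capacity /
        (1 + ((carrying_capacity - od0) / od0) * 2^(-r * t))
    }
    tibble(dose = dose, time_hr = t, od = od)
  })
  out <- bind_rows(curves)
  if (noise_sd > 0) {
    out$od <- out$od + with_seed(seed, rnorm(nrow(out), 0, noise_sd))
    out$od <- pmax(out$od, 0)
  }
  out
}
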