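#' Phase factors of the pump rate model
#'
#' The three building blocks of the composite production-rate model.
#' Each factor is dimensionless except the startup sigmoid, which carries
#' the rate scale `s_f`:
#'
#' * `startup_factor()`: `s_f * exp(s_t (t - t_i)) / (1 + exp(s_t (t - t_i)))`
#'   — strictly increasing in `t`, range `(0, s_f)`. Lumps rehydration of
#'   the dried yeast, lag-phase adaptation and CO2 saturation of the medium
#'   into one sigmoid.
#' * `stable_factor()`: `1 + 1/(1 + exp((t - t_s)/t_ds))` — strictly
#'   decreasing, range `(1, 2)`, value 1.5 at `t = t_s`. Models the diauxic
#'   dip as the culture switches from glucose to fructose.
#' * `decline_factor()`: `max(0, e - exp(t/t_e))` — strictly decreasing on
#'   `[0, t_e)`, exactly 0 for `t >= t_e`. Models exponential depletion of
#'   the final carbon source.
#'
#' All three accept any real `t` (they are mathematically defined for
#' `t < 0`); the rate and volume evaluators ([pump_rate()],
#' [cumulative_volume()]) restrict time to `t >= 0`, where model time
#' starts at inoculation. Logistic terms are computed through
#' [stats::plogis()], so large arguments (e.g. `s_t * (t - t_i)` of order
#' 60 at late times) do not overflow.
#'
#' @param t time(s) since inoculation (min); vectorised.
#' @param params a [four_params()] (or [six_params()]) object.
#' @param t_s diauxic shift onset (min).
#' @param t_ds diauxic steepness scale (min), `> 0`.
#' @param t_e exhaustion time (min), `> 0`.
#' @return Numeric vector the length of `t`.
#' @examples
#' p <- four_params(0.007291, 0.026052, 159.6, 1599.6, rate_unit = "mL/min")
#' startup_factor(p$t_i, p)       # s_f / 2 at the sigmoid midpoint
#' stable_factor(500, 500, 40)    # 1.5 at t = t_s
#' decline_factor(0, 1599.6)      # e - 1
#' @export
startup_factor <- function(t, params) {
  stopifnot(inherits(params, "four_params"))
  params$s_f * plogis(params$s_t * (t - params$t_i))
}

#' @rdname startup_factor
#' @export
stable_factor <- function(t, t_s, t_ds) {
  if (!is.numeric(t_ds) || length(t_ds) != 1L || !is.finite(t_ds) || t_ds <= 0) {
    abort_fermpump("t_ds must be a positive finite scalar", "fermpump_param_error")
  }
  # 1/(1+exp(x)) == plogis(-x), stable for large |x|
  1 + plogis(-(t - t_s) / t_ds)
}

#' @rdname startup_factor
#' @export
decline_factor <- function(t, t_e) {
  if (!is.numeric(t_e) || length(t_e) != 1L || !is.finite(t_e) || t_e <= 0) {
    abort_fermpump("t_e must be a positive finite scalar", "fermpump_param_error")
  }
  out <- numeric(length(t))
  live <- t < t_e            # exp(t/t_e) < e there; no overflow possible
  out[live] <- exp(1) - exp(t[live] / t_e)
  pmax(0, out)
}

check_model_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort_fermpump("t must be finite numeric", "fermpump_input_error")
  }
  if (any(t < 0)) {
    abort_fermpump("t must be >= 0 (model time starts at inoculation)",
                   "fermpump_input_error")
  }
  t
}

#' Evaluate the composite pump production rate
#'
#' For `four_params` the rate is the startup sigmoid times the decline
#' clamp; for `six_params` the diauxic stable-phase factor multiplies in as
#' well. The rate is identically zero for `t >= t_e` and is returned in the
#' parameter set's `rate_unit`.
#'
#' @param params a [four_params()] or [six_params()] object.
#' @param t times since inoculation (min), `>= 0`; vectorised.
#' @return Rate values, same length as `t`, in `params$rate_unit`.
#' @examples
#' p <- four_params(0.007291, 0.026052, 159.6, 1599.6, rate_unit = "mL/min")
#' pump_rate(p, peak_time(p)) * 1000  # peak rate in uL/min
#' @export
pump_rate <- function(params, t) UseMethod("pump_rate")

#' @export
pump_rate.four_params <- function(params, t) {
  validate_params(params)
  check_model_time(t)
  startup_factor(t, params) * decline_factor(t, params$t_e)
}

#' @export
pump_rate.six_params <- function(params, t) {
  validate_params(params)
  check_model_time(t)
  startup_factor(t, params) *
    stable_factor(t, params$t_s, params$t_ds) *
    decline_factor(t, params$t_e)
}

#' Cumulative pumped CO2 volume
#'
#' Integrates the model rate from inoculation: `V(t) = integral of Q from 0
#' to t`, by composite trapezoid quadrature on a fixed grid (default step
#' 0.5 min) clipped to `[0, t_e]`; the integrand is smooth and bounded so
#' the quadrature error is far below measurement noise. `V` is
#' non-decreasing and constant for `t >= t_e`. The unit is
#' `params$rate_unit` times minutes (uL if the rate is uL/min).
#'
#' @inheritParams pump_rate
#' @param grid_dt quadrature step (min).
#' @return Cumulative volumes, same length as `t`.
#' @export
cumulative_volume <- function(params, t, grid_dt = 0.5) {
  stopifnot(inherits(params, "four_params"))
  validate_params(params)
  check_model_time(t)
  stopifnot(is.numeric(grid_dt), length(grid_dt) == 1L, grid_dt > 0)
  t_clip <- pmin(t, params$t_e)
  # one shared grid: regular steps plus every (clipped) query point
  grid <- sort(unique(c(seq(0, params$t_e, by = grid_dt), params$t_e, t_clip)))
  grid <- grid[grid <= params$t_e]
  v <- pracma::cumtrapz(grid, pump_rate(params, grid))[, 1]
  v[match(t_clip, grid)]
}

#' Closed-form peak analytics
#'
#' Setting the derivative of the four-parameter rate model to zero and
#' simplifying (the startup sigmoid saturates well before exhaustion)
#' yields a closed-form time of maximum performance,
#' \deqn{t_{max} = t_i + \frac{1}{s_t}\ln(s_t t_e - 1),}
#' and the peak pump rate is the model evaluated there,
#' `Q_max = Q(t_max)`. The closed form is an approximation to the true
#' argmax (see [numeric_peak()]); because it evaluates the rate curve at an
#' approximate argmax, `peak_rate()` never exceeds the true maximum.
#'
#' Requires `s_t * t_e > 1`; otherwise the logarithm is undefined and an
#' error of class `fermpump_peak_undefined` is thrown (fall back to
#' [numeric_peak()]).
#'
#' @param params a [four_params()] object (extra diauxic fields of a
#'   `six_params` object are ignored by the closed form).
#' @return `peak_time()`: minutes; `peak_rate()`: rate in
#'   `params$rate_unit`.
#' @examples
#' p <- four_params(0.007291, 0.026052, 159.6, 1599.6, rate_unit = "mL/min")
#' peak_time(p)         # ~301.84 min
#' peak_rate(convert_rate_unit(p, "uL/min"))  # ~10.75 uL/min
#' @export
peak_time <- function(params) {
  stopifnot(inherits(params, "four_params"))
  validate_params(params)
  arg <- params$s_t * params$t_e - 1
  if (arg <= 0) {
    abort_fermpump(
      sprintf("analytic peak undefined: s_t * t_e = %.4g <= 1; use numeric_peak()",
              params$s_t * params$t_e),
      "fermpump_peak_undefined"
    )
  }
  params$t_i + log(arg) / params$s_t
}

#' @rdname peak_time
#' @export
peak_rate <- function(params) {
  t_max <- peak_time(params)
  # four-parameter closed form: evaluate without the diauxic factor
  p4 <- structure(params[c("s_f", "s_t", "t_i", "t_e", "rate_unit")],
                  class = "four_params")
  pump_rate(p4, max(t_max, 0))
}

#' Numeric peak of the rate curve
#'
#' Deterministic grid-then-refine search for the argmax of the model rate
#' on `[0, t_e]`: a 1-min scan brackets the maximum, then golden-section
#' refinement locates it to 0.01-min resolution. Works for both model
#' orders and serves as a check on the closed-form [peak_time()]
#' approximation.
#'
#' @inheritParams pump_rate
#' @return A list of class `peak_estimate` with fields `t_max` (min) and
#'   `q_max` (rate in `params$rate_unit`).
#' @export
numeric_peak <- function(params) {
  stopifnot(inherits(params, "four_params"))
  validate_params(params)
  grid <- seq(0, params$t_e, by = min(1, params$t_e / 100))
  q <- pump_rate(params, grid)
  i <- which.max(q)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(function(t) pump_rate(params, t),
                  lower = lo, upper = hi, maximum = TRUE, tol = 1e-3)
  structure(list(t_max = opt$maximum, q_max = opt$objective,
                 rate_unit = params$rate_unit),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("<peak estimate> t_max = %.2f min, Q_max = %.4g %s\n",
              x$t_max, x$q_max, x$rate_unit))
  invisible(x)
}
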