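RATE_UNITS <- c("uL/min", "mL/min")

match_rate_unit <- function(rate_unit) {
  if (missing(rate_unit) || is.null(rate_unit)) {
    abort_fermpump(
      "`rate_unit` must be given explicitly (\"uL/min\" or \"mL/min\"); fitted s_f values from the parameter chart are on a mL/min scale",
      "fermpump_unit_error"
    )
  }
  rate_unit <- as.character(rate_unit)
  if (length(rate_unit) != 1L || !rate_unit %in% RATE_UNITS) {
    abort_fermpump(
      sprintf("unknown rate unit %s; use one of: %s",
              deparse(rate_unit), paste(RATE_UNITS, collapse = ", ")),
      "fermpump_unit_error"
    )
  }
  rate_unit
}

#' Four-parameter pump model state
#'
#' The simplified production-rate model of the yeast pump is the product of
#' a startup sigmoid and an exponential decline clamp,
#' \deqn{Q(t) = s_f \frac{e^{s_t (t - t_i)}}{1 + e^{s_t (t - t_i)}}
#'       \max\!\big(0,\; e - e^{t/t_e}\big),}
#' parameterised by a rate scale `s_f`, a startup steepness `s_t` (1/min),
#' a startup latency `t_i` (min) and an exhaustion time `t_e` (min) at which
#' the rate reaches zero (equal to the pump runtime).
#'
#' `s_f` carries the rate unit of the trace the parameters describe. Fitted
#' values read from the published parameter chart (e.g. `s_f = 0.007291`)
#' are on a mL/min scale; the peak pump rates quoted alongside them are in
#' uL/min. The unit tag is therefore mandatory and conversions multiply by
#' exactly 1000 (see [convert_rate_unit()]).
#'
#' @param s_f rate scale, `>= 0`, in `rate_unit`.
#' @param s_t startup steepness (1/min), `> 0`.
#' @param t_i startup latency (min), `>= 0`.
#' @param t_e exhaustion time (min), `> 0` and `> t_i`.
#' @param rate_unit `"uL/min"` or `"mL/min"` (no default; must be explicit).
#' @return An object of class `four_params`.
#' @seealso [six_params()], [pump_rate()], [peak_time()]
#' @examples
#' p <- four_params(0.007291, 0.026052, 159.6, 1599.6, rate_unit = "mL/min")
#' peak_time(p)
#' @export
four_params <- function(s_f, s_t, t_i, t_e, rate_unit) {
  p <- structure(
    list(s_f = as.numeric(s_f), s_t = as.numeric(s_t),
         t_i = as.numeric(t_i), t_e = as.numeric(t_e),
         rate_unit = match_rate_unit(rate_unit)),
    class = "four_params"
  )
  validate_params(p)
}

#' Six-parameter pump model state
#'
#' Extends [four_params()] with the diauxic-shift term: a decreasing
#' logistic multiplier `1 + 1/(1 + exp((t - t_s)/t_ds))` that boosts the
#' modelled rate before the glucose-to-fructose metabolic transition and
#' relaxes to 1 after it, producing the transient "wiggle" seen in the
#' stable phase of high-inoculum pumps.
#'
#' @inheritParams four_params
#' @param t_s diauxic shift onset (min), `0 < t_s < t_e`.
#' @param t_ds diauxic transition steepness scale (min), `> 0`.
#' @return An object of class `six_params` (inherits `four_params`).
#' @export
six_params <- function(s_f, s_t, t_i, t_e, t_s, t_ds, rate_unit) {
  p <- structure(
    list(s_f = as.numeric(s_f), s_t = as.numeric(s_t),
         t_i = as.numeric(t_i), t_e = as.numeric(t_e),
         t_s = as.numeric(t_s), t_ds = as.numeric(t_ds),
         rate_unit = match_rate_unit(rate_unit)),
    class = c("six_params", "four_params")
  )
  validate_params(p)
}

validate_params <- function(p) {
  num_fields <- setdiff(names(p), "rate_unit")
  vals <- unlist(p[num_fields])
  if (any(!is.finite(vals))) {
    abort_fermpump("model parameters must all be finite", "fermpump_param_error")
  }
  if (p$s_f < 0) abort_fermpump("s_f must be >= 0", "fermpump_param_error")
  if (p$s_t <= 0) abort_fermpump("s_t must be > 0", "fermpump_param_error")
  if (p$t_i < 0) abort_fermpump("t_i must be >= 0", "fermpump_param_error")
  if (p$t_e <= 0) abort_fermpump("t_e must be > 0", "fermpump_param_error")
  if (p$t_e <= p$t_i) {
    abort_fermpump("t_e must exceed t_i (exhaustion after startup onset)",
                   "fermpump_param_error")
  }
  if (inherits(p, "six_params")) {
    if (p$t_ds <= 0) abort_fermpump("t_ds must be > 0", "fermpump_param_error")
    if (p$t_s <= 0 || p$t_s >= p$t_e) {
      abort_fermpump("t_s must satisfy 0 < t_s < t_e", "fermpump_param_error")
    }
  }
  p
}

#' @export
print.four_params <- function(x, ...) {
  kind <- if (inherits(x, "six_params")) "six-parameter" else "four-parameter"
  cat(sprintf("<%s pump model> (s_f in %s)\n", kind, x$rate_unit))
  num <- unlist(x[setdiff(names(x), "rate_unit")])
  print(num, ...)
  invisible(x)
}

#' Convert the rate unit of a parameter set
#'
#' Rescales `s_f` between uL/min and mL/min (factor of exactly 1000); the
#' time parameters are unaffected.
#'
#' @param p a [four_params()] or [six_params()] object.
#' @param to target unit, `"uL/min"` or `"mL/min"`.
#' @return `p` with `s_f` expressed in `to`.
#' @export
convert_rate_unit <- function(p, to) {
  stopifnot(inherits(p, "four_params"))
  to <- match_rate_unit(to)
  if (identical(p$rate_unit, to)) return(p)
  factor <- if (to == "uL/min") 1000 else 1 / 1000
  p$s_f <- p$s_f * factor
  p$rate_unit <- to
  p
}

#' Read / write model parameters as JSON
#'
#' The file is a flat JSON object with keys `model` (`"four"` or `"six"`),
#' the parameter fields, and a mandatory `rate_unit` tag. Numbers are
#' written at full precision so that decimal strings of up to 10
#' significant digits round-trip exactly.
#'
#' @param path file path.
#' @return `read_params_json()` returns a `four_params`/`six_params`
#'   object; `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$model) || !x$model %in% c("four", "six")) {
    abort_fermpump("parameter file must declare model: \"four\" or \"six\"",
                   "fermpump_io_error")
  }
  if (is.null(x$rate_unit)) {
    abort_fermpump("parameter file must declare rate_unit", "fermpump_unit_error")
  }
  if (identical(x$model, "six")) {
    six_params(x$s_f, x$s_t, x$t_i, x$t_e, x$t_s, x$t_ds, rate_unit = x$rate_unit)
  } else {
    four_params(x$s_f, x$s_t, x$t_i, x$t_e, rate_unit = x$rate_unit)
  }
}

#' @rdname read_params_json
#' @param p a parameter object to serialise.
#' @export
write_params_json <- function(p, path) {
  stopifnot(inherits(p, "four_params"))
  out <- c(list(model = if (inherits(p, "six_params")) "six" else "four"),
           p[setdiff(names(p), "rate_unit")],
           list(rate_unit = p$rate_unit))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
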