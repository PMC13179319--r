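#' Kymograph displacement trace
#'
#' Piston displacement extracted from a kymograph (a time-lapse line
#' profile along the pump cylinder, sampled every few minutes). Positions
#' are in pixels — sub-pixel (non-integer) tracking is accepted — and the
#' calibration converts pixel displacement to pumped volume.
#'
#' @param time_min sampling times (min), strictly increasing.
#' @param position_px piston positions (pixels); monotone non-decreasing up
#'   to tracking noise.
#' @param ul_per_pixel volume calibration (uL per pixel), `> 0`.
#' @return An object of class `displacement_trace`.
#' @export
displacement_trace <- function(time_min, position_px, ul_per_pixel) {
  time_min <- as.numeric(time_min); position_px <- as.numeric(position_px)
  if (length(time_min) < 2L || length(time_min) != length(position_px)) {
    abort_fermpump("need >= 2 paired samples", "fermpump_input_error")
  }
  if (any(!is.finite(time_min)) || any(!is.finite(position_px))) {
    abort_fermpump("samples must be finite", "fermpump_input_error")
  }
  if (any(diff(time_min) <= 0)) {
    abort_fermpump("times must be strictly increasing", "fermpump_input_error")
  }
  if (!is.numeric(ul_per_pixel) || length(ul_per_pixel) != 1L ||
      !is.finite(ul_per_pixel) || ul_per_pixel <= 0) {
    abort_fermpump("ul_per_pixel must be a positive scalar", "fermpump_input_error")
  }
  structure(list(time_min = time_min, position_px = position_px,
                 ul_per_pixel = ul_per_pixel),
            class = "displacement_trace")
}

#' Convert a displacement trace to a volume trace
#'
#' Pumped volume is displacement from the first sample times the
#' calibration: `V(t) = (x(t) - x(t0)) * ul_per_pixel`, so the first sample
#' is 0 uL.
#'
#' @param d a [displacement_trace()].
#' @return A volume [pump_trace()] in uL.
#' @export
displacement_to_volume <- function(d) {
  stopifnot(inherits(d, "displacement_trace"))
  v <- (d$position_px - d$position_px[1]) * d$ul_per_pixel
  pump_trace(d$time_min, v, kind = "volume", rate_unit = "uL/min",
             volume_slack = 1)  # raw tracking noise may dip below monotone
}

#' Mean flow rate over a time window
#'
#' `(V(t_end) - V(t_start)) / (t_end - t_start)` with volumes linearly
#' interpolated at the window ends; the standard summary of kymography
#' runs (e.g. average flow during the stable phase).
#'
#' @param d a [displacement_trace()] or a volume [pump_trace()].
#' @param t_start,t_end window bounds (min), inside the trace span.
#' @return Mean rate in uL/min (or the trace's volume unit per minute).
#' @export
mean_flow_rate <- function(d, t_start, t_end) {
  if (inherits(d, "displacement_trace")) d <- displacement_to_volume(d)
  assert_trace(d, "volume")
  if (!is.finite(t_start) || !is.finite(t_end) || t_start >= t_end) {
    abort_fermpump("need t_start < t_end", "fermpump_input_error")
  }
  if (t_start < min(d$time_min) || t_end > max(d$time_min)) {
    abort_fermpump("window falls outside the trace span", "fermpump_input_error")
  }
  v <- approx(d$time_min, d$value, xout = c(t_start, t_end))$y
  (v[2] - v[1]) / (t_end - t_start)
}

#' Hagen-Poiseuille pressure requirement
#'
#' Pressure needed to drive laminar flow `Q` through a circular channel:
#' `dp = 8 * mu * Q * L / (pi * R^4)`. All geometry and fluid inputs must
#' be supplied explicitly — there are no default channel dimensions. The
#' result scales linearly in `mu`, `Q` and `L` and as `R^-4`.
#'
#' @param mu dynamic viscosity (Pa s), `> 0`.
#' @param flow flow rate, `>= 0`, in `flow_unit`.
#' @param length channel length (m), `> 0`.
#' @param radius channel cross-section radius (m), `> 0`.
#' @param flow_unit `"m3/s"` or `"uL/min"` (1 uL/min = 1e-9/60 m3/s).
#' @return Required pressure difference (Pa).
#' @examples
#' required_pressure(mu = 0.05, flow = 27.68, length = 0.05,
#'                   radius = 250e-6, flow_unit = "uL/min")
#' @export
required_pressure <- function(mu, flow, length, radius,
                              flow_unit = c("m3/s", "uL/min")) {
  flow_unit <- match.arg(flow_unit)
  for (v in list(mu = mu, length = length, radius = radius)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort_fermpump("mu, length and radius must be positive scalars",
                     "fermpump_input_error")
    }
  }
  if (!is.numeric(flow) || length(flow) != 1L || !is.finite(flow) || flow < 0) {
    abort_fermpump("flow must be a non-negative scalar", "fermpump_input_error")
  }
  q <- if (flow_unit == "uL/min") flow * 1e-9 / 60 else flow
  8 * mu * q * length / (pi * radius^4)
}
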