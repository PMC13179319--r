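#' Pump configuration
#'
#' The experimental condition of a yeast pump: yeast inoculum mass `m` (mg
#' of instant dry yeast) and sucrose concentration `s` (wt% in 1 mL of
#' water). The affine parameter maps were calibrated for `m <= 5` mg and
#' `s <= 5` wt%; configurations outside that box carry `in_domain = FALSE`
#' and downstream interpolation warns (extrapolation was shown to be
#' unreliable, e.g. at 7 mg).
#'
#' @param m yeast inoculum mass (mg), `> 0`.
#' @param s sucrose concentration (wt%), `> 0`.
#' @return An object of class `pump_config` with fields `m`, `s`,
#'   `in_domain`.
#' @export
pump_config <- function(m, s) {
  m <- as.numeric(m); s <- as.numeric(s)
  if (length(m) != 1L || length(s) != 1L || !is.finite(m) || !is.finite(s) ||
      m <= 0 || s <= 0) {
    abort_fermpump("m and s must be positive finite scalars", "fermpump_input_error")
  }
  structure(list(m = m, s = s, in_domain = (m <= 5 && s <= 5)),
            class = "pump_config")
}

#' @export
print.pump_config <- function(x, ...) {
  cat(sprintf("<pump config> %.3g mg yeast, %.3g wt%% sucrose%s\n",
              x$m, x$s, if (x$in_domain) "" else "  [outside calibrated domain]"))
  invisible(x)
}

PARAM_NAMES <- c("s_f", "s_t", "t_i", "t_e")

#' Coefficient table of the two-parameter linear layer
#'
#' Each of the four rate-model parameters is an affine function of the pump
#' configuration, e.g. `s_f(m, s) = C_m * m + C_s * s + C_0`, so twelve
#' coefficients reduce the four-parameter model to two intuitive knobs:
#' yeast mass and sucrose concentration.
#'
#' @param coef a 4 x 3 numeric matrix: rows `s_f, s_t, t_i, t_e`, columns
#'   `m, s, const`.
#' @param rate_unit unit of the `s_f` row (the published coefficients are
#'   on the mL/min scale).
#' @return An object of class `coefficient_table`.
#' @seealso [default_coefficients()] for the published values.
#' @export
coefficient_table <- function(coef, rate_unit) {
  coef <- as.matrix(coef)
  if (!is.numeric(coef) || any(dim(coef) != c(4L, 3L)) || any(!is.finite(coef))) {
    abort_fermpump("coef must be a finite 4 x 3 numeric matrix", "fermpump_input_error")
  }
  dimnames(coef) <- list(PARAM_NAMES, c("m", "s", "const"))
  tab <- structure(list(coef = coef, rate_unit = match_rate_unit(rate_unit)),
                   class = "coefficient_table")
  # sanity: the derived model must be ordered (t_e > t_i > 0) at the four
  # corners of the calibrated domain
  for (m in c(1, 5)) for (s in c(1, 5)) {
    p <- drop(coef %*% c(m, s, 1))
    if (!(p["t_e"] > p["t_i"] && p["t_i"] > 0)) {
      abort_fermpump(
        sprintf("coefficient table gives t_e <= t_i or t_i <= 0 at (m=%g, s=%g)", m, s),
        "fermpump_input_error"
      )
    }
  }
  tab
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat(sprintf("<coefficient table> parameter = C_m*m + C_s*s + C_0 (s_f in %s)\n",
              x$rate_unit))
  print(x$coef, ...)
  invisible(x)
}

#' Published coefficient table
#'
#' The twelve coefficients of the affine configuration-to-parameter maps as
#' calibrated on the original syringe pump (yeast masses 1-7 mg, sucrose
#' 1-5 wt%, 37 degC, 1 mL medium), valid for interpolation at `m <= 5` mg
#' and `s <= 5` wt%. The `s_f` row is on the mL/min scale. Note these
#' coefficients and the worked-example parameter sets quoted in the
#' package's examples come from two distinct sources (a least-squares plane
#' versus chart-read parameters), so the table evaluated at (5, 5) does not
#' reproduce the worked-example parameters exactly; the package never mixes
#' the two silently.
#'
#' @return A [coefficient_table()].
#' @export
default_coefficients <- function() {
  path <- system.file("extdata", "pump_coefficients.json", package = "fermpump",
                      mustWork = TRUE)
  read_coefficients_json(path)
}

#' Read / write a coefficient table as JSON
#'
#' Flat JSON object with the twelve coefficients named `C_<x><p>` where
#' `<x>` is `m`, `s` or empty (constant term) and `<p>` one of
#' `sf, st, ti, te` — e.g. `C_msf`, `C_ste`, `C_ti` — plus a `rate_unit`
#' tag for the `s_f` row.
#'
#' @param path file path.
#' @return `read_coefficients_json()`: a [coefficient_table()];
#'   `write_coefficients_json()`: `path`, invisibly.
#' @export
read_coefficients_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  short <- c(s_f = "sf", s_t = "st", t_i = "ti", t_e = "te")
  coef <- matrix(NA_real_, 4, 3, dimnames = list(PARAM_NAMES, c("m", "s", "const")))
  for (p in PARAM_NAMES) {
    keys <- paste0("C_", c(paste0("m", short[p]), paste0("s", short[p]), short[p]))
    if (!all(keys %in% names(x))) {
      abort_fermpump(sprintf("coefficient file is missing one of: %s",
                             paste(keys, collapse = ", ")), "fermpump_io_error")
    }
    coef[p, ] <- unlist(x[keys])
  }
  if (is.null(x$rate_unit)) {
    abort_fermpump("coefficient file must declare rate_unit", "fermpump_unit_error")
  }
  coefficient_table(coef, rate_unit = x$rate_unit)
}

#' @rdname read_coefficients_json
#' @param table a [coefficient_table()].
#' @export
write_coefficients_json <- function(table, path) {
  stopifnot(inherits(table, "coefficient_table"))
  short <- c(s_f = "sf", s_t = "st", t_i = "ti", t_e = "te")
  out <- list()
  for (p in PARAM_NAMES) {
    out[[paste0("C_m", short[p])]] <- table$coef[p, "m"]
    out[[paste0("C_s", short[p])]] <- table$coef[p, "s"]
    out[[paste0("C_", short[p])]] <- table$coef[p, "const"]
  }
  out$rate_unit <- table$rate_unit
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Model parameters for a pump configuration
#'
#' Evaluates the affine maps at `(m, s)` and validates the result as a
#' [four_params()] object. Configurations outside the calibrated box
#' (`m <= 5`, `s <= 5`) are interpolated anyway but emit a structured
#' warning (`fermpump_domain_warning`); configurations at which the affine
#' maps produce invalid parameters (e.g. negative `s_f` near the origin)
#' raise an interpolation-out-of-range error.
#'
#' @param config a [pump_config()].
#' @param table a [coefficient_table()]; defaults to the published one.
#' @return A [four_params()] in the table's rate unit.
#' @examples
#' params_from_config(pump_config(5, 5))
#' @export
params_from_config <- function(config, table = default_coefficients()) {
  stopifnot(inherits(config, "pump_config"), inherits(table, "coefficient_table"))
  if (!config$in_domain) {
    warn_fermpump(
      sprintf("config (m=%g mg, s=%g wt%%) is outside the calibrated domain (m <= 5, s <= 5); extrapolation is unreliable",
              config$m, config$s),
      "fermpump_domain_warning"
    )
  }
  p <- drop(table$coef %*% c(config$m, config$s, 1))
  tryCatch(
    four_params(p["s_f"], p["s_t"], p["t_i"], p["t_e"], rate_unit = table$rate_unit),
    fermpump_param_error = function(e) {
      abort_fermpump(
        sprintf("interpolated parameters are invalid at (m=%g, s=%g): %s",
                config$m, config$s, conditionMessage(e)),
        "fermpump_interpolation_error"
      )
    }
  )
}

#' Refit the coefficient table from calibrations
#'
#' Each calibration pairs a pump configuration with the four-parameter fit
#' obtained on that condition (see [calibration()]). Per model parameter, a
#' least-squares plane `C_m * m + C_s * s + C_0` is fitted through the
#' calibration points; with exactly three non-collinear configurations the
#' plane interpolates them exactly. Adapting the model to a new yeast
#' strain or pump geometry therefore needs at least three calibrations.
#'
#' @param calibrations list of [calibration()] objects (>= 3, with
#'   configurations not collinear in the (m, s) plane, all parameter sets
#'   in the same rate unit).
#' @return A [coefficient_table()].
#' @export
fit_coefficients <- function(calibrations) {
  if (!is.list(calibrations) || length(calibrations) < 3L) {
    abort_fermpump("at least 3 calibrations are required", "fermpump_input_error")
  }
  ok <- vapply(calibrations, inherits, logical(1), what = "calibration")
  if (!all(ok)) abort_fermpump("expected a list of calibration objects",
                               "fermpump_input_error")
  units <- vapply(calibrations, function(c) c$params$rate_unit, character(1))
  if (length(unique(units)) != 1L) {
    abort_fermpump("all calibration parameter sets must share a rate unit",
                   "fermpump_unit_error")
  }
  m <- vapply(calibrations, function(c) c$config$m, numeric(1))
  s <- vapply(calibrations, function(c) c$config$s, numeric(1))
  X <- cbind(m = m, s = s, const = 1)
  if (qr(X)$rank < 3L) {
    abort_fermpump("calibration configurations are collinear in the (m, s) plane; the coefficient planes are not identifiable",
                   "fermpump_rank_error")
  }
  Y <- t(vapply(calibrations,
                function(c) unlist(c$params[PARAM_NAMES]),
                numeric(4)))
  coef <- t(qr.solve(X, Y))   # least squares; exact interpolation for n = 3
  coefficient_table(coef, rate_unit = units[1])
}

#' A calibration point
#'
#' Pairs a [pump_config()] with the [four_params()] fitted on a trace
#' measured at that configuration; input to [fit_coefficients()].
#'
#' @param config a [pump_config()].
#' @param params the fitted [four_params()].
#' @return An object of class `calibration`.
#' @export
calibration <- function(config, params) {
  stopifnot(inherits(config, "pump_config"), inherits(params, "four_params"))
  validate_params(params)
  structure(list(config = config, params = params), class = "calibration")
}

#' Predict pump performance for a configuration
#'
#' Composes [params_from_config()] with the closed-form peak analytics:
#' returns the time to peak pump rate, the peak rate (converted to uL/min
#' whatever the table's scale), and the runtime (the exhaustion time
#' `t_e`).
#'
#' @inheritParams params_from_config
#' @return A list of class `pump_performance` with `t_max_min`,
#'   `q_max_ul_min`, `runtime_min`, and the interpolated `params`.
#' @export
predict_performance <- function(config, table = default_coefficients()) {
  params <- params_from_config(config, table)
  p_ul <- convert_rate_unit(params, "uL/min")
  structure(list(
    t_max_min = peak_time(params),
    q_max_ul_min = peak_rate(p_ul),
    runtime_min = params$t_e,
    params = params,
    config = config
  ), class = "pump_performance")
}

#' @export
print.pump_performance <- function(x, ...) {
  cat(sprintf("<pump performance> m = %.3g mg, s = %.3g wt%%\n", x$config$m, x$config$s))
  cat(sprintf("  peak %.2f uL/min at %.2f min; runtime %.1f min\n",
              x$q_max_ul_min, x$t_max_min, x$runtime_min))
  invisible(x)
}

#' Inverse design: configuration for a target peak rate and runtime
#'
#' Mirrors the experimental control strategy — yeast inoculum mass sets the
#' pump rate, sucrose concentration fine-tunes the runtime — as an
#' alternating two-stage solve iterated to a fixed point: (1) at the
#' current sucrose level, pick `m` in `[1, 5]` minimizing the peak-rate
#' mismatch; (2) solve the affine runtime map `t_e(m, s) = target_runtime`
#' for `s` in closed form. Designs are confined to the calibrated box
#' `[1, 5] mg x [1, 5] wt%`; targets that would require leaving it raise an
#' `fermpump_infeasible_design` error that carries the closest achievable
#' design in its `closest` field.
#'
#' @param target_q_max desired peak pump rate (uL/min), `> 0`.
#' @param target_runtime desired runtime (min), `> 0`.
#' @param table a [coefficient_table()].
#' @param tol relative tolerance on meeting the targets.
#' @return A list of class `pump_design`: `config` ([pump_config()]),
#'   `achieved` ([predict_performance()] output) and `target`.
#' @export
inverse_design <- function(target_q_max, target_runtime,
                           table = default_coefficients(), tol = 1e-3) {
  stopifnot(inherits(table, "coefficient_table"))
  if (!is.finite(target_q_max) || target_q_max <= 0 ||
      !is.finite(target_runtime) || target_runtime <= 0) {
    abort_fermpump("targets must be positive and finite", "fermpump_input_error")
  }
  q_at <- function(m, s) {
    p <- drop(table$coef %*% c(m, s, 1))
    pr <- four_params(max(p["s_f"], 0), p["s_t"], max(p["t_i"], 0), p["t_e"],
                      rate_unit = table$rate_unit)
    peak_rate(convert_rate_unit(pr, "uL/min"))
  }
  te_row <- table$coef["t_e", ]
  s_for_runtime <- function(m) {
    (target_runtime - te_row["const"] - te_row["m"] * m) / te_row["s"]
  }

  s_cur <- 3  # domain midpoint as the nominal sucrose level
  m_cur <- NA_real_
  for (iter in 1:50) {
    opt <- optimize(function(m) abs(q_at(m, s_cur) - target_q_max),
                    lower = 1, upper = 5, tol = 1e-6)
    m_new <- opt$minimum
    s_new <- min(max(unname(s_for_runtime(m_new)), 1), 5)
    done <- !is.na(m_cur) && abs(m_new - m_cur) < 1e-7 && abs(s_new - s_cur) < 1e-7
    m_cur <- m_new; s_cur <- s_new
    if (done) break
  }
  cfg <- pump_config(m_cur, s_cur)
  achieved <- predict_performance(cfg, table)
  q_miss <- abs(achieved$q_max_ul_min - target_q_max) / target_q_max
  t_miss <- abs(achieved$runtime_min - target_runtime) / target_runtime
  if (q_miss > tol || t_miss > tol) {
    stop(structure(
      class = c("fermpump_infeasible_design", "fermpump_error", "error", "condition"),
      list(message = sprintf(
        "targets (Q_max = %.4g uL/min, runtime = %.4g min) are not reachable inside the calibrated domain; closest achievable: Q_max = %.4g uL/min, runtime = %.4g min at (m = %.3g mg, s = %.3g wt%%)",
        target_q_max, target_runtime,
        achieved$q_max_ul_min, achieved$runtime_min, cfg$m, cfg$s),
        call = NULL,
        closest = list(config = cfg, achieved = achieved))
    ))
  }
  structure(list(config = cfg, achieved = achieved,
                 target = list(q_max_ul_min = target_q_max,
                               runtime_min = target_runtime)),
            class = "pump_design")
}

#' @export
print.pump_design <- function(x, ...) {
  cat(sprintf("<pump design> use %.3g mg yeast, %.3g wt%% sucrose\n",
              x$config$m, x$config$s))
  cat(sprintf("  target: %.4g uL/min, %.4g min; achieved: %.4g uL/min, %.4g min\n",
              x$target$q_max_ul_min, x$target$runtime_min,
              x$achieved$q_max_ul_min, x$achieved$runtime_min))
  invisible(x)
}
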