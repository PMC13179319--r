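#' Noise specification for the synthetic-trace generator
#'
#' The generator is phenomenological: it does not simulate substrate
#' dynamics, only reproduces how kymography-derived traces look. Three
#' noise channels are available, all seeded for exact reproducibility:
#'
#' * `rate_sigma_frac` — additive Gaussian noise on the sampled rate, with
#'   standard deviation expressed as a fraction of the noiseless peak rate
#'   (default 4%);
#' * `replicate_cv` — lognormal, mean-preserving per-replicate jitter of
#'   the model parameters (coefficient of variation, default 5%), mimicking
#'   biological batch effects across the N = 6 replicates of a condition;
#' * `pixel_quantum` — optional quantization of volume traces to whole
#'   pixels (uL per pixel; 0 disables), mimicking kymograph resolution.
#'
#' The experimental studies publish only min-max replicate envelopes, not a
#' noise model, so these defaults are plausible stand-ins, not measured
#' values.
#'
#' @param rate_sigma_frac fraction of peak rate, `>= 0`.
#' @param replicate_cv coefficient of variation, `>= 0`.
#' @param pixel_quantum uL per pixel, `>= 0` (0 = off).
#' @param seed integer seed (mandatory for reproducibility).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(rate_sigma_frac = 0.04, replicate_cv = 0.05,
                       pixel_quantum = 0, seed = 1L) {
  vals <- c(rate_sigma_frac, replicate_cv, pixel_quantum)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort_fermpump("noise fractions must be finite and >= 0", "fermpump_input_error")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed)) {
    abort_fermpump("seed must be a single integer", "fermpump_input_error")
  }
  structure(list(rate_sigma_frac = rate_sigma_frac,
                 replicate_cv = replicate_cv,
                 pixel_quantum = pixel_quantum,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @details `zero_noise()` is shorthand for a spec with every noise channel
#'   switched off (exact model samples).
#' @export
zero_noise <- function(seed = 1L) {
  noise_spec(rate_sigma_frac = 0, replicate_cv = 0, pixel_quantum = 0, seed = seed)
}

#' Generate a synthetic pump trace
#'
#' Samples the model rate on `[0, t_e + 2 dt]` at cadence `dt` (default 3
#' min, the kymography capture interval), adds seeded Gaussian rate noise,
#' and — for `kind = "volume"` — integrates by cumulative trapezoid and
#' optionally quantizes to the pixel volume. A given `(params, dt, noise,
#' kind)` always yields the identical trace; the global RNG state is left
#' untouched.
#'
#' @param params a valid [four_params()] or [six_params()].
#' @param dt sampling interval (min), `> 0`.
#' @param noise a [noise_spec()].
#' @param kind `"rate"` or `"volume"` output.
#' @return A [pump_trace()] in `params$rate_unit`.
#' @examples
#' p <- four_params(0.007291, 0.026052, 159.6, 1599.6, rate_unit = "mL/min")
#' tr <- generate_trace(p, noise = noise_spec(seed = 7))
#' @export
generate_trace <- function(params, dt = 3, noise = noise_spec(),
                           kind = c("rate", "volume")) {
  stopifnot(inherits(params, "four_params"), inherits(noise, "noise_spec"))
  validate_params(params)
  kind <- match.arg(kind)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort_fermpump("dt must be a positive scalar", "fermpump_input_error")
  }
  times <- seq(0, params$t_e + 2 * dt, by = dt)
  q <- pump_rate(params, times)
  sigma <- noise$rate_sigma_frac * max(q)
  if (sigma > 0) {
    q <- q + withr::with_seed(noise$seed, rnorm(length(times), sd = sigma))
  }
  if (kind == "rate") {
    return(pump_trace(times, q, kind = "rate", rate_unit = params$rate_unit))
  }
  v <- pracma::cumtrapz(times, q)[, 1]
  if (noise$pixel_quantum > 0) {
    v <- round(v / noise$pixel_quantum) * noise$pixel_quantum
  }
  pump_trace(times, v, kind = "volume", rate_unit = params$rate_unit,
             volume_slack = 1)
}

# mean-preserving lognormal multiplier(s) with coefficient of variation cv
lognormal_jitter <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

jitter_params <- function(params, cv) {
  fields <- intersect(names(params), c("s_f", "s_t", "t_i", "t_e", "t_s", "t_ds"))
  mult <- lognormal_jitter(length(fields), cv)
  for (k in seq_along(fields)) params[[fields[k]]] <- params[[fields[k]]] * mult[k]
  validate_params(params)
}

#' Generate replicate traces for one condition
#'
#' Emulates the N = 6 replicate envelopes of a condition: each replicate
#' gets its own parameter set, drawn by mean-preserving lognormal jitter
#' (cv = `noise$replicate_cv`) around `params`, then a trace via
#' [generate_trace()]. Sub-seeds derive from the master seed by fixed
#' arithmetic — parameter jitter of replicate `i` uses `seed + i`, its rate
#' noise uses `seed + n + i` — so every replicate is individually
#' reproducible.
#'
#' @inheritParams generate_trace
#' @param n number of replicates (default 6).
#' @return A list of `n` [pump_trace()] objects; the jittered parameter set
#'   of each replicate is attached as attribute `"params"`.
#' @export
generate_replicates <- function(params, n = 6, dt = 3, noise = noise_spec(),
                                kind = c("rate", "volume")) {
  kind <- match.arg(kind)
  stopifnot(inherits(noise, "noise_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort_fermpump("n must be a positive integer", "fermpump_input_error")
  }
  lapply(seq_len(n), function(i) {
    p_i <- withr::with_seed(noise$seed + i,
                            jitter_params(params, noise$replicate_cv))
    noise_i <- noise
    noise_i$seed <- noise$seed + as.integer(n) + i
    tr <- generate_trace(p_i, dt = dt, noise = noise_i, kind = kind)
    attr(tr, "params") <- p_i
    tr
  })
}

#' Min-max envelope of replicate traces
#'
#' Replicate parameter jitter shifts each replicate's exhaustion time, so
#' traces of one condition can differ in length; the envelope is computed
#' over the time points shared by all replicates (the common head of the
#' sampling grid).
#'
#' @param traces list of [pump_trace()] objects sampled on the same cadence
#'   from time 0.
#' @return A data frame with `time_min`, `lo`, `hi`.
#' @export
replicate_envelope <- function(traces) {
  lapply(traces, assert_trace)
  n_common <- min(vapply(traces, nrow, integer(1)))
  t0 <- traces[[1]]$time_min[seq_len(n_common)]
  for (tr in traces[-1]) {
    if (!isTRUE(all.equal(tr$time_min[seq_len(n_common)], t0))) {
      abort_fermpump("replicates must share their sampling grid",
                     "fermpump_input_error")
    }
  }
  vals <- vapply(traces, function(tr) tr$value[seq_len(n_common)],
                 numeric(n_common))
  data.frame(time_min = t0,
             lo = apply(vals, 1, min),
             hi = apply(vals, 1, max))
}

#' Generate a synthetic calibration grid
#'
#' For each configuration, reads the four model parameters off the
#' coefficient table and applies seeded lognormal jitter
#' (cv = `noise$replicate_cv`), emulating per-condition fitting scatter.
#' Feeds [fit_coefficients()] recovery tests: with zero noise and three
#' non-collinear configurations the generating table is recovered exactly.
#'
#' @param table a [coefficient_table()].
#' @param configs list of [pump_config()] objects, all inside the
#'   calibrated domain.
#' @param noise a [noise_spec()]; `replicate_cv` drives the jitter.
#' @return A list of [calibration()] objects (empty list for no configs).
#' @export
generate_calibration_grid <- function(table, configs, noise = zero_noise()) {
  stopifnot(inherits(table, "coefficient_table"), inherits(noise, "noise_spec"))
  if (!length(configs)) return(list())
  lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    stopifnot(inherits(cfg, "pump_config"))
    if (!cfg$in_domain) {
      abort_fermpump(
        sprintf("config (m=%g, s=%g) is outside the calibrated domain", cfg$m, cfg$s),
        "fermpump_input_error"
      )
    }
    p <- params_from_config(cfg, table)
    p <- withr::with_seed(noise$seed + i, jitter_params(p, noise$replicate_cv))
    calibration(cfg, p)
  })
}
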