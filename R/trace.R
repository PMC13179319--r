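#' Time-series trace of pump output
#'
#' A `pump_trace` is a data frame with columns `time_min` and `value` plus
#' attributes declaring what the values are: instantaneous production rate
#' (`kind = "rate"`) or cumulative pumped volume (`kind = "volume"`), and
#' the rate unit (`"uL/min"` or `"mL/min"`; volume traces use the matching
#' uL/mL). Kymography-derived experimental traces are sampled every 3
#' minutes; the generator in [generate_trace()] follows the same cadence.
#'
#' Times must be strictly increasing. Volume traces are checked to be
#' non-decreasing up to a slack (fraction of the observed span, default 5%)
#' that tolerates measurement noise and pixel quantization.
#'
#' @param time_min sampling times (min), strictly increasing.
#' @param value rates or cumulative volumes.
#' @param kind `"rate"` or `"volume"`.
#' @param rate_unit `"uL/min"` or `"mL/min"`.
#' @param volume_slack tolerated downward excursion in a volume trace, as a
#'   fraction of the observed value span.
#' @return A data frame of class `pump_trace`.
#' @export
pump_trace <- function(time_min, value, kind = c("rate", "volume"),
                       rate_unit, volume_slack = 0.05) {
  kind <- match.arg(kind)
  rate_unit <- match_rate_unit(rate_unit)
  time_min <- as.numeric(time_min)
  value <- as.numeric(value)
  if (length(time_min) != length(value)) {
    abort_fermpump("time_min and value must have equal length", "fermpump_input_error")
  }
  if (length(time_min) < 2L) {
    abort_fermpump("a trace needs at least 2 samples", "fermpump_input_error")
  }
  if (any(!is.finite(time_min)) || any(!is.finite(value))) {
    abort_fermpump("trace samples must be finite", "fermpump_input_error")
  }
  if (any(diff(time_min) <= 0)) {
    abort_fermpump("trace times must be strictly increasing", "fermpump_input_error")
  }
  if (kind == "volume") {
    span <- diff(range(value))
    drop <- -min(0, min(diff(value)))
    if (span > 0 && drop > volume_slack * span) {
      abort_fermpump(
        sprintf("volume trace decreases by %.3g, more than the allowed slack (%.3g)",
                drop, volume_slack * span),
        "fermpump_input_error"
      )
    }
  }
  structure(data.frame(time_min = time_min, value = value),
            kind = kind, rate_unit = rate_unit,
            class = c("pump_trace", "data.frame"))
}

trace_kind <- function(trace) attr(trace, "kind")
trace_unit <- function(trace) attr(trace, "rate_unit")

assert_trace <- function(trace, kind = NULL) {
  if (!inherits(trace, "pump_trace")) {
    abort_fermpump("expected a pump_trace object", "fermpump_input_error")
  }
  if (!is.null(kind) && !identical(trace_kind(trace), kind)) {
    abort_fermpump(sprintf("expected a %s trace, got %s", kind, trace_kind(trace)),
                   "fermpump_input_error")
  }
  invisible(trace)
}

#' Read or write a trace CSV
#'
#' The CSV has the two-column header `time_min,value`. The file itself does
#' not carry the trace kind or unit, so both must be declared when reading.
#' Unsorted times are rejected.
#'
#' @param path CSV file path.
#' @inheritParams pump_trace
#' @return `read_trace_csv()` a [pump_trace()]; `write_trace_csv()` `path`,
#'   invisibly.
#' @export
read_trace_csv <- function(path, kind, rate_unit) {
  df <- read.csv(path)
  if (!all(c("time_min", "value") %in% names(df))) {
    abort_fermpump("trace CSV must have header: time_min,value", "fermpump_io_error")
  }
  pump_trace(df$time_min, df$value, kind = kind, rate_unit = rate_unit)
}

#' @rdname read_trace_csv
#' @param trace a [pump_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  assert_trace(trace)
  write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Differentiate a volume trace into a rate trace
#'
#' Centered finite differences (one-sided at the two edges) followed by a
#' moving average of odd width `window` (default 3 samples). Output times
#' equal input times. Used as the pre-step when fitting the rate model to
#' piston-displacement (volume) data.
#'
#' @param trace a volume [pump_trace()].
#' @param window odd smoothing width in samples; `1` disables smoothing.
#' @return A rate [pump_trace()] in the matching rate unit.
#' @examples
#' v <- pump_trace(0:10, 2 * (0:10), kind = "volume", rate_unit = "uL/min")
#' rate_from_volume(v)$value   # constant 2 uL/min
#' @export
rate_from_volume <- function(trace, window = 3) {
  assert_trace(trace, "volume")
  if (!is.numeric(window) || length(window) != 1L || window < 1 || window %% 2 != 1) {
    abort_fermpump("window must be a positive odd integer", "fermpump_input_error")
  }
  t <- trace$time_min
  v <- trace$value
  n <- length(t)
  if (n < window + 1L) {
    abort_fermpump("too few samples for the requested smoothing window",
                   "fermpump_input_error")
  }
  r <- numeric(n)
  r[1] <- (v[2] - v[1]) / (t[2] - t[1])
  r[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    idx <- 2:(n - 1)
    r[idx] <- (v[idx + 1] - v[idx - 1]) / (t[idx + 1] - t[idx - 1])
  }
  if (window > 1) {
    half <- (window - 1L) / 2L
    sm <- vapply(seq_len(n), function(i) {
      j <- max(1L, i - half):min(n, i + half)   # window shrinks at edges
      mean(r[j])
    }, numeric(1))
    r <- sm
  }
  pump_trace(t, r, kind = "rate", rate_unit = trace_unit(trace))
}

#' Average replicate traces
#'
#' Point-wise mean of replicate traces sampled on a common time grid; a
#' pre-step for fitting condition-level parameters when per-replicate fits
#' are not wanted.
#'
#' @param traces list of [pump_trace()] objects with identical times, kind
#'   and unit.
#' @return A single [pump_trace()].
#' @export
mean_of_replicates <- function(traces) {
  if (!length(traces)) abort_fermpump("no traces given", "fermpump_input_error")
  lapply(traces, assert_trace)
  t0 <- traces[[1]]$time_min
  k0 <- trace_kind(traces[[1]]); u0 <- trace_unit(traces[[1]])
  for (tr in traces[-1]) {
    if (!isTRUE(all.equal(tr$time_min, t0)) ||
        !identical(trace_kind(tr), k0) || !identical(trace_unit(tr), u0)) {
      abort_fermpump("replicates must share times, kind and unit",
                     "fermpump_input_error")
    }
  }
  vals <- rowMeans(vapply(traces, function(tr) tr$value, numeric(length(t0))))
  pump_trace(t0, vals, kind = k0, rate_unit = u0,
             volume_slack = 1)  # means of noisy replicates can dip locally
}
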