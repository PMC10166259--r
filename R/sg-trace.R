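#' Strain-gauge force trace
#'
#' Container for a uniformly sampled analog force signal, the substrate of
#' lick detection. Samples are volts of the amplified strain-gauge signal.
#'
#' @param samples numeric vector of samples (volts); must be finite.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param t0_s time of the first sample, seconds.
#' @param units unit label, default `"V"`.
#' @param channel channel label carried into the JSON sidecar on export.
#'
#' @return An object of class `sg_trace`: a list with elements `samples`,
#'   `fs_hz`, `t0_s`, `units`, `channel`.
#' @examples
#' tr <- sg_trace(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), fs_hz = 1000)
#' tr
#' @export
sg_trace <- function(samples, fs_hz, t0_s = 0, units = "V", channel = "sg") {
  if (!is.numeric(samples)) stop_param("`samples` must be numeric")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_data("trace samples must all be finite")
  }
  check_scalar(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  check_scalar(t0_s, "t0_s")
  structure(
    list(samples = as.numeric(samples), fs_hz = as.numeric(fs_hz),
         t0_s = as.numeric(t0_s), units = units, channel = channel),
    class = "sg_trace"
  )
}

#' Sample times of a trace
#' @param x an [sg_trace].
#' @return numeric vector of times (s), same length as `x$samples`.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "sg_trace"))
  x$t0_s + (seq_along(x$samples) - 1) / x$fs_hz
}

#' @export
print.sg_trace <- function(x, ...) {
  dur <- length(x$samples) / x$fs_hz
  cat(sprintf("<sg_trace> %d samples @ %g Hz (%.3f s), range [%.4g, %.4g] %s\n",
              length(x$samples), x$fs_hz, dur,
              min(x$samples), max(x$samples), x$units))
  invisible(x)
}

#' @export
plot.sg_trace <- function(x, ...) {
  plot(trace_times(x), x$samples, type = "l",
       xlab = "time (s)", ylab = sprintf("signal (%s)", x$units), ...)
  invisible(x)
}

#' Ordered lick event series
#'
#' Ordered lick timestamps with a source label distinguishing ground truth,
#' offline-detected and online-TTL series.
#'
#' @param times_s numeric vector of event times in seconds; sorted on input.
#' @param source character label, e.g. `"ground_truth"`, `"sg_offline"`,
#'   `"sg_online"`.
#' @return An object of class `lick_events`.
#' @export
lick_events <- function(times_s, source = "unknown") {
  if (length(times_s) && (!is.numeric(times_s) || anyNA(times_s))) {
    stop_param("`times_s` must be numeric without NA")
  }
  structure(
    list(times_s = sort(as.numeric(times_s)), source = as.character(source)[1]),
    class = "lick_events"
  )
}

#' @export
print.lick_events <- function(x, ...) {
  cat(sprintf("<lick_events> %d events [%s]", length(x$times_s), x$source))
  if (length(x$times_s)) {
    cat(sprintf(", span %.3f-%.3f s", min(x$times_s), max(x$times_s)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.lick_events <- function(x) length(x$times_s)

# Accept either a lick_events object or a bare numeric vector of times.
as_lick_times <- function(x) {
  if (inherits(x, "lick_events")) return(x$times_s)
  if (is.numeric(x)) return(sort(as.numeric(x)))
  stop_param("expected a `lick_events` object or a numeric vector of times")
}
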