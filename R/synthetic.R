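# Synthetic-data generators: lick trains and strain-gauge traces,
# event-locked calcium traces, and frame clocks with dropped frames. Every
# generator retains its ground truth so detector and classifier performance
# can be scored exactly.

#' Specification of a synthetic lick train
#'
#' Licks are drawn from a renewal process: each interlick interval is a hard
#' refractory period plus an exponential residual. At the default 10 Hz mean
#' rate with an 80 ms refractory period this concentrates the interlick
#' distribution just below 100 ms, emulating the ~100 ms interval mode of
#' real licking bouts.
#'
#' @param rate_hz mean lick rate (Hz, >= 0; 0 yields an empty train).
#' @param refractory_s minimum interlick interval (s, > 0); when
#'   `rate_hz > 0` it must satisfy `refractory_s < 1 / rate_hz`.
#' @param duration_s span of the train (s, > 0).
#' @param amplitude_V mean transient peak height (V, > 0).
#' @param amplitude_cv coefficient of variation of peak heights (>= 0);
#'   amplitudes are lognormal so they remain positive.
#' @param width_s full width of the force transient (s, > 0).
#' @param seed integer seed; identical spec + seed give identical output.
#' @return object of class `lick_train_spec`.
#' @export
lick_train_spec <- function(rate_hz = 10, refractory_s = 0.08,
                            duration_s = 10, amplitude_V = 0.3,
                            amplitude_cv = 0.2, width_s = 0.12, seed = 1) {
  check_scalar(rate_hz, "rate_hz", 0)
  check_scalar(refractory_s, "refractory_s", 0, strict_lower = TRUE)
  check_scalar(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_scalar(amplitude_V, "amplitude_V", 0, strict_lower = TRUE)
  check_scalar(amplitude_cv, "amplitude_cv", 0)
  check_scalar(width_s, "width_s", 0, strict_lower = TRUE)
  if (rate_hz > 0 && refractory_s >= 1 / rate_hz) {
    stop_param("`refractory_s` must be shorter than the mean interlick interval 1/rate_hz")
  }
  structure(list(rate_hz = rate_hz, refractory_s = refractory_s,
                 duration_s = duration_s, amplitude_V = amplitude_V,
                 amplitude_cv = amplitude_cv, width_s = width_s,
                 seed = as.integer(seed)),
            class = "lick_train_spec")
}

#' Noise model for synthetic strain-gauge traces
#'
#' @param sigma_V Gaussian noise standard deviation (V, >= 0).
#' @param drift_V_per_s linear baseline drift rate (V/s).
#' @param baseline_V constant baseline offset (V).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_V = 0.01, drift_V_per_s = 0, baseline_V = 0) {
  check_scalar(sigma_V, "sigma_V", 0)
  check_scalar(drift_V_per_s, "drift_V_per_s")
  check_scalar(baseline_V, "baseline_V")
  structure(list(sigma_V = sigma_V, drift_V_per_s = drift_V_per_s,
                 baseline_V = baseline_V),
            class = "noise_spec")
}

#' Generate a synthetic lick train
#'
#' Renewal process with interlick interval = `refractory_s` + Exp(rate
#' lambda), where lambda is set so the mean interval equals `1 / rate_hz`.
#' Per-lick peak amplitudes are lognormal with mean `amplitude_V` and CV
#' `amplitude_cv`, attached as attribute `"amplitudes_V"`.
#'
#' @param spec a [lick_train_spec].
#' @return a [lick_events] with source `"ground_truth"`; attributes
#'   `amplitudes_V`, `duration_s` and `spec`.
#' @export
gen_lick_train <- function(spec) {
  if (!inherits(spec, "lick_train_spec")) {
    stop_param("`spec` must be a lick_train_spec")
  }
  with_seed(spec$seed, {
    times <- numeric(0)
    if (spec$rate_hz > 0) {
      mean_ili <- 1 / spec$rate_hz
      lambda <- 1 / (mean_ili - spec$refractory_s)
      expected <- spec$duration_s * spec$rate_hz
      t_last <- 0
      repeat {
        m <- max(16L, ceiling(expected - length(times)) + 10L +
                   ceiling(4 * sqrt(expected + 1)))
        new <- t_last + cumsum(spec$refractory_s + stats::rexp(m, lambda))
        times <- c(times, new)
        t_last <- times[length(times)]
        if (t_last > spec$duration_s) break
      }
      times <- times[times <= spec$duration_s]
    }
    n <- length(times)
    amps <- if (n) {
      if (spec$amplitude_cv > 0) {
        sdlog <- sqrt(log(1 + spec$amplitude_cv^2))
        stats::rlnorm(n, meanlog = log(spec$amplitude_V) - sdlog^2 / 2,
                      sdlog = sdlog)
      } else rep(spec$amplitude_V, n)
    } else numeric(0)
    out <- lick_events(times, "ground_truth")
    attr(out, "amplitudes_V") <- amps
    attr(out, "duration_s") <- spec$duration_s
    attr(out, "spec") <- spec
    out
  })
}

# Raised-cosine bump of unit peak and full width w, centered at 0.
raised_cosine <- function(t, w) {
  ifelse(abs(t) <= w / 2, 0.5 * (1 + cos(2 * pi * t / w)), 0)
}

#' Synthesize a strain-gauge trace from a lick train
#'
#' Each lick contributes one raised-cosine force transient (unimodal, compact
#' support, analytic peak at the lick time) riding on a baseline with
#' optional linear drift and Gaussian noise.
#'
#' @param licks [lick_events] (ground truth) or numeric times; per-lick peak
#'   amplitudes are taken from the `"amplitudes_V"` attribute when present.
#' @param kernel_width_s full width of the transient (s).
#' @param amplitude_V scalar or per-lick peak amplitudes; overrides the
#'   attribute when given.
#' @param noise a [noise_spec].
#' @param fs_hz sampling rate (must exceed `2 / kernel_width_s`).
#' @param duration_s trace span; defaults to the train's `duration_s`
#'   attribute, else last lick + 0.5 s.
#' @param seed integer seed for the noise draw.
#' @return an [sg_trace]; the ground-truth times are attached as attribute
#'   `"truth"`.
#' @export
gen_sg_trace <- function(licks, kernel_width_s = 0.12, amplitude_V = NULL,
                         noise = noise_spec(), fs_hz = 1000,
                         duration_s = NULL, seed = 1) {
  stopifnot(inherits(noise, "noise_spec"))
  check_scalar(kernel_width_s, "kernel_width_s", 0, strict_lower = TRUE)
  if (fs_hz <= 2 / kernel_width_s) {
    stop_param("`fs_hz` must exceed 2 / kernel_width_s to resolve the transient")
  }
  times <- as_lick_times(licks)
  n_licks <- length(times)
  amps <- amplitude_V
  if (is.null(amps)) amps <- attr(licks, "amplitudes_V")
  if (is.null(amps)) amps <- 0.3
  amps <- rep_len(amps, n_licks)
  if (is.null(duration_s)) {
    duration_s <- attr(licks, "duration_s")
    if (is.null(duration_s)) {
      duration_s <- if (n_licks) max(times) + 0.5 else 1
    }
  }
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  x <- noise$baseline_V + noise$drift_V_per_s * t
  if (noise$sigma_V > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, sd = noise$sigma_V))
  }
  half <- kernel_width_s / 2
  for (k in seq_len(n_licks)) {
    i0 <- max(1L, ceiling((times[k] - half) * fs_hz) + 1L)
    i1 <- min(n, floor((times[k] + half) * fs_hz) + 1L)
    if (i1 >= i0) {
      idx <- i0:i1
      x[idx] <- x[idx] + amps[k] * raised_cosine(t[idx] - times[k],
                                                 kernel_width_s)
    }
  }
  out <- sg_trace(x, fs_hz = fs_hz)
  attr(out, "truth") <- times
  out
}

#' Calcium indicator kernel
#'
#' Minimal difference-of-exponentials indicator model,
#' `h(t) = (exp(-t/decay) - exp(-t/rise))`, normalized to peak `peak_df`.
#'
#' @param rise_s rise time constant (s, > 0).
#' @param decay_s decay time constant (s, > rise_s).
#' @param peak_df transient peak in trace units.
#' @return object of class `calcium_kernel`.
#' @export
calcium_kernel <- function(rise_s = 0.07, decay_s = 0.5, peak_df = 1) {
  check_scalar(rise_s, "rise_s", 0, strict_lower = TRUE)
  check_scalar(decay_s, "decay_s", 0, strict_lower = TRUE)
  check_scalar(peak_df, "peak_df", 0, strict_lower = TRUE)
  if (decay_s <= rise_s) stop_param("`decay_s` must exceed `rise_s`")
  structure(list(rise_s = rise_s, decay_s = decay_s, peak_df = peak_df),
            class = "calcium_kernel")
}

#' Evaluate a calcium kernel at times since event onset
#'
#' @param kernel a [calcium_kernel].
#' @param t times since event onset (s); values before onset return 0.
#' @return numeric vector, peak equal to `kernel$peak_df`.
#' @export
eval_kernel <- function(kernel, t) {
  stopifnot(inherits(kernel, "calcium_kernel"))
  tpk <- with(kernel, rise_s * decay_s / (decay_s - rise_s) *
                log(decay_s / rise_s))
  hpk <- exp(-tpk / kernel$decay_s) - exp(-tpk / kernel$rise_s)
  h <- ifelse(t >= 0, exp(-t / kernel$decay_s) - exp(-t / kernel$rise_s), 0)
  kernel$peak_df * h / hpk
}

#' Generate event-locked synthetic calcium traces
#'
#' A fraction of units is "locked": each carries one kernel-shaped transient
#' per event of its assigned label; the remainder are pure noise. Labels are
#' assigned to locked units round-robin over the event labels, and the
#' ground-truth label per unit (`"unmodulated"` for noise units) is retained.
#'
#' @param events data.frame with columns `time_s` and `label`, or a named
#'   list of numeric time vectors.
#' @param kernel a [calcium_kernel].
#' @param locked_fraction fraction of units locked to events (in \[0, 1\]).
#' @param noise_sigma Gaussian noise SD added to every unit (>= 0).
#' @param frame_ts strictly increasing frame timestamps (s); must be
#'   non-empty.
#' @param n_units number of units.
#' @param seed integer seed.
#' @return a [calcium_traces] object; attribute `"truth_labels"` holds the
#'   per-unit ground-truth class labels.
#' @export
gen_calcium_traces <- function(events, kernel = calcium_kernel(),
                               locked_fraction = 0.3, noise_sigma = 0.1,
                               frame_ts, n_units = 50, seed = 1) {
  stopifnot(inherits(kernel, "calcium_kernel"))
  check_scalar(locked_fraction, "locked_fraction", 0, 1)
  check_scalar(noise_sigma, "noise_sigma", 0)
  if (missing(frame_ts) || !length(frame_ts)) {
    stop_param("`frame_ts` must be a non-empty timestamp vector")
  }
  if (is.unsorted(frame_ts, strictly = TRUE)) {
    stop_param("`frame_ts` must be strictly increasing")
  }
  if (is.list(events) && !is.data.frame(events)) {
    events <- data.frame(
      time_s = unlist(events, use.names = FALSE),
      label = rep(names(events), lengths(events))
    )
  }
  stopifnot(is.data.frame(events), all(c("time_s", "label") %in% names(events)))
  labels <- unique(as.character(events$label))
  n_frames <- length(frame_ts)
  n_locked <- round(locked_fraction * n_units)
  truth <- rep("unmodulated", n_units)
  if (n_locked > 0) {
    truth[seq_len(n_locked)] <- rep_len(labels, n_locked)
  }
  mat <- with_seed(seed, {
    m <- if (noise_sigma > 0) {
      matrix(stats::rnorm(n_units * n_frames, sd = noise_sigma),
             nrow = n_units)
    } else matrix(0, nrow = n_units, ncol = n_frames)
    cutoff <- 8 * kernel$decay_s
    for (u in seq_len(n_locked)) {
      ev <- events$time_s[as.character(events$label) == truth[u]]
      for (e in ev) {
        idx <- which(frame_ts >= e & frame_ts <= e + cutoff)
        if (length(idx)) {
          m[u, idx] <- m[u, idx] + eval_kernel(kernel, frame_ts[idx] - e)
        }
      }
    }
    m
  })
  out <- calcium_traces(mat, frame_ts,
                        unit_ids = sprintf("u%03d", seq_len(n_units)))
  attr(out, "truth_labels") <- truth
  out
}

#' Generate a frame clock with dropped frames
#'
#' Returns the nominal uniform timestamp grid with the listed frame indices
#' removed. Indices are 1-based (R convention) within `1..n_frames`.
#'
#' @param nominal_rate_hz nominal frame rate (Hz, > 0).
#' @param n_frames number of frames on the nominal grid (>= 1).
#' @param dropped_idx integer indices of dropped frames (1-based, unique).
#' @return numeric vector of surviving timestamps (s), starting at 0.
#' @export
gen_frame_clock <- function(nominal_rate_hz, n_frames, dropped_idx = integer(0)) {
  check_scalar(nominal_rate_hz, "nominal_rate_hz", 0, strict_lower = TRUE)
  check_scalar(n_frames, "n_frames", 1)
  dropped_idx <- as.integer(dropped_idx)
  if (length(dropped_idx)) {
    if (anyDuplicated(dropped_idx) ||
        any(dropped_idx < 1L | dropped_idx > n_frames)) {
      stop_param("`dropped_idx` must be unique indices within 1..n_frames")
    }
  }
  ts <- (seq_len(n_frames) - 1) / nominal_rate_hz
  if (length(dropped_idx)) ts <- ts[-dropped_idx]
  ts
}
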