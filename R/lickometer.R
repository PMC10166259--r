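#' Offline lick-detection parameters
#'
#' Defaults reproduce the published offline pipeline: the raw strain-gauge
#' signal is downsampled with an antialiasing low-pass to 1 kHz, low-pass
#' filtered at 64 Hz, and peaks are extracted with a minimal distance of
#' 60 ms, a minimal prominence of 0.015 (trace units, volts of the amplified
#' signal) and a minimal width of 50 ms at half prominence.
#'
#' @param target_fs_hz working sampling rate after downsampling (Hz).
#' @param lowpass_hz low-pass cutoff applied at the working rate (Hz);
#'   must be below `target_fs_hz / 2`.
#' @param min_distance_s minimal distance between reported peaks (s).
#' @param min_prominence minimal peak prominence (trace units).
#' @param min_width_s minimal peak width at half prominence (s).
#' @return object of class `offline_params`.
#' @export
offline_params <- function(target_fs_hz = 1000, lowpass_hz = 64,
                           min_distance_s = 0.060, min_prominence = 0.015,
                           min_width_s = 0.050) {
  check_scalar(target_fs_hz, "target_fs_hz", 0, strict_lower = TRUE)
  check_scalar(lowpass_hz, "lowpass_hz", 0, strict_lower = TRUE)
  check_scalar(min_distance_s, "min_distance_s", 0, strict_lower = TRUE)
  check_scalar(min_prominence, "min_prominence", 0, strict_lower = TRUE)
  check_scalar(min_width_s, "min_width_s", 0, strict_lower = TRUE)
  if (lowpass_hz >= target_fs_hz / 2) {
    stop_param("`lowpass_hz` must be below the working Nyquist frequency")
  }
  structure(list(target_fs_hz = target_fs_hz, lowpass_hz = lowpass_hz,
                 min_distance_s = min_distance_s,
                 min_prominence = min_prominence, min_width_s = min_width_s),
            class = "offline_params")
}

#' Online comparator parameters
#'
#' The online detector emulates the analog comparator that emits a TTL pulse
#' when the strain-gauge signal crosses a reference voltage set (by default)
#' 100 mV above the baseline. The baseline is the median of a leading window;
#' after an onset the comparator re-arms only once the signal falls below
#' baseline + `rearm_fraction * threshold` (hysteresis).
#'
#' @param threshold_V threshold above baseline, volts (default 0.100).
#' @param baseline_window_s leading window used to estimate baseline (s).
#' @param rearm_fraction hysteresis fraction of the threshold (in (0, 1]).
#' @return object of class `online_params`.
#' @export
online_params <- function(threshold_V = 0.100, baseline_window_s = 2,
                          rearm_fraction = 0.5) {
  check_scalar(threshold_V, "threshold_V", 0, strict_lower = TRUE)
  check_scalar(baseline_window_s, "baseline_window_s", 0, strict_lower = TRUE)
  check_scalar(rearm_fraction, "rearm_fraction", 0, 1, strict_lower = TRUE)
  structure(list(threshold_V = threshold_V,
                 baseline_window_s = baseline_window_s,
                 rearm_fraction = rearm_fraction),
            class = "online_params")
}

# Zero-phase IIR filtering with odd-reflection edge padding, so constant
# signals pass unchanged and peak locations are not displaced.
zero_phase_filter <- function(flt, x, fs_hz, cutoff_hz) {
  n <- length(x)
  if (n < 4L) return(x)
  p <- min(n - 1L, ceiling(8 * fs_hz / cutoff_hz))
  left <- 2 * x[1L] - x[seq(p + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - p)]
  y <- signal::filtfilt(flt, c(left, x, right))
  y[(p + 1L):(p + n)]
}

#' Preprocess a strain-gauge trace for offline detection
#'
#' Downsamples to the working rate through a zero-phase antialiasing
#' Butterworth low-pass, then applies a zero-phase 4th-order Butterworth
#' low-pass at `lowpass_hz`. Both stages are forward-backward filtered so
#' peak times are not shifted.
#'
#' @param trace an [sg_trace] with `fs_hz >= params$target_fs_hz`.
#' @param params an [offline_params].
#' @return an [sg_trace] at `target_fs_hz`.
#' @export
preprocess <- function(trace, params = offline_params()) {
  stopifnot(inherits(trace, "sg_trace"), inherits(params, "offline_params"))
  fs <- trace$fs_hz
  target <- params$target_fs_hz
  if (fs < target) {
    stop_param(sprintf("trace rate %g Hz is below the working rate %g Hz",
                       fs, target))
  }
  x <- trace$samples
  if (fs > target) {
    aa_cut <- 0.4 * target
    aa <- signal::butter(6, aa_cut / (fs / 2), type = "low")
    x <- zero_phase_filter(aa, x, fs, aa_cut)
    ratio <- fs / target
    if (abs(ratio - round(ratio)) < 1e-9) {
      x <- x[seq(1L, length(x), by = round(ratio))]
    } else {
      t_old <- (seq_along(x) - 1) / fs
      t_new <- seq(0, t_old[length(t_old)], by = 1 / target)
      x <- stats::approx(t_old, x, xout = t_new)$y
    }
  }
  lp <- signal::butter(4, params$lowpass_hz / (target / 2), type = "low")
  x <- zero_phase_filter(lp, x, target, params$lowpass_hz)
  sg_trace(x, fs_hz = target, t0_s = trace$t0_s, units = trace$units,
           channel = trace$channel)
}

#' Detect licks offline from a strain-gauge trace
#'
#' Applies [preprocess()] when the trace is not already at the working rate,
#' then extracts peaks subject to the minimal-distance (60 ms), minimal
#' prominence (0.015) and minimal width (50 ms) constraints. When two peaks
#' violate the distance rule the taller one is retained.
#'
#' @inheritParams preprocess
#' @return a [lick_events] with source `"sg_offline"`; the peak table
#'   (index, height, prominence, width) is attached as attribute `"peaks"`.
#' @export
detect_licks_offline <- function(trace, params = offline_params()) {
  stopifnot(inherits(trace, "sg_trace"), inherits(params, "offline_params"))
  if (!length(trace$samples)) return(lick_events(numeric(0), "sg_offline"))
  if (trace$fs_hz != params$target_fs_hz) trace <- preprocess(trace, params)
  pk <- find_peaks(trace$samples, trace$fs_hz,
                   min_distance_s = params$min_distance_s,
                   min_prominence = params$min_prominence,
                   min_width_s = params$min_width_s)
  out <- lick_events(trace$t0_s + (pk$index - 1) / trace$fs_hz, "sg_offline")
  attr(out, "peaks") <- pk
  out
}

#' Emulate the online comparator detector
#'
#' One TTL onset is emitted per upward crossing of baseline + threshold; the
#' comparator then stays quiet until the signal falls below
#' baseline + `rearm_fraction * threshold`. The baseline is the median of
#' the leading `baseline_window_s` of the trace.
#'
#' @param trace an [sg_trace] (raw or preprocessed).
#' @param params an [online_params].
#' @return a [lick_events] with source `"sg_online"`; attributes `baseline_V`
#'   and `threshold_V` record the operating point.
#' @export
emulate_online_comparator <- function(trace, params = online_params()) {
  stopifnot(inherits(trace, "sg_trace"), inherits(params, "online_params"))
  x <- trace$samples
  n <- length(x)
  if (!n) return(lick_events(numeric(0), "sg_online"))
  nb <- max(1L, min(n, round(params$baseline_window_s * trace$fs_hz)))
  baseline <- stats::median(x[seq_len(nb)])
  thr <- baseline + params$threshold_V
  rearm <- baseline + params$rearm_fraction * params$threshold_V
  above <- x >= thr
  ups <- which(c(above[1L], diff(above) == 1) > 0)
  if (above[1L]) ups <- unique(c(1L, ups))
  below_cum <- cumsum(x < rearm)
  onsets <- integer(0)
  last <- 0L
  for (u in ups) {
    if (last == 0L) {
      onsets <- c(onsets, u); last <- u
    } else if (u > last + 1L && (below_cum[u - 1L] - below_cum[last]) > 0) {
      onsets <- c(onsets, u); last <- u
    }
  }
  out <- lick_events(trace$t0_s + (onsets - 1) / trace$fs_hz, "sg_online")
  attr(out, "baseline_V") <- baseline
  attr(out, "threshold_V") <- params$threshold_V
  out
}

#' Match detected licks to ground truth
#'
#' Greedy one-to-one matching by ascending absolute time difference, ties
#' broken toward the earlier truth event. A detected lick is a true positive
#' when its matched truth event lies strictly within `tolerance_s` (default
#' 60 ms, the minimal interlick interval used by the offline detector).
#'
#' @param detected,truth [lick_events] or numeric time vectors (s).
#' @param tolerance_s matching tolerance in seconds (>= 0).
#' @return object of class `lick_match`: list with counts `tp`, `fp`, `fn`,
#'   a data.frame `pairs` (`detected`, `truth`, `dt`) and `tolerance_s`.
#' @export
match_licks <- function(detected, truth, tolerance_s = 0.060) {
  if (!is_scalar_num(tolerance_s) || tolerance_s < 0) {
    stop_param("`tolerance_s` must be a non-negative number")
  }
  d <- as_lick_times(detected)
  tt <- as_lick_times(truth)
  pairs <- data.frame(detected = numeric(0), truth = numeric(0),
                      dt = numeric(0))
  if (length(d) && length(tt)) {
    lo <- findInterval(d - tolerance_s, tt) + 1L
    hi <- findInterval(d + tolerance_s, tt)
    cand_i <- rep.int(seq_along(d), pmax(0L, hi - lo + 1L))
    cand_j <- unlist(lapply(seq_along(d), function(i) {
      if (hi[i] >= lo[i]) seq.int(lo[i], hi[i]) else integer(0)
    }), use.names = FALSE)
    if (length(cand_i)) {
      dt <- abs(d[cand_i] - tt[cand_j])
      ok <- dt < tolerance_s
      cand_i <- cand_i[ok]; cand_j <- cand_j[ok]; dt <- dt[ok]
      ord <- order(dt, tt[cand_j])
      used_d <- logical(length(d)); used_t <- logical(length(tt))
      sel <- integer(0)
      for (k in ord) {
        if (!used_d[cand_i[k]] && !used_t[cand_j[k]]) {
          used_d[cand_i[k]] <- TRUE
          used_t[cand_j[k]] <- TRUE
          sel <- c(sel, k)
        }
      }
      if (length(sel)) {
        sel <- sel[order(d[cand_i[sel]])]
        pairs <- data.frame(detected = d[cand_i[sel]], truth = tt[cand_j[sel]],
                            dt = dt[sel])
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = length(d) - tp, fn = length(tt) - tp,
                 pairs = pairs, tolerance_s = tolerance_s,
                 n_detected = length(d), n_truth = length(tt)),
            class = "lick_match")
}

#' @export
print.lick_match <- function(x, ...) {
  cat(sprintf("<lick_match> tp=%d fp=%d fn=%d (tolerance %g ms)\n",
              x$tp, x$fp, x$fn, 1000 * x$tolerance_s))
  invisible(x)
}

#' Sensitivity and positive predictive value of a match
#'
#' Sensitivity = TP / (TP + FN); PPV = TP / (TP + FP). Either quantity is
#' `NA` (an explicit undefined sentinel, never a silent 0) when its
#' denominator is zero.
#'
#' @param m a `lick_match` from [match_licks()].
#' @return list with numeric elements `sensitivity` and `ppv`.
#' @export
confusion_metrics <- function(m) {
  stopifnot(inherits(m, "lick_match"))
  sens <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
  ppv  <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_
  list(sensitivity = sens, ppv = ppv)
}

#' Sweep the online comparator threshold
#'
#' Runs the comparator at each threshold, matches its onsets to ground truth
#' and reports sensitivity and PPV per threshold — the desk-scale analogue of
#' artificially lowering the reference voltage to study its effect on the
#' detector's operating point.
#'
#' @param trace an [sg_trace].
#' @param truth ground-truth [lick_events] or numeric times.
#' @param thresholds_V numeric vector of thresholds above baseline (V, > 0).
#' @param params base [online_params]; its threshold is replaced per row.
#' @param tolerance_s matching tolerance (s).
#' @return data.frame with one row per threshold: `threshold_V`,
#'   `n_detected`, `tp`, `fp`, `fn`, `sensitivity`, `ppv`.
#' @export
threshold_sweep <- function(trace, truth, thresholds_V,
                            params = online_params(), tolerance_s = 0.060) {
  if (!length(thresholds_V)) {
    return(data.frame(threshold_V = numeric(0), n_detected = integer(0),
                      tp = integer(0), fp = integer(0), fn = integer(0),
                      sensitivity = numeric(0), ppv = numeric(0)))
  }
  if (any(thresholds_V <= 0)) stop_param("thresholds must be positive")
  rows <- lapply(thresholds_V, function(th) {
    p <- params; p$threshold_V <- th
    det <- emulate_online_comparator(trace, p)
    m <- match_licks(det, truth, tolerance_s)
    met <- confusion_metrics(m)
    data.frame(threshold_V = th, n_detected = length(det$times_s),
               tp = m$tp, fp = m$fp, fn = m$fn,
               sensitivity = met$sensitivity, ppv = met$ppv)
  })
  do.call(rbind, rows)
}

#' Interlick intervals and their histogram
#'
#' @param licks [lick_events] or numeric times.
#' @param bin_s histogram bin width (s).
#' @return list with `intervals_s` (successive differences), `histogram`
#'   (a `hist()` object, `NULL` when fewer than 2 events) and `mode_s`
#'   (midpoint of the most populated bin, `NA` when undefined).
#' @export
interlick_intervals <- function(licks, bin_s = 0.02) {
  times <- as_lick_times(licks)
  if (length(times) < 2L) {
    return(list(intervals_s = numeric(0), histogram = NULL, mode_s = NA_real_))
  }
  iv <- diff(times)
  brk <- seq(0, max(iv) + bin_s, by = bin_s)
  h <- graphics::hist(iv, breaks = brk, plot = FALSE)
  list(intervals_s = iv, histogram = h,
       mode_s = h$mids[which.max(h$counts)])
}
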