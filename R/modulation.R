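#' Denoised calcium trace set
#'
#' Units x frames matrix of denoised temporal traces (as produced upstream by
#' a source-extraction algorithm) together with the recorded frame
#' timestamps.
#'
#' @param mat numeric matrix, units in rows, frames in columns.
#' @param frame_ts strictly increasing frame timestamps (s), one per column.
#' @param unit_ids character unit identifiers (default `u001`, ...).
#' @return object of class `calcium_traces`.
#' @export
calcium_traces <- function(mat, frame_ts, unit_ids = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop_param("`mat` must be a numeric matrix (units x frames)")
  }
  if (ncol(mat) != length(frame_ts)) {
    stop_param("matrix column count must equal the number of frame timestamps")
  }
  if (is.unsorted(frame_ts, strictly = TRUE)) {
    stop_param("`frame_ts` must be strictly increasing")
  }
  if (is.null(unit_ids)) unit_ids <- sprintf("u%03d", seq_len(nrow(mat)))
  stopifnot(length(unit_ids) == nrow(mat))
  rownames(mat) <- unit_ids
  structure(list(mat = mat, frame_ts = as.numeric(frame_ts),
                 unit_ids = as.character(unit_ids)),
            class = "calcium_traces")
}

#' @export
print.calcium_traces <- function(x, ...) {
  cat(sprintf("<calcium_traces> %d units x %d frames (%.1f s @ ~%.1f Hz)\n",
              nrow(x$mat), ncol(x$mat), diff(range(x$frame_ts)),
              1 / stats::median(diff(x$frame_ts))))
  invisible(x)
}

#' Align behavioral events to imaging frames
#'
#' Each event maps to the recorded frame whose timestamp is closest; an event
#' equidistant between two frames maps to the earlier one. Events outside
#' the recorded frame span are flagged.
#'
#' @param event_ts numeric event times (s).
#' @param frame_ts strictly increasing frame timestamps (s), non-empty.
#' @return data.frame with columns `event_time_s`, `frame` (1-based index),
#'   `frame_time_s`, `outside`.
#' @export
align_events_to_frames <- function(event_ts, frame_ts) {
  if (!length(frame_ts)) stop_param("`frame_ts` must be non-empty")
  if (is.unsorted(frame_ts, strictly = TRUE)) {
    stop_param("`frame_ts` must be strictly increasing")
  }
  n <- length(frame_ts)
  idx <- findInterval(event_ts, frame_ts)
  lower <- pmax(idx, 1L)
  upper <- pmin(idx + 1L, n)
  d_lo <- abs(event_ts - frame_ts[lower])
  d_hi <- abs(frame_ts[upper] - event_ts)
  frame <- ifelse(idx < 1L, 1L, ifelse(d_lo <= d_hi, lower, upper))
  data.frame(event_time_s = as.numeric(event_ts), frame = as.integer(frame),
             frame_time_s = frame_ts[frame],
             outside = event_ts < frame_ts[1L] | event_ts > frame_ts[n])
}

#' MAD-normalize a trace
#'
#' Robust per-unit z-score: `(x - median(x)) / MAD(x)` with the raw median
#' absolute deviation (no consistency constant). A constant trace (MAD = 0)
#' raises a degenerate-trace error; such units are excluded upstream rather
#' than imputed. The result is invariant under positive affine transforms of
#' the raw trace.
#'
#' @param x numeric vector, length >= 2.
#' @return normalized numeric vector in MAD units.
#' @export
mad_normalize <- function(x) {
  if (length(x) < 2L) stop_param("trace must have at least 2 samples")
  med <- stats::median(x)
  m <- stats::median(abs(x - med))
  if (m == 0) {
    lb_stop("degenerate trace: MAD is zero", "lickbox_degenerate_error")
  }
  (x - med) / m
}

#' Event-triggered average of MAD-normalized traces
#'
#' Each unit's trace is MAD-normalized over the whole recording, segments of
#' `pre_frames` before to `post_frames` after each event frame are cut out,
#' and averaged across events. Events whose window exceeds the recording are
#' skipped and counted; units with zero MAD are excluded and reported.
#'
#' @param traces a [calcium_traces].
#' @param event_frames integer frame indices of the events (1-based).
#' @param pre_frames,post_frames window extent in frames (>= 0).
#' @return object of class `event_avg`: list with `average` (kept units x
#'   window matrix, MAD units), `lag_frames`, `n_events_used`,
#'   `n_events_skipped`, `excluded_units`.
#' @export
event_triggered_average <- function(traces, event_frames, pre_frames,
                                    post_frames) {
  stopifnot(inherits(traces, "calcium_traces"))
  check_scalar(pre_frames, "pre_frames", 0)
  check_scalar(post_frames, "post_frames", 0)
  n_frames <- ncol(traces$mat)
  ev <- as.integer(event_frames)
  usable <- ev - pre_frames >= 1L & ev + post_frames <= n_frames
  if (!any(usable)) {
    stop_data("no event window fits inside the recording")
  }
  ev_use <- ev[usable]
  lag <- seq.int(-pre_frames, post_frames)
  excluded <- character(0)
  rows <- list()
  for (u in seq_len(nrow(traces$mat))) {
    z <- tryCatch(mad_normalize(traces$mat[u, ]),
                  lickbox_degenerate_error = function(e) NULL)
    if (is.null(z)) {
      excluded <- c(excluded, traces$unit_ids[u])
      next
    }
    seg <- vapply(ev_use, function(f) z[f + lag], numeric(length(lag)))
    rows[[traces$unit_ids[u]]] <- rowMeans(seg)
  }
  avg <- do.call(rbind, rows)
  structure(list(average = avg, lag_frames = lag,
                 n_events_used = length(ev_use),
                 n_events_skipped = sum(!usable),
                 excluded_units = excluded),
            class = "event_avg")
}

#' Extract the modulation alignment events from a session log
#'
#' Initiation-class units are aligned to nose pokes (walking-delay period),
#' licking-class units to head entries (licking-response period), and
#' postlick-class units to water deliveries (reward-anticipation / reward
#' period).
#'
#' @param log a [run_session()] session log.
#' @return named list of event-time vectors: `initiation`, `licking`,
#'   `postlick`; alignments with no events are dropped.
#' @export
event_times_from_log <- function(log) {
  stopifnot(inherits(log, "lickbox_session"))
  tr <- log$trials
  ev <- list(initiation = tr$t_nose_poke[!is.na(tr$t_nose_poke)],
             licking = tr$t_head_entry[!is.na(tr$t_head_entry)],
             postlick = tr$t_reward[!is.na(tr$t_reward)])
  ev[lengths(ev) > 0]
}

#' Call and classify event-modulated units
#'
#' For each of the three alignments (nose poke / head entry / reward) the
#' MAD-normalized event-triggered average is computed; a unit is "modulated"
#' when the peak of any alignment's average reaches `threshold` (3x MAD by
#' default), and its class — initiation, licking or postlick — is the
#' alignment carrying the maximal peak. Alignments missing from `events`
#' are skipped and noted in attribute `"skipped_alignments"`.
#'
#' @param traces a [calcium_traces].
#' @param events a session log, or a named list of event-time vectors with
#'   any of `initiation`, `licking`, `postlick` (see
#'   [event_times_from_log()]).
#' @param threshold modulation threshold in MAD units (default 3).
#' @param pre_s,post_s averaging window around each event (s).
#' @return object of class `modulation_result`: data.frame with one row per
#'   unit: `unit`, `peak_mad`, `peak_alignment`, `class` (one of
#'   `initiation`, `licking`, `postlick`, `unmodulated`, or `excluded` for
#'   zero-MAD units), plus one `peak_<alignment>` column per alignment.
#' @export
classify_modulation <- function(traces, events, threshold = 3.0,
                                pre_s = 1.0, post_s = 2.0) {
  stopifnot(inherits(traces, "calcium_traces"))
  check_scalar(threshold, "threshold", 0, strict_lower = TRUE)
  if (inherits(events, "lickbox_session")) {
    events <- event_times_from_log(events)
  }
  stopifnot(is.list(events), length(events) > 0, !is.null(names(events)))
  alignments <- intersect(c("initiation", "licking", "postlick"),
                          names(events))
  if (!length(alignments)) {
    stop_param("`events` must name at least one of initiation/licking/postlick")
  }
  frame_period <- stats::median(diff(traces$frame_ts))
  pre_f <- round(pre_s / frame_period)
  post_f <- round(post_s / frame_period)
  skipped <- character(0)
  peaks <- list()
  excluded <- character(0)
  for (al in alignments) {
    ev_t <- events[[al]]
    map <- align_events_to_frames(ev_t, traces$frame_ts)
    frames <- map$frame[!map$outside]
    eta <- tryCatch(
      event_triggered_average(traces, frames, pre_f, post_f),
      lickbox_data_error = function(e) NULL
    )
    if (is.null(eta)) {
      skipped <- c(skipped, al)
      next
    }
    pk <- apply(eta$average, 1, max)
    peaks[[al]] <- pk[traces$unit_ids] # NA for excluded units
    names(peaks[[al]]) <- traces$unit_ids
    excluded <- union(excluded, eta$excluded_units)
  }
  if (!length(peaks)) stop_data("no alignment could be computed")
  pk_mat <- do.call(cbind, peaks)
  best <- apply(pk_mat, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
  peak_val <- pk_mat[cbind(seq_len(nrow(pk_mat)),
                           ifelse(is.na(best), 1L, best))]
  peak_val[is.na(best)] <- NA_real_
  cls <- ifelse(is.na(best), "excluded",
                ifelse(peak_val >= threshold, colnames(pk_mat)[best],
                       "unmodulated"))
  out <- data.frame(unit = traces$unit_ids, peak_mad = peak_val,
                    peak_alignment = ifelse(is.na(best), NA_character_,
                                            colnames(pk_mat)[best]),
                    class = cls, stringsAsFactors = FALSE)
  for (al in colnames(pk_mat)) out[[paste0("peak_", al)]] <- pk_mat[, al]
  structure(out, threshold = threshold,
            skipped_alignments = skipped,
            class = c("modulation_result", "data.frame"))
}

#' Split event-aligned trace segments by trial outcome
#'
#' Cuts one window per trial around the alignment event (head entry by
#' default) and groups the segments by trial outcome. Each usable trial is
#' assigned to exactly one outcome group.
#'
#' @param traces a [calcium_traces].
#' @param log a [run_session()] session log with outcome labels.
#' @param align trial event to align on: `"head_entry"`, `"nose_poke"`,
#'   `"cue"`, or `"reward"`.
#' @param pre_s,post_s window extent (s).
#' @return list with one element per outcome (`hit`, `error`, `miss`), each
#'   an array trials x time x units of MAD-normalized segments (groups with
#'   no usable trials are `NULL`); attribute `"lag_s"` gives the time axis.
#' @export
split_by_trial_type <- function(traces, log, align = "head_entry",
                                pre_s = 1.0, post_s = 2.0) {
  stopifnot(inherits(traces, "calcium_traces"),
            inherits(log, "lickbox_session"))
  align <- match.arg(align, c("head_entry", "nose_poke", "cue", "reward"))
  col <- c(head_entry = "t_head_entry", nose_poke = "t_nose_poke",
           cue = "t_cue", reward = "t_reward")[[align]]
  tr <- log$trials
  frame_period <- stats::median(diff(traces$frame_ts))
  pre_f <- round(pre_s / frame_period)
  post_f <- round(post_s / frame_period)
  n_frames <- ncol(traces$mat)
  zmat <- matrix(NA_real_, nrow(traces$mat), n_frames)
  for (u in seq_len(nrow(traces$mat))) {
    z <- tryCatch(mad_normalize(traces$mat[u, ]),
                  lickbox_degenerate_error = function(e) rep(NA_real_, n_frames))
    zmat[u, ] <- z
  }
  lag <- seq.int(-pre_f, post_f)
  out <- list(hit = NULL, error = NULL, miss = NULL)
  for (oc in names(out)) {
    rows_oc <- which(tr$outcome == oc & !is.na(tr[[col]]))
    if (!length(rows_oc)) next
    map <- align_events_to_frames(tr[[col]][rows_oc], traces$frame_ts)
    ok <- !map$outside & map$frame - pre_f >= 1L & map$frame + post_f <= n_frames
    if (!any(ok)) next
    frames <- map$frame[ok]
    arr <- array(NA_real_, dim = c(length(frames), length(lag),
                                   nrow(traces$mat)),
                 dimnames = list(NULL, NULL, traces$unit_ids))
    for (k in seq_along(frames)) {
      arr[k, , ] <- t(zmat[, frames[k] + lag, drop = FALSE])
    }
    out[[oc]] <- arr
  }
  structure(out, lag_s = lag * frame_period, align = align)
}

#' Percentage of lost imaging frames
#'
#' Gaps in the recorded frame clock are converted to lost-frame counts by
#' rounding each gap to the nearest integer multiple of the nominal frame
#' period: a gap of `k` periods contributes `k - 1` lost frames. The loss
#' percentage is `100 * lost / (observed + lost)`.
#'
#' @param frame_ts strictly increasing recorded frame timestamps (s), >= 2.
#' @param nominal_rate_hz nominal frame rate (Hz, > 0).
#' @return loss percentage (numeric scalar); attribute `"lost_frames"`
#'   carries the count.
#' @export
compute_frame_loss <- function(frame_ts, nominal_rate_hz) {
  check_scalar(nominal_rate_hz, "nominal_rate_hz", 0, strict_lower = TRUE)
  if (length(frame_ts) < 2L) stop_param("need at least 2 frame timestamps")
  if (is.unsorted(frame_ts, strictly = TRUE)) {
    stop_data("frame timestamps must be strictly increasing")
  }
  period <- 1 / nominal_rate_hz
  gaps <- diff(frame_ts)
  lost <- sum(pmax(0, round(gaps / period) - 1))
  pct <- 100 * lost / (length(frame_ts) + lost)
  structure(pct, lost_frames = lost)
}
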