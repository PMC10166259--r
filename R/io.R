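# Plain-format I/O: raw little-endian float32 sample files with JSON
# sidecars for traces and trace matrices, CSV event tables, and the session
# log directory layout (events.csv + summary.json).

#' Write / read a strain-gauge trace
#'
#' Samples are stored as raw little-endian 32-bit floats; the JSON sidecar
#' records `sampling_rate_hz`, `units`, `t0_s`, `channel` and `n_samples`.
#'
#' @param trace an [sg_trace].
#' @param f32_path path of the raw sample file.
#' @param meta_path path of the JSON sidecar (default: `f32_path` with a
#'   `.json` extension appended).
#' @return `write_sg_trace()` returns `f32_path` invisibly;
#'   `read_sg_trace()` returns an [sg_trace].
#' @export
write_sg_trace <- function(trace, f32_path, meta_path = paste0(f32_path, ".json")) {
  stopifnot(inherits(trace, "sg_trace"))
  con <- file(f32_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$samples), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(sampling_rate_hz = trace$fs_hz, units = trace$units,
         t0_s = trace$t0_s, channel = trace$channel,
         n_samples = length(trace$samples)),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(f32_path)
}

#' @rdname write_sg_trace
#' @export
read_sg_trace <- function(f32_path, meta_path = paste0(f32_path, ".json")) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- as.integer(meta$n_samples)
  con <- file(f32_path, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  if (length(x) != n) stop_data("sample file shorter than sidecar declares")
  sg_trace(x, fs_hz = meta$sampling_rate_hz, t0_s = meta$t0_s,
           units = meta$units %||% "V", channel = meta$channel %||% "sg")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read lick event tables
#'
#' Event tables are CSV with header `time_s,label`; bare ground-truth tables
#' (single `time_s` column) are also accepted on read.
#'
#' @param licks a [lick_events] or numeric times.
#' @param path CSV path.
#' @param source source label applied on read when the file has no labels.
#' @return `read_lick_events()` returns a [lick_events].
#' @export
write_lick_events <- function(licks, path) {
  times <- as_lick_times(licks)
  label <- if (inherits(licks, "lick_events")) licks$source else "unknown"
  utils::write.csv(data.frame(time_s = times, label = label),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lick_events
#' @export
read_lick_events <- function(path, source = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) stop_data("event table lacks a `time_s` column")
  src <- source %||% (if ("label" %in% names(df) && nrow(df)) df$label[1] else "unknown")
  lick_events(df$time_s, src)
}

#' Write / read a calcium trace matrix
#'
#' The matrix is stored row-major (unit by unit) as raw little-endian
#' float32; the JSON sidecar names dimensions, unit ids and the frame
#' timestamp CSV (`frame,time_s`).
#'
#' @param traces a [calcium_traces].
#' @param f32_path raw sample file path.
#' @param meta_path JSON sidecar path.
#' @param frames_path frame-timestamp CSV path.
#' @return `read_calcium_traces()` returns a [calcium_traces].
#' @export
write_calcium_traces <- function(traces, f32_path,
                                 meta_path = paste0(f32_path, ".json"),
                                 frames_path = paste0(f32_path, ".frames.csv")) {
  stopifnot(inherits(traces, "calcium_traces"))
  con <- file(f32_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(traces$mat)), con, size = 4L, endian = "little")
  utils::write.csv(data.frame(frame = seq_along(traces$frame_ts),
                              time_s = traces$frame_ts),
                   frames_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_units = nrow(traces$mat), n_frames = ncol(traces$mat),
         unit_ids = traces$unit_ids,
         frame_timestamps_file = basename(frames_path)),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(f32_path)
}

#' @rdname write_calcium_traces
#' @export
read_calcium_traces <- function(f32_path,
                                meta_path = paste0(f32_path, ".json"),
                                frames_path = NULL) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(frames_path)) {
    frames_path <- file.path(dirname(f32_path), meta$frame_timestamps_file)
  }
  frames <- utils::read.csv(frames_path)
  n_units <- as.integer(meta$n_units)
  n_frames <- as.integer(meta$n_frames)
  con <- file(f32_path, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n_units * n_frames, size = 4L,
               endian = "little")
  if (length(x) != n_units * n_frames) {
    stop_data("sample file shorter than sidecar declares")
  }
  calcium_traces(matrix(x, nrow = n_units, byrow = TRUE),
                 frames$time_s, unit_ids = meta$unit_ids)
}

#' Write / read a session log directory
#'
#' A session is serialized as `events.csv` (the [export_ttl_map()] long
#' table, times at ms precision) and `summary.json` (config, per-trial
#' outcome table, reversal indices, seed).
#'
#' @param log a [run_session()] session log.
#' @param dir output directory (created if needed).
#' @return `read_session_log()` returns a `lickbox_session` rebuilt from the
#'   two files (trial table restored at ms precision).
#' @export
write_session_log <- function(log, dir) {
  stopifnot(inherits(log, "lickbox_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- export_ttl_map(log)
  ev$time_s <- round(ev$time_s, 3)
  utils::write.csv(ev, file.path(dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  tr <- log$trials
  num <- vapply(tr, is.numeric, logical(1))
  tr[num] <- lapply(tr[num], function(x) round(x, 3))
  jsonlite::write_json(
    list(config = unclass(log$config), trials = tr,
         reversal_trials = log$reversal_trials, seed = log$seed,
         agent_kind = log$agent_kind),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(dir) {
  s <- jsonlite::read_json(file.path(dir, "summary.json"),
                           simplifyVector = TRUE)
  cfg <- s$config
  config <- task_config(
    n_blocks = cfg$n_blocks, block_min_len = cfg$block_min_len,
    criterion = cfg$criterion, criterion_window = cfg$criterion_window,
    lr_duration_s = cfg$lr_duration_s, ra_duration_s = cfg$ra_duration_s,
    post_reward_s = cfg$post_reward_s, reward_prob = cfg$reward_prob,
    first_rewarded_spout = cfg$first_rewarded_spout,
    immediate_feedback = cfg$immediate_feedback, stage = cfg$stage,
    seed = cfg$seed)
  trials <- as.data.frame(s$trials)
  structure(list(config = config, trials = trials,
                 reversal_trials = as.integer(s$reversal_trials),
                 seed = as.integer(s$seed), agent_kind = s$agent_kind),
            class = "lickbox_session")
}
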