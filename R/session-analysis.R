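#' Moving-average block performance
#'
#' The performance at trial `t` of a block is the hit fraction over the
#' trailing `min(t, window)` trials, i.e. a 5-trial moving average by
#' default, with partial windows at the block start (plotting convention).
#' Misses count as non-hits.
#'
#' @param outcomes character vector of `"hit"`/`"error"`/`"miss"` (or a
#'   logical hit vector) for one block, in trial order.
#' @param window moving-average length in trials (>= 1).
#' @return object of class `performance_curve`: data.frame with columns
#'   `trial` and `hit_fraction`; the window length is attribute `"window"`.
#' @export
block_performance <- function(outcomes, window = 5) {
  check_scalar(window, "window", 1)
  hits <- outcomes_to_hits(outcomes)
  n <- length(hits)
  if (!n) {
    out <- data.frame(trial = integer(0), hit_fraction = numeric(0))
  } else {
    cs <- cumsum(hits)
    t <- seq_len(n)
    lo <- pmax(0L, t - as.integer(window))
    out <- data.frame(trial = t,
                      hit_fraction = (cs - c(0, cs)[lo + 1L]) / (t - lo))
  }
  structure(out, window = as.integer(window),
            class = c("performance_curve", "data.frame"))
}

outcomes_to_hits <- function(outcomes) {
  if (is.logical(outcomes)) return(outcomes)
  if (is.character(outcomes) || is.factor(outcomes)) {
    return(as.character(outcomes) == "hit")
  }
  stop_param("`outcomes` must be a character/factor outcome vector or logical")
}

#' @export
plot.performance_curve <- function(x, ...) {
  plot(x$trial, x$hit_fraction, type = "s", ylim = c(0, 1),
       xlab = "trial in block", ylab = "hit fraction", ...)
  invisible(x)
}

#' Trials to reach the learning criterion
#'
#' Smallest trial index `t` at which a full `window`-trial trailing window
#' has hit fraction at or above `criterion` (70% correct licking over five
#' trials by default). Unlike the displayed performance curve, a full window
#' is required.
#'
#' @inheritParams block_performance
#' @param criterion required hit fraction (0, 1].
#' @return integer trial index, or `NA` when the criterion is never reached.
#' @export
trials_to_criterion <- function(outcomes, criterion = 0.70, window = 5) {
  check_scalar(criterion, "criterion", 0, 1, strict_lower = TRUE)
  check_scalar(window, "window", 1)
  hits <- outcomes_to_hits(outcomes)
  n <- length(hits)
  window <- as.integer(window)
  if (n < window) return(NA_integer_)
  cs <- cumsum(hits)
  frac <- (cs[window:n] - c(0, cs)[seq.int(1L, n - window + 1L)]) / window
  hit_at <- which(frac >= criterion)
  if (!length(hit_at)) NA_integer_ else hit_at[1L] + window - 1L
}

#' Per-block reversal summary of a session
#'
#' @param log a [run_session()] session log.
#' @param criterion,window learning-criterion parameters passed to
#'   [trials_to_criterion()].
#' @return data.frame with one row per block entered: `block`,
#'   `rewarded_spout`, `length`, `trials_to_criterion`, `n_hit`, `n_error`,
#'   `n_miss`. Counts sum to the block length.
#' @export
reversal_summary <- function(log, criterion = 0.70, window = 5) {
  stopifnot(inherits(log, "lickbox_session"))
  tr <- log$trials
  if (!nrow(tr)) {
    return(data.frame(block = integer(0), rewarded_spout = character(0),
                      length = integer(0), trials_to_criterion = integer(0),
                      n_hit = integer(0), n_error = integer(0),
                      n_miss = integer(0)))
  }
  rows <- lapply(sort(unique(tr$block)), function(b) {
    oc <- tr$outcome[tr$block == b]
    data.frame(
      block = b,
      rewarded_spout = tr$rewarded_spout[tr$block == b][1L],
      length = length(oc),
      trials_to_criterion = trials_to_criterion(oc, criterion, window),
      n_hit = sum(oc == "hit"),
      n_error = sum(oc == "error"),
      n_miss = sum(oc == "miss"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
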