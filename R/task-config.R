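#' Configuration of the directional-licking task
#'
#' Defaults reproduce the final-stage serial reversal-learning paradigm: a
#' contingency block lasts at least 15 trials (`block_min_len`) and reverses
#' once the hit fraction over a 15-trial sliding window (`criterion_window`)
#' reaches 70% (`criterion`); the licking-response (LR) period lasts 2 s, hit
#' trials are followed by a 1 s reward-anticipation (RA) period before water
#' delivery and a 4 s post-reward interval; errors and misses close the gate
#' at cue time. Training-stage variants are expressed as flags:
#'
#' * stage 1 — gate always open, single spout, cue + reward immediately at
#'   the first lick (no LR/RA structure); error outcomes cannot occur.
#' * stage 2 — single spout with the LR and RA periods.
#' * stage 3 — nose poke required to open the gate; still single spout.
#' * stage 4 — both spouts (discriminative learning) with immediate white
#'   noise feedback on a wrong lick.
#' * stage 5 / `"final"` — full paradigm, delayed feedback at LR end.
#'
#' @param n_blocks number of contingency blocks (>= 1); a session contains at
#'   most `n_blocks - 1` reversals. Serial reversal = `n_blocks > 2`.
#' @param block_min_len minimum trials in a block before a reversal may fire.
#' @param criterion hit fraction required over the sliding window (0, 1].
#' @param criterion_window sliding window length (trials).
#' @param lr_duration_s licking-response period (s).
#' @param ra_duration_s reward-anticipation period (s).
#' @param post_reward_s post-reward interval (s).
#' @param reward_prob probability that a hit is rewarded with water
#'   (probabilistic reversal learning when < 1).
#' @param first_rewarded_spout `"left"` or `"right"`.
#' @param immediate_feedback play the error cue at the wrong lick instead of
#'   at LR end.
#' @param stage training stage: 1 to 5 or `"final"`.
#' @param seed integer seed for the engine's reward stream.
#' @return object of class `task_config`.
#' @export
task_config <- function(n_blocks = 2, block_min_len = 15, criterion = 0.70,
                        criterion_window = 15, lr_duration_s = 2.0,
                        ra_duration_s = 1.0, post_reward_s = 4.0,
                        reward_prob = 1.0,
                        first_rewarded_spout = c("left", "right"),
                        immediate_feedback = NULL, stage = "final",
                        seed = 1) {
  check_scalar(n_blocks, "n_blocks", 1)
  check_scalar(block_min_len, "block_min_len", 1)
  check_scalar(criterion, "criterion", 0, 1, strict_lower = TRUE)
  check_scalar(criterion_window, "criterion_window", 1)
  check_scalar(lr_duration_s, "lr_duration_s", 0, strict_lower = TRUE)
  check_scalar(ra_duration_s, "ra_duration_s", 0, strict_lower = TRUE)
  check_scalar(post_reward_s, "post_reward_s", 0, strict_lower = TRUE)
  check_scalar(reward_prob, "reward_prob", 0, 1)
  first_rewarded_spout <- match.arg(first_rewarded_spout)
  stage <- as.character(stage)
  if (!stage %in% c("1", "2", "3", "4", "5", "final")) {
    stop_param("`stage` must be one of 1..5 or \"final\"")
  }
  stage_num <- if (stage == "final") 6L else as.integer(stage)
  if (is.null(immediate_feedback)) immediate_feedback <- stage_num == 4L
  structure(list(
    n_blocks = as.integer(n_blocks),
    block_min_len = as.integer(block_min_len),
    criterion = criterion,
    criterion_window = as.integer(criterion_window),
    lr_duration_s = lr_duration_s,
    ra_duration_s = ra_duration_s,
    post_reward_s = post_reward_s,
    reward_prob = reward_prob,
    first_rewarded_spout = first_rewarded_spout,
    immediate_feedback = isTRUE(immediate_feedback),
    stage = stage,
    # derived stage flags
    single_spout = stage_num <= 3L,
    require_nose_poke = stage_num >= 3L,
    immediate_reward = stage_num == 1L,
    seed = as.integer(seed)
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<task_config> stage %s | %d block(s), min length %d, criterion %.0f%%/%d\n",
    "  LR %g s, RA %g s, post-reward %g s, reward p=%g, first spout %s\n"),
    x$stage, x$n_blocks, x$block_min_len, 100 * x$criterion,
    x$criterion_window, x$lr_duration_s, x$ra_duration_s, x$post_reward_s,
    x$reward_prob, x$first_rewarded_spout))
  invisible(x)
}

#' Classify a trial outcome from the first lick
#'
#' A trial is a hit when the first lick within the 2 s licking-response
#' period lands on the rewarded spout, an error when it lands on the other
#' spout, and a miss when no lick occurs within the period. With a single
#' spout presented (training stages 1-3) any lick is a hit. Only the first
#' lick decides the outcome.
#'
#' @param first_lick_side `"left"`, `"right"`, or `NA` if no lick occurred.
#' @param first_lick_latency_s latency from head entry (s, >= 0), or `NA`.
#' @param rewarded_spout the currently rewarded spout.
#' @param config a [task_config].
#' @return one of `"hit"`, `"error"`, `"miss"`.
#' @export
classify_outcome <- function(first_lick_side, first_lick_latency_s,
                             rewarded_spout, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  if (is.null(first_lick_side) || is.na(first_lick_side)) return("miss")
  if (is.na(first_lick_latency_s) || first_lick_latency_s < 0) {
    stop_param("`first_lick_latency_s` must be >= 0 when a lick occurred")
  }
  if (first_lick_latency_s > config$lr_duration_s) return("miss")
  if (config$single_spout) return("hit")
  if (identical(first_lick_side, rewarded_spout)) "hit" else "error"
}

#' Schedule the within-trial event times implied by an outcome
#'
#' Hits: the tone cue plays at the end of the LR period, water is delivered
#' after the RA period, and the trial ends (gate closes) after the
#' post-reward interval. Errors and misses: the white-noise cue plays at LR
#' end — or at the wrong lick itself under immediate feedback — and the gate
#' closes at the cue, ending the trial. Stage 1 collapses cue and reward
#' onto the first lick.
#'
#' @param outcome `"hit"`, `"error"` or `"miss"`.
#' @param head_entry_t head-entry time (s).
#' @param config a [task_config].
#' @param first_lick_t absolute time of the outcome-defining lick (s) or `NA`.
#' @return named list: `cue`, `cue_type`, `reward` (`NA` unless hit),
#'   `gate_close`, `trial_end`.
#' @export
schedule_trial_events <- function(outcome, head_entry_t,
                                  config = task_config(),
                                  first_lick_t = NA_real_) {
  stopifnot(inherits(config, "task_config"))
  outcome <- match.arg(outcome, c("hit", "error", "miss"))
  lr_end <- head_entry_t + config$lr_duration_s
  if (outcome == "hit") {
    cue <- if (config$immediate_reward && !is.na(first_lick_t)) {
      first_lick_t
    } else lr_end
    reward <- if (config$immediate_reward) cue else cue + config$ra_duration_s
    trial_end <- reward + config$post_reward_s
    list(cue = cue, cue_type = "tone_5khz", reward = reward,
         gate_close = trial_end, trial_end = trial_end)
  } else {
    cue <- if (outcome == "error" && config$immediate_feedback &&
               !is.na(first_lick_t)) {
      first_lick_t
    } else lr_end
    list(cue = cue, cue_type = "white_noise", reward = NA_real_,
         gate_close = cue, trial_end = cue)
  }
}

#' Evaluate the reversal criterion over the current block
#'
#' A reversal fires only when (1) the current block holds at least
#' `block_min_len` trials and (2) the hit fraction over the trailing
#' `criterion_window` trials — the whole block when it is still shorter —
#' reaches `criterion`. Misses count as non-hits. The window never spans a
#' reversal: callers pass outcomes of the current block only.
#'
#' @param block_outcomes character vector of outcomes for the current block.
#' @param config a [task_config].
#' @return list with `reverse` (logical) and `window_perf` (hit fraction over
#'   the evaluated window; `NA` for an empty block).
#' @export
update_reversal <- function(block_outcomes, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  n <- length(block_outcomes)
  if (!n) return(list(reverse = FALSE, window_perf = NA_real_))
  w <- min(n, config$criterion_window)
  window <- block_outcomes[(n - w + 1L):n]
  perf <- mean(window == "hit")
  list(reverse = n >= config$block_min_len && perf >= config$criterion,
       window_perf = perf)
}
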