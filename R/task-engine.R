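#' Run a simulated directional-licking session
#'
#' Discrete-event simulation of the two-spout task. Each completed trial
#' follows nose poke -> gate opening -> walking delay -> head entry ->
#' licking-response period -> cue (5 kHz tone on hits, white noise on errors
#' and misses) -> reward-anticipation period and water on hits -> gate
#' closure. After every trial the reversal criterion is evaluated over the
#' current block only; when it fires and blocks remain, the rewarded spout
#' flips and the criterion window resets.
#'
#' Water delivery on hits is Bernoulli with probability
#' `config$reward_prob`, drawn from a reward stream pre-seeded with
#' `config$seed`; outcome classification is unaffected. With
#' `reward_prob = 1` no stochasticity enters the engine and the session is
#' exactly the deterministic task.
#'
#' @param config a [task_config].
#' @param agent a [make_agent()] policy.
#' @param max_trials maximum number of agent turns (>= 1).
#' @return object of class `lickbox_session`: list with `config`, `trials`
#'   (one data.frame row per completed trial), `reversal_trials` (indices of
#'   trials whose completion triggered a reversal), `seed`, `agent_kind`.
#' @examples
#' log <- run_session(task_config(n_blocks = 2, seed = 42),
#'                    make_agent("perfect", seed = 42), max_trials = 40)
#' log$reversal_trials  # first reversal fires at trial 15
#' @export
run_session <- function(config = task_config(), agent, max_trials = 200) {
  stopifnot(inherits(config, "task_config"), inherits(agent, "lick_agent"))
  check_scalar(max_trials, "max_trials", 1)
  max_trials <- as.integer(max_trials)
  reward_u <- with_seed(config$seed, stats::runif(max_trials))

  rows <- vector("list", max_trials)
  n_done <- 0L
  t_now <- 0
  block <- 1L
  rewarded <- config$first_rewarded_spout
  block_outcomes <- character(0)
  reversal_trials <- integer(0)
  last <- NULL

  for (turn in seq_len(max_trials)) {
    obs <- list(trial = n_done + 1L, block = block,
                rewarded_spout = rewarded, last = last)
    act <- agent$fn(obs)
    if (!is.list(act) || is.null(act$type) ||
        !act$type %in% c("lick", "enter_no_lick", "no_entry")) {
      lb_stop(sprintf("agent returned a malformed action at trial %d",
                      n_done + 1L), "lickbox_protocol_error")
    }
    if (act$type == "no_entry") {
      t_now <- t_now + 5
      next
    }
    for (f in c("np_latency_s", "walk_s")) {
      if (!is_scalar_num(act[[f]]) || act[[f]] < 0) {
        lb_stop(sprintf("agent action missing non-negative `%s` at trial %d",
                        f, n_done + 1L), "lickbox_protocol_error")
      }
    }
    if (config$require_nose_poke) {
      t_np <- t_now + act$np_latency_s
      t_gate <- t_np
    } else {
      t_np <- NA_real_
      t_gate <- NA_real_  # gate already open
    }
    t_he <- (if (is.na(t_np)) t_now + act$np_latency_s else t_np) + act$walk_s

    if (act$type == "lick") {
      if (!act$side %in% c("left", "right") ||
          !is_scalar_num(act$lick_latency_s) || act$lick_latency_s < 0) {
        lb_stop(sprintf("agent returned a malformed lick action at trial %d",
                        n_done + 1L), "lickbox_protocol_error")
      }
      lick_side <- act$side
      lick_lat <- act$lick_latency_s
      t_lick <- t_he + lick_lat
    } else {
      lick_side <- NA_character_
      lick_lat <- NA_real_
      t_lick <- NA_real_
    }

    outcome <- classify_outcome(lick_side, lick_lat, rewarded, config)
    if (outcome == "miss") { # a late lick does not count as a response
      lick_side <- NA_character_; lick_lat <- NA_real_; t_lick <- NA_real_
    }
    sched <- schedule_trial_events(outcome, t_he, config, t_lick)
    got_water <- outcome == "hit" &&
      (config$reward_prob >= 1 || reward_u[turn] <= config$reward_prob)
    t_reward <- if (got_water) sched$reward else NA_real_

    n_done <- n_done + 1L
    rows[[n_done]] <- data.frame(
      trial = n_done, block = block, rewarded_spout = rewarded,
      outcome = outcome, first_lick_side = lick_side,
      t_nose_poke = t_np, t_gate_open = t_gate, t_head_entry = t_he,
      t_first_lick = t_lick, t_cue = sched$cue, cue_type = sched$cue_type,
      t_reward = t_reward, rewarded = got_water,
      t_gate_close = sched$gate_close, t_trial_end = sched$trial_end,
      stringsAsFactors = FALSE
    )
    block_outcomes <- c(block_outcomes, outcome)
    upd <- update_reversal(block_outcomes, config)
    if (upd$reverse && block < config$n_blocks) {
      reversal_trials <- c(reversal_trials, n_done)
      rewarded <- if (rewarded == "left") "right" else "left"
      block <- block + 1L
      block_outcomes <- character(0)
    }
    last <- list(side = lick_side, outcome = outcome, rewarded = got_water,
                 cue_type = sched$cue_type)
    t_now <- sched$trial_end
  }

  trials <- if (n_done) do.call(rbind, rows[seq_len(n_done)]) else
    data.frame(trial = integer(0), block = integer(0),
               rewarded_spout = character(0), outcome = character(0),
               first_lick_side = character(0), t_nose_poke = numeric(0),
               t_gate_open = numeric(0), t_head_entry = numeric(0),
               t_first_lick = numeric(0), t_cue = numeric(0),
               cue_type = character(0), t_reward = numeric(0),
               rewarded = logical(0), t_gate_close = numeric(0),
               t_trial_end = numeric(0))
  structure(list(config = config, trials = trials,
                 reversal_trials = reversal_trials,
                 seed = config$seed, agent_kind = agent$kind),
            class = "lickbox_session")
}

#' @export
print.lickbox_session <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("<lickbox_session> %d trials, %d block(s), %d reversal(s) [agent %s]\n",
              n, if (n) max(x$trials$block) else 0L,
              length(x$reversal_trials), x$agent_kind))
  if (n) {
    tab <- table(factor(x$trials$outcome, c("hit", "error", "miss")))
    cat(sprintf("  hit %d | error %d | miss %d\n",
                tab[["hit"]], tab[["error"]], tab[["miss"]]))
  }
  invisible(x)
}

#' Export the TTL event map of a session
#'
#' One timestamped, channel-labeled row per physical event the controller
#' would emit or receive: nose poke, gate opening/closure, head-entry beam
#' crossing, first lick per trial (left/right channel), auditory cue (tone or
#' white noise channel), and water valve.
#'
#' @param log a [run_session()] result.
#' @return data.frame with columns `trial`, `block`, `event`, `time_s`,
#'   `detail`, sorted by time.
#' @export
export_ttl_map <- function(log) {
  stopifnot(inherits(log, "lickbox_session"))
  tr <- log$trials
  if (!nrow(tr)) {
    return(data.frame(trial = integer(0), block = integer(0),
                      event = character(0), time_s = numeric(0),
                      detail = character(0)))
  }
  one <- function(trial, block, event, time_s, detail = "") {
    if (is.na(time_s)) NULL else
      data.frame(trial = trial, block = block, event = event,
                 time_s = time_s, detail = detail, stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(tr)), function(i) {
    r <- tr[i, ]
    do.call(rbind, Filter(Negate(is.null), list(
      one(r$trial, r$block, "nose_poke", r$t_nose_poke),
      one(r$trial, r$block, "gate_open", r$t_gate_open),
      one(r$trial, r$block, "head_entry", r$t_head_entry),
      if (!is.na(r$t_first_lick))
        one(r$trial, r$block, paste0("lick_", r$first_lick_side),
            r$t_first_lick),
      one(r$trial, r$block,
          if (r$cue_type == "tone_5khz") "cue_tone" else "cue_noise",
          r$t_cue, r$outcome),
      if (isTRUE(r$rewarded)) one(r$trial, r$block, "water", r$t_reward),
      one(r$trial, r$block, "gate_close", r$t_gate_close)
    )))
  })
  out <- do.call(rbind, out)
  out[order(out$time_s, out$trial), , drop = FALSE]
}
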