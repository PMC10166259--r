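test_that("trial outcomes partition into hit, error and miss", {
  cfg <- task_config()
  expect_equal(classify_outcome("left", 0.5, "left", cfg), "hit")
  expect_equal(classify_outcome("right", 0.5, "left", cfg), "error")
  expect_equal(classify_outcome(NA, NA, "left", cfg), "miss")
  # a lick after the 2 s LR period does not count as a response
  expect_equal(classify_outcome("left", 2.5, "left", cfg), "miss")
  # single-spout training stages cannot produce errors
  cfg1 <- task_config(stage = 1)
  expect_equal(classify_outcome("right", 0.5, "left", cfg1), "hit")
})

test_that("trial event times follow the LR/RA/post-reward schedule", {
  cfg <- task_config()
  hit <- schedule_trial_events("hit", head_entry_t = 10.0, cfg)
  expect_equal(hit$cue, 12.0)      # HE + 2 s LR
  expect_equal(hit$reward, 13.0)   # cue + 1 s RA
  expect_equal(hit$trial_end, 17.0) # reward + 4 s post-reward
  expect_equal(hit$cue_type, "tone_5khz")

  err <- schedule_trial_events("error", 10.0, cfg, first_lick_t = 10.4)
  expect_equal(err$cue, 12.0)            # delayed feedback at LR end
  expect_true(is.na(err$reward))
  expect_equal(err$gate_close, err$cue)  # gate closes at the cue
  expect_equal(err$cue_type, "white_noise")

  # immediate feedback: white noise at the wrong lick itself
  cfg4 <- task_config(stage = 4)
  err4 <- schedule_trial_events("error", 10.0, cfg4, first_lick_t = 10.4)
  expect_equal(err4$cue, 10.4)

  for (oc in c("hit", "error", "miss")) {
    s <- schedule_trial_events(oc, 5.0, cfg, first_lick_t = 5.3)
    ts <- c(5.0, s$cue, s$reward, s$gate_close, s$trial_end)
    expect_false(is.unsorted(ts[!is.na(ts)]))
  }
})

test_that("the reversal criterion requires 15 trials and 70% over the window", {
  cfg <- task_config()
  expect_false(update_reversal(rep("hit", 14), cfg)$reverse) # length gate
  r15 <- update_reversal(rep("hit", 15), cfg)
  expect_true(r15$reverse)
  expect_equal(r15$window_perf, 1.0)
  # alternating hits and errors never reach 70%
  alt <- rep(c("hit", "error"), 10)
  ralt <- update_reversal(alt, cfg)
  expect_false(ralt$reverse)
  expect_lt(ralt$window_perf, 0.70)
  # misses count as non-hits
  expect_false(update_reversal(c(rep("hit", 10), rep("miss", 5)),
                               cfg)$reverse)
})

test_that("sessions reverse on criterion and respect the block budget", {
  # an always-correct agent triggers the first reversal at trial 15
  log <- run_session(task_config(n_blocks = 2, seed = 1),
                     make_agent("perfect", seed = 1), max_trials = 40)
  expect_equal(log$reversal_trials[1], 15L)

  # n_blocks = 4: exactly 3 reversals, at trials 15, 30, 45
  log4 <- run_session(task_config(n_blocks = 4, seed = 1),
                      make_agent("perfect", seed = 1), max_trials = 70)
  expect_equal(log4$reversal_trials, c(15L, 30L, 45L))
  expect_true(all(log4$trials$outcome == "hit"))
  # contingency alternates across blocks
  expect_equal(unique(log4$trials$rewarded_spout[log4$trials$block == 1]), "left")
  expect_equal(unique(log4$trials$rewarded_spout[log4$trials$block == 2]), "right")

  # an agent that never enters completes no trials and never reverses
  none <- run_session(task_config(seed = 1), make_agent("no_entry"),
                      max_trials = 20)
  expect_equal(nrow(none$trials), 0)
  expect_length(none$reversal_trials, 0)
})

test_that("identical config, agent and seed reproduce the session exactly", {
  for (kind in c("epsilon_random", "wsls_qlearner")) {
    a <- run_session(task_config(n_blocks = 3, reward_prob = 0.8, seed = 11),
                     make_agent(kind, seed = 5), max_trials = 60)
    b <- run_session(task_config(n_blocks = 3, reward_prob = 0.8, seed = 11),
                     make_agent(kind, seed = 5), max_trials = 60)
    expect_identical(a$trials, b$trials)
    expect_identical(a$reversal_trials, b$reversal_trials)
  }
})

test_that("probabilistic reward withholds water without changing outcomes", {
  log <- run_session(task_config(reward_prob = 0.5, seed = 21),
                     make_agent("perfect", seed = 21), max_trials = 40)
  expect_true(all(log$trials$outcome == "hit"))
  expect_true(any(!log$trials$rewarded))   # some hits unrewarded
  expect_true(all(is.na(log$trials$t_reward[!log$trials$rewarded])))
  # water only ever follows a hit
  expect_true(all(log$trials$outcome[log$trials$rewarded] == "hit"))

  # reward_prob = 1 is exactly the deterministic task
  d1 <- run_session(task_config(reward_prob = 1, seed = 2),
                    make_agent("wsls_qlearner", seed = 2), max_trials = 50)
  expect_true(all(d1$trials$rewarded == (d1$trials$outcome == "hit")))
})

test_that("agent policies behave as specified", {
  # epsilon = 1: uniform side choice, long-run hit rate near 1/2
  log <- run_session(task_config(n_blocks = 1, seed = 3),
                     make_agent("epsilon_random", list(epsilon = 1), seed = 3),
                     max_trials = 300)
  p <- mean(log$trials$outcome == "hit")
  expect_lt(abs(p - 0.5), 3.5 * sqrt(0.25 / 300)) # binomial 3.5-sigma band

  # high-alpha q-learner recovers within a bounded number of post-reversal
  # trials
  logq <- run_session(task_config(n_blocks = 2, seed = 13),
                      make_agent("wsls_qlearner",
                                 list(alpha = 0.8, beta = 10), seed = 13),
                      max_trials = 120)
  expect_length(logq$reversal_trials, 1)
  rev_at <- logq$reversal_trials[1]
  post <- logq$trials$outcome[(rev_at + 1):min(rev_at + 10, nrow(logq$trials))]
  expect_true("hit" %in% post)

  # stage 1 (single spout, gate open) never emits errors
  s1 <- run_session(task_config(stage = 1, n_blocks = 1, seed = 4),
                    make_agent("side_biased", list(p_left = 0.5), seed = 4),
                    max_trials = 50)
  expect_false(any(s1$trials$outcome == "error"))

  expect_error(make_agent("teleport"))
})

test_that("random sessions never violate the task invariants", {
  kinds <- c("perfect", "side_biased", "epsilon_random", "wsls_qlearner")
  set.seed(77)
  for (i in 1:30) {
    cfg <- task_config(n_blocks = sample(1:4, 1),
                       reward_prob = sample(c(1, 0.8), 1),
                       first_rewarded_spout = sample(c("left", "right"), 1),
                       seed = i)
    ag <- make_agent(sample(kinds, 1), seed = i + 100)
    log <- run_session(cfg, ag, max_trials = 40)
    tr <- log$trials
    # reversal never fires before block_min_len trials of the current block
    blk_len <- table(tr$block)
    if (length(blk_len) > 1) {
      expect_true(all(blk_len[-length(blk_len)] >= cfg$block_min_len))
    }
    if (nrow(tr)) expect_length(log$reversal_trials, max(tr$block) - 1L)
    # outcome partition
    expect_true(all(tr$outcome %in% c("hit", "error", "miss")))
    # reward implies hit
    expect_true(all(tr$outcome[tr$rewarded] == "hit"))
    # timestamps non-decreasing in state order within each trial
    for (j in seq_len(nrow(tr))) {
      ts <- unlist(tr[j, c("t_nose_poke", "t_gate_open", "t_head_entry",
                           "t_first_lick", "t_cue", "t_reward",
                           "t_gate_close", "t_trial_end")])
      expect_false(is.unsorted(ts[!is.na(ts)]))
    }
    # trials advance in time
    if (nrow(tr) > 1) expect_false(is.unsorted(tr$t_trial_end))
  }
})

test_that("the TTL map lists one labeled row per physical event", {
  empty <- export_ttl_map(run_session(task_config(seed = 1),
                                      make_agent("no_entry"), max_trials = 3))
  expect_equal(nrow(empty), 0)

  one <- run_session(task_config(n_blocks = 1, seed = 1),
                     make_agent("perfect", seed = 1), max_trials = 1)
  ttl <- export_ttl_map(one)
  expect_equal(sum(ttl$event == "water"), 1)
  expect_equal(sum(ttl$event == "cue_tone"), 1)

  log <- run_session(task_config(n_blocks = 2, seed = 6),
                     make_agent("epsilon_random", list(epsilon = 0.5),
                                seed = 6), max_trials = 25)
  ttl2 <- export_ttl_map(log)
  expect_false(is.unsorted(ttl2$time_s))
  # counting oracle: per trial, NP + gate open + HE + gate close + cue
  # (5 rows) + lick if licked + water if rewarded
  tr <- log$trials
  expected_rows <- 5 * nrow(tr) + sum(!is.na(tr$t_first_lick)) +
    sum(tr$rewarded)
  expect_equal(nrow(ttl2), expected_rows)
})
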