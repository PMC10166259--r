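test_that("events map to the nearest frame, ties to the earlier frame", {
  frames <- c(0, 0.05, 0.10)
  expect_equal(align_events_to_frames(0.05, frames)$frame, 2L)
  expect_equal(align_events_to_frames(0.06, frames)$frame, 2L)
  expect_equal(align_events_to_frames(0.025, frames)$frame, 1L) # tie -> earlier
  expect_equal(align_events_to_frames(0.075, frames)$frame, 2L) # tie -> earlier
  out <- align_events_to_frames(c(-0.5, 0.04, 0.7), frames)
  expect_equal(out$outside, c(TRUE, FALSE, TRUE))
  expect_error(align_events_to_frames(1, numeric(0)),
               class = "lickbox_param_error")
})

test_that("MAD normalization is a robust z-score invariant to affine maps", {
  expect_equal(mad_normalize(1:5), c(-2, -1, 0, 1, 2))

  set.seed(3)
  x <- rnorm(200)
  expect_equal(mad_normalize(3.7 * x + 11), mad_normalize(x),
               tolerance = 1e-12)

  expect_error(mad_normalize(rep(2, 100)),
               class = "lickbox_degenerate_error")
  # majority-constant traces also have MAD 0
  expect_error(mad_normalize(c(rep(0, 99), 5)),
               class = "lickbox_degenerate_error")
})

test_that("event-triggered averages accumulate normalized segments", {
  frame_ts <- gen_frame_clock(20, 200)
  set.seed(4)
  mat <- matrix(rnorm(2 * 200), nrow = 2)
  tr <- calcium_traces(mat, frame_ts)

  # single event: average equals that segment of the normalized trace
  eta1 <- event_triggered_average(tr, 100, pre_frames = 10, post_frames = 20)
  z <- mad_normalize(mat[1, ])
  expect_equal(as.numeric(eta1$average[1, ]), z[90:120])
  expect_equal(eta1$n_events_used, 1)

  # out-of-bounds events are skipped and counted
  eta2 <- event_triggered_average(tr, c(5, 100, 199), 10, 20)
  expect_equal(eta2$n_events_used, 1)
  expect_equal(eta2$n_events_skipped, 2)
  expect_error(event_triggered_average(tr, c(2, 199), 10, 20),
               class = "lickbox_data_error")

  # constant units are excluded, not imputed
  mat2 <- rbind(mat[1, ], rep(1, 200))
  eta3 <- event_triggered_average(calcium_traces(mat2, frame_ts), 100, 5, 5)
  expect_equal(eta3$excluded_units, "u002")
  expect_equal(nrow(eta3$average), 1)
})

test_that("noise stays under the 3xMAD threshold and locked units exceed it", {
  frame_ts <- gen_frame_clock(20, 12000)
  events <- list(licking = seq(10, 500, by = 10)) # 50 events
  tr <- gen_calcium_traces(events, calcium_kernel(peak_df = 0.8),
                           locked_fraction = 0.1, noise_sigma = 0.1,
                           frame_ts = frame_ts, n_units = 20, seed = 15)
  truth <- attr(tr, "truth_labels")
  map <- align_events_to_frames(events$licking, frame_ts)
  eta <- event_triggered_average(tr, map$frame, 20, 40)
  peaks <- apply(eta$average, 1, max)
  expect_true(all(peaks[truth == "unmodulated"] < 3))
  expect_true(all(peaks[truth == "licking"] >= 3))
})

test_that("modulation classes recover the generator's ground-truth labels", {
  ev <- make_alignment_events(n_events = 30, seed = 6)
  frame_ts <- gen_frame_clock(20, ceiling(max(ev$postlick) + 10) * 20)
  tr <- gen_calcium_traces(ev, calcium_kernel(peak_df = 0.8),
                           locked_fraction = 0.5, noise_sigma = 0.1,
                           frame_ts = frame_ts, n_units = 12, seed = 16)
  res <- classify_modulation(tr, ev)
  expect_s3_class(res, "modulation_result")
  expect_equal(attr(res, "threshold"), 3.0)
  expect_equal(res$class, attr(tr, "truth_labels"))
  # class label and threshold are mutually consistent
  expect_true(all((res$class != "unmodulated") == (res$peak_mad >= 3)))
})

test_that("trial-type splits assign each usable trial to one outcome group", {
  log <- run_session(task_config(n_blocks = 1, seed = 9),
                     make_agent("perfect", seed = 9), max_trials = 12)
  dur <- max(log$trials$t_trial_end) + 10
  frame_ts <- gen_frame_clock(20, ceiling(dur) * 20)
  ev <- event_times_from_log(log)
  tr <- gen_calcium_traces(ev, locked_fraction = 0.5, noise_sigma = 0.1,
                           frame_ts = frame_ts, n_units = 4, seed = 9)
  sp <- split_by_trial_type(tr, log)
  # all-hit session: error and miss groups empty
  expect_null(sp$error)
  expect_null(sp$miss)
  expect_equal(dim(sp$hit)[1], nrow(log$trials))
  expect_equal(dim(sp$hit)[3], 4)

  mixed <- run_session(task_config(n_blocks = 2, seed = 10),
                       make_agent("epsilon_random", list(epsilon = 0.6),
                                  seed = 10), max_trials = 30)
  dur2 <- max(mixed$trials$t_trial_end) + 10
  fts2 <- gen_frame_clock(20, ceiling(dur2) * 20)
  tr2 <- gen_calcium_traces(event_times_from_log(mixed), locked_fraction = 0,
                            noise_sigma = 0.1, frame_ts = fts2,
                            n_units = 3, seed = 10)
  sp2 <- split_by_trial_type(tr2, mixed)
  n_grouped <- sum(vapply(sp2, function(a) if (is.null(a)) 0L else dim(a)[1],
                          integer(1)))
  expect_equal(n_grouped, nrow(mixed$trials))
})

test_that("frame loss follows the gap-rounding rule", {
  expect_equal(as.numeric(compute_frame_loss(gen_frame_clock(30, 500), 30)), 0)

  # 10 single-frame gaps in a 1000-frame nominal grid: exactly 1.0%
  drop10 <- gen_frame_clock(30, 1000, dropped_idx = seq(50, 950, by = 100))
  expect_equal(as.numeric(compute_frame_loss(drop10, 30)), 1.0)

  # one gap of 3 nominal periods counts 2 lost frames
  gap3 <- gen_frame_clock(30, 1000, dropped_idx = c(400, 401))
  fl <- compute_frame_loss(gap3, 30)
  expect_equal(attr(fl, "lost_frames"), 2)
  expect_equal(as.numeric(fl), 100 * 2 / 1000)

  expect_error(compute_frame_loss(c(1, 0.5), 30), class = "lickbox_data_error")
  expect_error(compute_frame_loss(1, 30), class = "lickbox_param_error")
})
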