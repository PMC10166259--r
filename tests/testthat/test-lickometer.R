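test_that("preprocessing downsamples to 1 kHz with the analytic passband", {
  # constant trace passes unchanged
  const <- sg_trace(rep(0.5, 60000), fs_hz = 30000)
  out <- preprocess(const)
  expect_equal(out$fs_hz, 1000)
  expect_equal(out$samples, rep(0.5, length(out$samples)), tolerance = 1e-6)

  t <- seq(0, 2, by = 1 / 30000)
  # 10 Hz unit sine: passband, amplitude within 1%
  s10 <- preprocess(sg_trace(sin(2 * pi * 10 * t), fs_hz = 30000))
  core <- s10$samples[200:(length(s10$samples) - 200)]
  expect_equal(max(abs(core)), 1, tolerance = 0.01)

  # 500 Hz sine: stopband, amplitude < 0.01
  s500 <- preprocess(sg_trace(sin(2 * pi * 500 * t), fs_hz = 30000))
  expect_lt(max(abs(s500$samples)), 0.01)

  expect_error(preprocess(sg_trace(rnorm(100), fs_hz = 500)),
               class = "lickbox_param_error")
})

test_that("preprocessing does not displace transient peaks (zero phase)", {
  licks <- c(0.8, 1.7, 2.9)
  raw <- gen_sg_trace(licks, noise = noise_spec(sigma_V = 0), fs_hz = 30000,
                      duration_s = 4)
  pp <- preprocess(raw)
  for (tc in licks) {
    w <- which(abs(trace_times(pp) - tc) < 0.1)
    t_peak <- trace_times(pp)[w][which.max(pp$samples[w])]
    expect_lt(abs(t_peak - tc), 2 / 1000 + 1e-9)
  }
})

test_that("offline detector applies prominence, width and distance rules", {
  expect_length(detect_licks_offline(sg_trace(rep(0, 2000), 1000))$times_s, 0)

  # five clean bumps at 150 ms spacing: all found within +-5 ms
  centers <- 0.5 + 0.15 * (0:4)
  tr <- bump_trace(centers, amps = 0.1, width_s = 0.12)
  det <- detect_licks_offline(tr)
  expect_length(det$times_s, 5)
  expect_true(all(abs(det$times_s - centers) < 0.005))

  # sub-prominence bumps are ignored
  weak <- bump_trace(centers, amps = 0.01, width_s = 0.12)
  expect_length(detect_licks_offline(weak)$times_s, 0)

  # two distinct peaks 50 ms apart: the 60 ms distance rule keeps the taller
  two <- bump_trace(c(1.00, 1.05), amps = c(0.08, 0.12), width_s = 0.03)
  p <- offline_params(min_width_s = 0.005)
  det2 <- detect_licks_offline(two, p)
  expect_length(det2$times_s, 1)
  expect_lt(abs(det2$times_s - 1.05), 0.005)

  # detector output always honors its constraints, also under noise
  licks <- gen_lick_train(lick_train_spec(duration_s = 15, seed = 4))
  noisy <- gen_sg_trace(licks, noise = noise_spec(sigma_V = 0.03),
                        fs_hz = 2000, seed = 4)
  d <- detect_licks_offline(noisy)
  pk <- attr(d, "peaks")
  if (length(d$times_s) > 1) expect_true(all(diff(d$times_s) >= 0.060))
  expect_true(all(pk$prominence >= 0.015))
  expect_true(all(pk$width_s >= 0.050))
})

test_that("online comparator emits one onset per armed threshold crossing", {
  expect_equal(online_params()$threshold_V, 0.100)

  # never crosses: empty
  sub <- sg_trace(rep(0.05, 4000), 1000)
  expect_length(emulate_online_comparator(sub)$times_s, 0)

  # rectangular pulse 0.15 V above a flat baseline: one onset at the first
  # suprathreshold sample
  x <- rep(0.2, 5000); x[3001:3200] <- 0.35
  on <- emulate_online_comparator(sg_trace(x, 1000))
  expect_equal(on$times_s, 3.000)

  # hysteresis: a dip that stays above baseline + threshold/2 does not
  # re-arm; a dip below it does
  x2 <- rep(0, 5000)
  x2[1001:1100] <- 0.15; x2[1101:1200] <- 0.08; x2[1201:1300] <- 0.15
  expect_length(emulate_online_comparator(sg_trace(x2, 1000))$times_s, 1)
  x2[1101:1200] <- 0.02
  expect_length(emulate_online_comparator(sg_trace(x2, 1000))$times_s, 2)
})

test_that("sensitivity and PPV follow their defining ratios", {
  m <- match_licks(c(1, 2, 3, 9), c(1, 2, 3, 4))
  expect_equal(m$tp, 3); expect_equal(m$fp, 1); expect_equal(m$fn, 1)
  met <- confusion_metrics(m)
  expect_equal(met$sensitivity, 0.75)
  expect_equal(met$ppv, 0.75)

  # undefined ratios are NA sentinels, never silent zeros
  empty <- match_licks(numeric(0), numeric(0))
  met0 <- confusion_metrics(empty)
  expect_true(is.na(met0$sensitivity))
  expect_true(is.na(met0$ppv))
})

test_that("threshold sweep reproduces direct comparator runs and is monotone", {
  expect_equal(nrow(threshold_sweep(sg_trace(rep(0, 100), 1000), 1,
                                    numeric(0))), 0)

  # peaks of 0.03, 0.05, 0.12 V over baseline: thresholds 0.10/0.04/0.02
  # detect 1, 2, 3 of them
  tr <- bump_trace(c(1, 2, 3), amps = c(0.03, 0.05, 0.12), width_s = 0.12,
                   duration_s = 4)
  sw <- threshold_sweep(tr, c(1, 2, 3), thresholds_V = c(0.10, 0.04, 0.02))
  expect_equal(sw$n_detected, c(1, 2, 3))
  expect_equal(sw$tp, c(1, 2, 3))

  # single threshold equals a direct comparator run
  direct <- emulate_online_comparator(tr, online_params(threshold_V = 0.04))
  expect_equal(sw$n_detected[2], length(direct$times_s))

  # monotone direction on noisy synthetic data
  licks <- gen_lick_train(lick_train_spec(rate_hz = 5, refractory_s = 0.15,
                                          duration_s = 20, seed = 8))
  noisy <- gen_sg_trace(licks, noise = noise_spec(sigma_V = 0.02), seed = 8)
  sw2 <- threshold_sweep(noisy, licks, seq(0.02, 0.14, by = 0.02))
  expect_true(all(diff(sw2$sensitivity) <= 1e-12))
  expect_true(all(diff(sw2$fp) <= 0))
  expect_true(all(diff(sw2$fn) >= 0))
})

test_that("interlick intervals summarize successive differences", {
  ili <- interlick_intervals(c(0, 0.1, 0.2))
  expect_equal(ili$intervals_s, c(0.1, 0.1))

  expect_length(interlick_intervals(c(1))$intervals_s, 0)

  # offline-detected series: all intervals >= the 60 ms distance rule
  licks <- gen_lick_train(lick_train_spec(duration_s = 15, seed = 6))
  tr <- gen_sg_trace(licks, noise = noise_spec(sigma_V = 0.02), seed = 6)
  det <- detect_licks_offline(tr)
  expect_true(all(interlick_intervals(det)$intervals_s >= 0.060))

  # 10 Hz train: interval histogram mode near 100 ms
  train <- gen_lick_train(lick_train_spec(rate_hz = 10, duration_s = 120,
                                          seed = 2))
  expect_lt(abs(interlick_intervals(train)$mode_s - 0.1), 0.03)
})
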