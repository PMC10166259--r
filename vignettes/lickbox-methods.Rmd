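---
title: "Models and design choices behind lickbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind lickbox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickbox)
```

lickbox is the hardware-free computational core of a strain-gauge
lickometer and directional-licking operant platform. This vignette explains
the models implemented in each module, the tunable parameters and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and the numerical choices made where the published procedures leave
the design open.

## Offline lick detection

A lick deflects the spout's strain gauge and produces a force transient of
a few hundred millivolts (after amplification) lasting on the order of
100 ms. The offline pipeline is:

1. **Downsample to 1 kHz** (`target_fs_hz`) through an antialiasing
   low-pass. We use a 6th-order Butterworth at 0.4 x the working rate,
   applied forward-backward, followed by integer decimation (linear
   interpolation for non-integer rate ratios). Zero-phase filtering is a
   deliberate choice: causal filters delay peaks by a filter-dependent lag,
   and unbiased peak *times* are the quantity of interest here.
2. **Low-pass at 64 Hz** (`lowpass_hz`), a zero-phase 4th-order
   Butterworth. Lick transients live well below 30 Hz; this removes sensor
   and amplifier noise without reshaping the peak.
3. **Peak extraction** with three constraints: minimal peak distance
   60 ms (`min_distance_s`, two candidates closer than this resolve to the
   taller), minimal prominence 0.015 (`min_prominence`), and minimal width
   50 ms at half prominence (`min_width_s`).

The prominence value is treated as volts of the amplified signal — the same
units as the trace — and is exposed in `offline_params()` so users whose
amplification differs can rescale it. Edge effects of forward-backward IIR
filtering are controlled by odd-reflection padding of about 8 filter time
constants, so constant traces pass through unchanged and transients near
the trace boundaries are not distorted.

## Online comparator emulation

The online detector is an analog comparator that raises a TTL when the
signal crosses a reference voltage, by default 100 mV
(`online_params(threshold_V = 0.100)`) above baseline. Two details are not
dictated by the circuit description and were fixed as follows:

* **Baseline** is the median of a leading 2 s window
  (`baseline_window_s`), a robust estimate insensitive to licks inside the
  window (thresholds on the real rig are set manually per animal).
* **Re-arming** uses hysteresis: after an onset, a new onset requires the
  signal to first fall below baseline + threshold/2 (`rearm_fraction`).
  Without hysteresis, noise riding on a supra-threshold plateau would emit
  TTL bursts no analog comparator would produce.

`threshold_sweep()` reruns the comparator over a threshold grid and scores
each run against ground truth, reproducing the qualitative trade-off of
lowering the reference voltage: sensitivity can only rise (false positives
too) as the threshold drops.

## Detector validation

`match_licks()` pairs detected with ground-truth licks one-to-one,
greedily by ascending absolute time difference, ties broken toward the
earlier truth event; a pair within 60 ms (the detector's minimal interlick
distance) is a true positive. Sensitivity is TP/(TP+FN) and PPV is
TP/(TP+FP); when a denominator is zero the metric is `NA`, never a silent
zero. On realistic instances — detections are small-jitter copies of truth
events spaced at least a refractory period apart, plus insertions and
deletions — the greedy matching attains the exhaustive maximum-cardinality
optimum; the test suite verifies this against an augmenting-path oracle on
thousands of random instances.

## Synthetic lick trains and traces

`gen_lick_train()` draws interlick intervals from a renewal process:
a hard refractory period plus an exponential residual, with the exponential
rate set so the mean interval is `1/rate_hz`. Two parameters suffice to
match the observed interlick distribution shape, which concentrates just
below 100 ms at a 10 Hz lick rate; the defaults are `rate_hz = 10`,
`refractory_s = 0.08`.

`gen_sg_trace()` renders each lick as a raised-cosine bump: unimodal,
compactly supported, with an analytic peak at the lick time. The default
full width is 120 ms, which gives a half-prominence width of about 60 ms.
This width was chosen to be consistent with the detector's own 50 ms
minimal-width rule — a transient whose half-prominence width fell below
50 ms would describe a lick the published detector could never accept, so
narrower defaults would misrepresent the real signal the pipeline was
tuned on. Peak amplitudes are lognormal with mean `amplitude_V = 0.3` V
and CV 0.2; no amplitude distribution for real licks is published, so
these are documented placeholders exposed in the spec object. Noise is
white Gaussian plus optional linear drift; real traces additionally show
motion artifacts and multi-lick superposition at high rates, so detector
scores on synthetic data bound performance from above.

## The task engine

The task is a freely-moving two-spout directional-licking paradigm. A
trial is: nose poke opens the gate; the animal walks (walking delay, WD)
to the licking chamber (head entry, HE); the first lick within the 2 s
licking-response period (`lr_duration_s`) decides the outcome — hit on the
rewarded spout, error on the other, miss if no lick. At LR end a cue plays
(5 kHz tone on hits, white noise otherwise). Hits then wait a 1 s
reward-anticipation period (`ra_duration_s`) before water, and end after a
4 s post-reward interval (`post_reward_s`); errors and misses close the
gate at the cue. A contingency block reverses once it holds at least 15
trials (`block_min_len`) *and* the hit fraction over the trailing 15-trial
window (`criterion_window`) reaches 70% (`criterion`); `n_blocks` bounds
the number of reversals, and `reward_prob < 1` gives probabilistic reward.

Choices on points the task description leaves open:

* **The criterion window never spans a reversal.** It is evaluated over
  the current block only and resets when the contingency flips; otherwise
  pre-reversal hits could satisfy the post-reversal criterion immediately.
* **Short blocks**: while the block is shorter than the window, the window
  is the whole block, but the 15-trial length gate still applies.
* **First lick decides.** Later licks within the LR are ignored for
  classification; "70% hit" is read literally, so misses count as
  non-hits in the window.
* **Walking delay has no timeout**; the agents draw WD from 0.3–1.2 s.
* **Probabilistic reward** changes only water delivery, never the outcome
  label, and the engine's reward draws use a stream separate from the
  agent's private RNG, so `reward_prob = 1` is bit-identical to the
  deterministic task under the same seed.
* Time is continuous simulated seconds (doubles); logs serialize at ms
  precision. Trial and block indices are 1-based.

Training-stage variants are config flags: single spout (stages 1–3), gate
permanently open (1–2), nose-poke requirement (3+), immediate error
feedback (4), immediate cue+reward at the lick (1). A single-spout stage
cannot emit error outcomes, which the tests assert.

Agent policies (`make_agent()`) stand in for the animal: an omniscient
always-correct agent (the engine exposes the current rewarded spout in the
observation for exactly this oracle use), a side-biased licker, an
epsilon-greedy stay-on-reward policy, and a two-armed Q-learner with
softmax choice that behaves win-stay/lose-shift at high learning rate.

## Session analysis

`block_performance()` is a trailing moving average of hits with window 5;
at the block start the window is truncated to the available trials, the
convention used when plotting performance curves. `trials_to_criterion()`
(70% over 5 trials by default) instead requires a *full* window — a
criterion evaluated on a one-trial "window" would be meaningless — and
returns `NA` when never reached. Both behaviors are documented because the
displayed curve and the criterion would otherwise silently disagree on the
first four trials.

## Event-aligned calcium modulation

Inputs are denoised per-unit temporal traces from an upstream source
extractor, plus frame timestamps. The published construction ("waveform
average of the median absolute deviation of the traces") is ambiguous; we
read it as **MAD-normalize, then average**: each unit's whole-recording
trace is robustly z-scored, `(x - median) / MAD` with the raw MAD (no
1.4826 consistency constant), and segments around each event are averaged.
Under this reading the "3x MAD" modulation threshold is well defined on
the averaged waveform's peak. Units with zero MAD are excluded and
reported, never imputed.

Behavioral events align to the closest recorded frame, ties to the earlier
frame. Because the walking delay varies per trial, the three functional
classes are assigned by **peak competition across three fixed alignments**
rather than time-warping: averages aligned to nose poke (the WD period),
head entry (the LR period) and water delivery (the RA/reward period) are
computed over a window of 1 s before to 2 s after the event; a unit is
modulated when any alignment's average peaks at or above 3 MAD units, and
its class — initiation, licking, postlick — is the alignment with the
maximal peak. Latency jitter between the event streams makes the true
alignment's average the sharpest, which is what the generator-recovery
tests exercise. For a pure-noise unit the averaged normalized trace has a
standard deviation of roughly `1.48/sqrt(n_events)` per frame, so with 40+
events the 3-MAD threshold sits far in the tail and false positives are
rare, as the Monte-Carlo tests confirm.

The synthetic generator places one difference-of-exponentials transient
(rise 0.07 s, decay 0.5 s, a minimal indicator model) per assigned event
in "locked" units and white noise everywhere; it does not emulate
correlated noise, baseline drift, overlapping transients from bursting, or
source-extraction crosstalk, so classifier scores on it are an upper bound.

`compute_frame_loss()` converts gaps in the recorded frame clock into lost
frames by rounding each gap to the nearest multiple of the nominal period
(`k` periods lost means `k - 1` frames), and reports
`100 * lost / (observed + lost)` percent.

## Commutator simulation

A magnet rotating with the tether cable is read by three Hall sensors at
0°, 120°, 240°. The sensor transfer function is not published; a signed
cosine of the angular offset (bipolar Hall output) is the minimal model
with the right symmetry. The decoder combines the three direction fields
into a resultant vector — each reading weighting its sensor's unit vector —
whose angle estimates the magnet orientation; the sector is
`floor(angle / 60°)` among 6 radial positions. On noise-free readings this
is exact everywhere, including sector boundaries, where a decode based
purely on the reading ordering is tie-ambiguous. The published decision
matrix is shown only pictorially; its entries are reconstructed from the
shortest-rotation principle: the command for a sector transition is the
sign of the shortest signed sector displacement, one sector step per
update, ambiguous half-turns taken positive. The motor is idealized as
instant. Under these rules the cumulative command provably tracks any
sufficiently finely sampled trajectory within one sector (60°); per-step
rotations above one sector are flagged as aliasing.

## Numerical notes

* Generators take an integer seed and restore the caller's RNG state;
  identical spec + seed give bit-identical output.
* Kernel support is truncated at 8 decay constants (relative error
  < 1e-3 of peak).
* The sector decoder nudges exact boundary angles upward by 1e-7 degrees
  so the floor convention is stable under floating-point round-off.
* Filter edge padding is odd (antisymmetric) reflection, length about 8
  time constants of the filter's cutoff.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
detection round trips use ~220-lick, 45 s traces synthesized at 10 kHz;
matcher validation uses 1000 random instances of up to 10 events; engine
invariants are checked over 500 random-agent sessions of 35 trials;
modulation recovery uses 50 units x ~28,000 frames at 20 Hz with 40 events
per alignment; commutator tracking uses 10 full turns sampled at 5°. These
sizes give stable statistics for every threshold being checked while
keeping a full run in tens of seconds.

## Known limitations

* The published animal-derived detector scores (sensitivity ~0.74 offline,
  ~0.55 online, PPV ~0.8) depend on the original video-annotated
  recordings and are not reproducible from synthetic data; lickbox
  reproduces the *procedures* and their qualitative behavior.
* Cues are symbolic labels; no audio is synthesized, and nothing runs in
  real time or talks to hardware.
* Agent policies are deliberately simple; they exercise the engine, they
  do not model mouse learning.
* The capacitive touch-sensor comparison channel is out of scope.
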