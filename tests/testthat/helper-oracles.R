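# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Maximum-cardinality one-to-one matching between detected and truth times
# with |dt| < tol, by augmenting paths (exhaustive optimum for the small
# instances used in tests).
bf_match_count <- function(d, t, tol) {
  if (!length(d) || !length(t)) return(0L)
  adj <- lapply(seq_along(d), function(i) which(abs(d[i] - t) < tol))
  st <- new.env()
  st$matched_t <- rep(0L, length(t))
  try_aug <- function(i) {
    for (j in adj[[i]]) {
      if (!st$seen[j]) {
        st$seen[j] <- TRUE
        if (st$matched_t[j] == 0L || try_aug(st$matched_t[j])) {
          st$matched_t[j] <- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  cnt <- 0L
  for (i in seq_along(d)) {
    st$seen <- rep(FALSE, length(t))
    if (try_aug(i)) cnt <- cnt + 1L
  }
  cnt
}

# Random detector-like matching instance: truth licks with >= 120 ms
# spacing, detections = truth + small timing jitter, with misses and
# spurious detections.
random_match_instance <- function(n_max = 10) {
  n <- sample.int(n_max, 1)
  truth <- cumsum(runif(n, 0.12, 0.45))
  keep <- runif(n) > 0.15
  det <- truth[keep] + rnorm(sum(keep), sd = 0.01)
  n_fp <- rpois(1, 1)
  if (n_fp > 0) det <- c(det, runif(n_fp, 0, max(truth) + 0.2))
  list(detected = sort(det), truth = truth)
}

# Raised-cosine bump train on a zero baseline, for constructed detector
# inputs (full width w -> half-prominence width ~ w/2).
bump_trace <- function(centers, amps, width_s, fs_hz = 1000, duration_s = NULL,
                       baseline = 0) {
  if (is.null(duration_s)) duration_s <- max(centers) + 0.5
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  x <- rep(baseline, n)
  amps <- rep_len(amps, length(centers))
  for (k in seq_along(centers)) {
    r <- t - centers[k]
    idx <- which(abs(r) <= width_s / 2)
    x[idx] <- x[idx] + amps[k] * 0.5 * (1 + cos(2 * pi * r[idx] / width_s))
  }
  sg_trace(x, fs_hz = fs_hz)
}

# Jittered alignment-event streams mimicking a behavioral session: nose
# pokes, head entries after a variable walking delay, rewards after the LR +
# RA periods plus consumption jitter.
make_alignment_events <- function(n_events = 40, seed = 1) {
  set.seed(seed)
  np <- cumsum(runif(n_events, 8, 12))
  he <- np + runif(n_events, 0.3, 1.5)
  rw <- he + 3 + runif(n_events, 0, 0.3)
  list(initiation = np, licking = he, postlick = rw)
}
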