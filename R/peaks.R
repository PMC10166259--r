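# Peak extraction with prominence and width-at-half-prominence, the
# primitives behind the offline lick detector. Conventions follow the usual
# findpeaks semantics: prominence is measured against the higher of the two
# bases (lowest point between the peak and the nearest higher terrain on each
# side, window boundaries counting as terrain lower than any sample), width is
# measured at half-prominence below the peak with linear interpolation, and
# the minimum-distance rule keeps the taller of two conflicting peaks.

# Indices of strict local maxima; for flat-topped peaks the first sample of
# the plateau is reported.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (!length(nz)) return(integer(0))
  # Backward-fill zero slopes with the next nonzero slope so a plateau
  # followed by a drop registers as one falling edge at the plateau start.
  if (length(nz) < length(s)) {
    filled <- s
    idx <- rev(seq_len(length(s) - 1L))
    for (i in idx) if (filled[i] == 0) filled[i] <- filled[i + 1L]
    s <- filled
  }
  which(s[-length(s)] == 1 & s[-1L] == -1) + 1L
}

# Prominence of peak at index p: walk outward on each side until a sample
# higher than x[p] (or the boundary); the base on that side is the minimum
# encountered. Returns the prominence and the index range walked.
peak_prominence <- function(x, p) {
  n <- length(x)
  h <- x[p]
  i <- p; lmin <- h
  while (i > 1L) {
    i <- i - 1L
    if (x[i] > h) break
    if (x[i] < lmin) lmin <- x[i]
  }
  left_end <- i
  i <- p; rmin <- h
  while (i < n) {
    i <- i + 1L
    if (x[i] > h) break
    if (x[i] < rmin) rmin <- x[i]
  }
  right_end <- i
  list(prominence = h - max(lmin, rmin),
       left = left_end, right = right_end)
}

# Width at half prominence (samples, interpolated crossings).
peak_width <- function(x, p, prominence, left, right) {
  ref <- x[p] - prominence / 2
  i <- p
  while (i > left && x[i] > ref) i <- i - 1L
  xl <- if (x[i] > ref) i else {
    # interpolate between i and i+1
    i + (ref - x[i]) / (x[i + 1L] - x[i])
  }
  i <- p
  while (i < right && x[i] > ref) i <- i + 1L
  xr <- if (x[i] > ref) i else {
    i - (ref - x[i]) / (x[i - 1L] - x[i])
  }
  xr - xl
}

#' Find peaks with prominence, width and minimum-distance constraints
#'
#' Internal engine of [detect_licks_offline()]. Candidate peaks are local
#' maxima; those below `min_prominence` or narrower than `min_width_s` at
#' half prominence are discarded; remaining peaks closer than
#' `min_distance_s` are resolved by keeping the taller one.
#'
#' @param x numeric signal.
#' @param fs_hz sampling rate.
#' @param min_distance_s,min_prominence,min_width_s constraints; any may be 0.
#' @return data.frame with columns `index`, `height`, `prominence`,
#'   `width_s`, sorted by index.
#' @keywords internal
find_peaks <- function(x, fs_hz, min_distance_s = 0, min_prominence = 0,
                       min_width_s = 0) {
  cand <- local_maxima(x)
  if (!length(cand)) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width_s = numeric(0)))
  }
  prom <- numeric(length(cand))
  lb <- integer(length(cand)); rb <- integer(length(cand))
  for (k in seq_along(cand)) {
    pr <- peak_prominence(x, cand[k])
    prom[k] <- pr$prominence; lb[k] <- pr$left; rb[k] <- pr$right
  }
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]; lb <- lb[keep]; rb <- rb[keep]
  if (!length(cand)) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width_s = numeric(0)))
  }
  width <- numeric(length(cand))
  for (k in seq_along(cand)) {
    width[k] <- peak_width(x, cand[k], prom[k], lb[k], rb[k]) / fs_hz
  }
  keep <- width >= min_width_s
  cand <- cand[keep]; prom <- prom[keep]; width <- width[keep]
  # minimum distance: accept in order of decreasing height
  if (length(cand) > 1L && min_distance_s > 0) {
    min_dist <- min_distance_s * fs_hz
    ord <- order(x[cand], decreasing = TRUE)
    accepted <- integer(0)
    sel <- logical(length(cand))
    for (k in ord) {
      if (!length(accepted) || all(abs(cand[k] - accepted) >= min_dist)) {
        accepted <- c(accepted, cand[k])
        sel[k] <- TRUE
      }
    }
    cand <- cand[sel]; prom <- prom[sel]; width <- width[sel]
  }
  o <- order(cand)
  data.frame(index = cand[o], height = x[cand][o],
             prominence = prom[o], width_s = width[o])
}
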