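# Magnet-and-three-Hall-sensor ring encoder simulation and the
# sector-decoding decision logic that keeps a tethered recording cable
# untwisted: the magnet angle is decoded into one of 6 radial sectors from
# the three direction fields, and each sector transition commands the motor
# one sector step along the shortest rotation.

#' Ring encoder geometry
#'
#' @param sensor_deg angular positions of the three Hall sensors (degrees,
#'   distinct modulo 360; default 0/120/240).
#' @param n_sectors number of radial sectors partitioning the circle
#'   (default 6).
#' @return object of class `ring_geometry`.
#' @export
ring_geometry <- function(sensor_deg = c(0, 120, 240), n_sectors = 6) {
  if (length(sensor_deg) != 3 || anyNA(sensor_deg)) {
    stop_param("`sensor_deg` must give three sensor angles")
  }
  if (anyDuplicated(sensor_deg %% 360)) {
    stop_param("sensor positions must be distinct modulo 360 degrees")
  }
  check_scalar(n_sectors, "n_sectors", 1)
  structure(list(sensor_deg = as.numeric(sensor_deg),
                 n_sectors = as.integer(n_sectors)),
            class = "ring_geometry")
}

#' Hall-sensor readings for a magnet angle
#'
#' Bipolar cosine response: sensor `i` reads `cos(angle - position_i)`
#' (peak response 1 when the magnet faces the sensor), periodic in 360
#' degrees.
#'
#' @param angle_deg magnet angle(s) in degrees.
#' @param geometry a [ring_geometry].
#' @return numeric vector of 3 readings, or a `length(angle_deg) x 3` matrix.
#' @export
hall_readings <- function(angle_deg, geometry = ring_geometry()) {
  stopifnot(inherits(geometry, "ring_geometry"))
  out <- outer(angle_deg, geometry$sensor_deg,
               function(a, p) cos((a - p) * pi / 180))
  colnames(out) <- paste0("h", seq_along(geometry$sensor_deg))
  if (length(angle_deg) == 1L) out[1L, ] else out
}

#' Decode the magnet sector from three Hall readings
#'
#' The three direction fields are combined into a resultant vector (each
#' reading weighting the unit vector of its sensor axis), whose angle is the
#' magnet orientation estimate; the sector is `floor(angle / 60)` within
#' 0..5. For noise-free readings at angle theta this returns
#' `floor(theta / 60) %% 6`, each sector occupying a contiguous 60-degree
#' arc. All-zero (or vanishing) readings are indeterminate and return `NA`.
#'
#' @param readings numeric vector of 3 Hall readings.
#' @param geometry a [ring_geometry].
#' @return integer sector in `0..5`, or `NA` when indeterminate.
#' @export
sector_decode <- function(readings, geometry = ring_geometry()) {
  stopifnot(inherits(geometry, "ring_geometry"))
  if (length(readings) != 3 || anyNA(readings)) {
    stop_param("`readings` must be three finite values")
  }
  pos <- geometry$sensor_deg * pi / 180
  x <- sum(readings * cos(pos))
  y <- sum(readings * sin(pos))
  if (sqrt(x^2 + y^2) < 1e-9) return(NA_integer_)
  theta <- (atan2(y, x) * 180 / pi) %% 360
  sector_width <- 360 / geometry$n_sectors
  # epsilon nudges exact boundaries into the upper sector (floor convention)
  as.integer(floor(((theta + 1e-7) %% 360) / sector_width)) %%
    geometry$n_sectors
}

#' Motor command for a sector transition
#'
#' One entry of the 6x6 decision matrix: the command is the sign of the
#' shortest signed sector displacement from `prev_sector` to `new_sector`,
#' quantized to one sector step per update (-1, 0 or +1; the ambiguous
#' half-turn displacement is taken positive). An indeterminate sector on
#' either side holds the motor (0).
#'
#' @param prev_sector,new_sector sectors in `0..5`, or `NA`.
#' @param n_sectors number of sectors.
#' @return integer command in `{-1, 0, +1}` (sector steps).
#' @export
decision_step <- function(prev_sector, new_sector, n_sectors = 6) {
  if (is.na(prev_sector) || is.na(new_sector)) return(0L)
  if (!prev_sector %in% 0:(n_sectors - 1) ||
      !new_sector %in% 0:(n_sectors - 1)) {
    stop_param("sectors must lie in 0..n_sectors-1")
  }
  raw <- (new_sector - prev_sector) %% n_sectors
  d <- if (raw > n_sectors / 2) raw - n_sectors else raw
  as.integer(sign(d))
}

#' The full sector-transition decision matrix
#'
#' @param n_sectors number of sectors.
#' @return `n_sectors x n_sectors` integer matrix; entry `[a+1, b+1]` is the
#'   motor command for the transition `a -> b`.
#' @export
decision_matrix <- function(n_sectors = 6) {
  m <- outer(0:(n_sectors - 1), 0:(n_sectors - 1),
             Vectorize(function(a, b) decision_step(a, b, n_sectors)))
  dimnames(m) <- list(from = 0:(n_sectors - 1), to = 0:(n_sectors - 1))
  m
}

#' Closed-loop tracking of a magnet trajectory
#'
#' Simulates the commutator loop: at each trajectory sample the three Hall
#' readings (plus optional Gaussian sensor noise) are decoded into a sector,
#' the decision matrix issues a one-sector motor command, and the cumulative
#' motor angle is accumulated (idealized instant motor). The trajectory
#' should be sampled finely enough that the magnet rotates less than one
#' sector (60 degrees) per step; larger sector jumps are flagged as aliased.
#'
#' @param angle_deg numeric magnet-angle trajectory (degrees, unwrapped).
#' @param geometry a [ring_geometry].
#' @param noise_sigma sensor noise SD, same units as the unit-peak response.
#' @param seed integer seed for the noise draw.
#' @return data.frame log with columns `step`, `angle_deg`, `h1..h3`,
#'   `sector`, `command_step`, `motor_deg` (cumulative command, degrees),
#'   `aliased`. Attribute `"n_aliased"` counts flagged steps.
#' @export
simulate_tracking <- function(angle_deg, geometry = ring_geometry(),
                              noise_sigma = 0, seed = 1) {
  stopifnot(inherits(geometry, "ring_geometry"))
  check_scalar(noise_sigma, "noise_sigma", 0)
  n <- length(angle_deg)
  if (n < 1L) stop_param("trajectory must contain at least one sample")
  h <- hall_readings(angle_deg, geometry)
  if (n == 1L) h <- matrix(h, nrow = 1, dimnames = list(NULL, names(h)))
  if (noise_sigma > 0) {
    h <- h + with_seed(seed, matrix(stats::rnorm(3 * n, sd = noise_sigma),
                                    ncol = 3))
  }
  sector_width <- 360 / geometry$n_sectors
  sectors <- integer(n)
  cmd <- integer(n)
  motor <- numeric(n)
  aliased <- logical(n)
  prev <- NA_integer_
  motor_cum <- 0
  for (i in seq_len(n)) {
    s <- sector_decode(h[i, ], geometry)
    sectors[i] <- s
    if (i == 1L || is.na(s)) {
      cmd[i] <- 0L
    } else {
      if (!is.na(prev)) {
        raw <- (s - prev) %% geometry$n_sectors
        d <- if (raw > geometry$n_sectors / 2) raw - geometry$n_sectors else raw
        aliased[i] <- abs(d) > 1
      }
      cmd[i] <- decision_step(prev, s, geometry$n_sectors)
    }
    if (!is.na(s)) prev <- s
    motor_cum <- motor_cum + cmd[i] * sector_width
    motor[i] <- motor_cum
  }
  if (any(aliased)) {
    warning(sprintf("%d step(s) rotated more than one sector: trajectory undersampled (aliasing)",
                    sum(aliased)))
  }
  out <- data.frame(step = seq_len(n), angle_deg = angle_deg,
                    h1 = h[, 1], h2 = h[, 2], h3 = h[, 3],
                    sector = sectors, command_step = cmd,
                    motor_deg = motor, aliased = aliased)
  attr(out, "n_aliased") <- sum(aliased)
  out
}
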