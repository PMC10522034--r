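#' Construct a reach trajectory object
#'
#' @param time_s,x_cm,y_cm Equal-length numeric vectors; time must be
#'   strictly increasing and at least 3 samples long (nominal 200 Hz).
#' @param start_position,target_position Length-2 (x, y) in cm; the target
#'   sits 10 cm straight ahead of the start by default.
#' @return A `reach_trajectory`.
#' @export
trajectory <- function(time_s, x_cm, y_cm,
                       start_position = c(0, 0),
                       target_position = c(0, 10)) {
  n <- length(time_s)
  if (n < 3L || length(x_cm) != n || length(y_cm) != n)
    stop("need >= 3 samples with equal-length time/x/y", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  structure(list(time_s = time_s, x_cm = x_cm, y_cm = y_cm,
                 start_position = start_position,
                 target_position = target_position),
            class = "reach_trajectory")
}

## Speed from central finite differences of position (forward/backward at the
## ends); no smoothing is applied before thresholding.
trajectory_speed <- function(traj) {
  t <- traj$time_s; x <- traj$x_cm; y <- traj$y_cm
  n <- length(t)
  vx <- numeric(n); vy <- numeric(n)
  idx <- 2:(n - 1L)
  vx[idx] <- (x[idx + 1L] - x[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  vy[idx] <- (y[idx + 1L] - y[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  vx[1] <- (x[2] - x[1]) / (t[2] - t[1])
  vy[1] <- (y[2] - y[1]) / (t[2] - t[1])
  vx[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  vy[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

radial_distance <- function(traj) {
  sqrt((traj$x_cm - traj$start_position[1])^2 +
         (traj$y_cm - traj$start_position[2])^2)
}

#' Detect movement onset
#'
#' First sample whose speed exceeds 5\% of peak speed after the hand has left
#' the 0.5 cm-diameter start region; speed comes from central finite
#' differences of position.
#'
#' @param traj A [trajectory()].
#' @param threshold_frac Fraction of peak speed (default 0.05).
#' @param start_radius_cm Radius of the start region (default 0.25).
#' @return Sample index.
#' @export
detect_onset <- function(traj, threshold_frac = 0.05, start_radius_cm = 0.25) {
  sp <- trajectory_speed(traj)$speed
  rd <- radial_distance(traj)
  exit <- which(rd > start_radius_cm)
  if (!length(exit))
    stop("no movement onset: hand never left the start region", call. = FALSE)
  thr <- threshold_frac * max(sp)
  cand <- which(sp > thr & seq_along(sp) >= exit[1])
  if (!length(cand))
    stop("no movement onset: speed never exceeded threshold after start exit",
         call. = FALSE)
  cand[1]
}

#' Detect movement offset
#'
#' First sample whose speed drops below 5\% of peak speed after the hand has
#' reached 9.5 cm from the start in any radial direction. Reaches that never
#' cross the 9.5 cm gate are incomplete.
#'
#' @param traj A [trajectory()].
#' @param threshold_frac Fraction of peak speed (default 0.05).
#' @param min_reach_cm Radial gate (default 9.5).
#' @return Sample index.
#' @export
detect_offset <- function(traj, threshold_frac = 0.05, min_reach_cm = 9.5) {
  sp <- trajectory_speed(traj)$speed
  rd <- radial_distance(traj)
  gate <- which(rd >= min_reach_cm)
  if (!length(gate))
    stop("incomplete reach: 9.5 cm gate never crossed", call. = FALSE)
  thr <- threshold_frac * max(sp)
  cand <- which(sp < thr & seq_along(sp) >= gate[1])
  if (!length(cand))
    stop("no movement offset: speed never fell below threshold after the gate",
         call. = FALSE)
  cand[1]
}

## Signed angle (degrees, CCW positive) from vector a to vector b.
signed_angle_deg <- function(a, b) {
  cross <- a[1] * b[2] - a[2] * b[1]
  dot <- a[1] * b[1] + a[2] * b[2]
  if (cross == 0 && dot == 0)
    stop("undefined angle: zero-length movement vector", call. = FALSE)
  atan2(cross, dot) * 180 / pi
}

#' Initial movement vector and endpoint hand angle
#'
#' The initial movement vector (IMV) is the signed angle (CCW positive)
#' between the straight start-to-target direction and the instantaneous
#' movement direction at onset; the endpoint hand angle is the signed angle
#' between the start-to-target direction and the start-to-endpoint chord at
#' offset. Feedback integration is their difference (`ep_angle - imv`).
#'
#' @param traj A [trajectory()].
#' @param onset_index,offset_index Marks from [detect_onset()] /
#'   [detect_offset()]; detected automatically when missing.
#' @param chord_samples If > 0, the movement direction at onset is taken as
#'   the chord over the first `chord_samples` samples after onset instead of
#'   the instantaneous velocity direction (documents the ambiguity between
#'   the two readings; default 0 = instantaneous velocity).
#' @return A `kinematic_marks` list: `onset_index`, `offset_index`,
#'   `imv_deg`, `ep_angle_deg`, `fb_integration_deg`.
#' @export
movement_angles <- function(traj, onset_index = NULL, offset_index = NULL,
                            chord_samples = 0L) {
  if (is.null(onset_index)) onset_index <- detect_onset(traj)
  if (is.null(offset_index)) offset_index <- detect_offset(traj)
  if (onset_index >= offset_index)
    stop("onset must precede offset", call. = FALSE)
  opt <- traj$target_position - traj$start_position
  v_onset <- if (chord_samples > 0L) {
    j <- min(onset_index + chord_samples, length(traj$x_cm))
    c(traj$x_cm[j] - traj$x_cm[onset_index],
      traj$y_cm[j] - traj$y_cm[onset_index])
  } else {
    sp <- trajectory_speed(traj)
    c(sp$vx[onset_index], sp$vy[onset_index])
  }
  v_end <- c(traj$x_cm[offset_index], traj$y_cm[offset_index]) -
    traj$start_position
  imv <- signed_angle_deg(opt, v_onset)
  ep <- signed_angle_deg(opt, v_end)
  structure(list(onset_index = onset_index, offset_index = offset_index,
                 imv_deg = imv, ep_angle_deg = ep,
                 fb_integration_deg = ep - imv),
            class = "kinematic_marks")
}

#' Generate a smooth two-segment reach trajectory
#'
#' Fixture generator for the kinematic detectors: a 10 cm reach whose early
#' heading equals `imv_deg` and whose endpoint lies at `ep_angle_deg`
#' relative to the start-to-target direction (CCW positive). The forward
#' progression follows a minimum-jerk profile (so speed rises from and
#' returns to zero); the lateral profile holds the initial heading up to
#' `correction_onset_cm` of forward distance and then blends smoothly (cubic
#' Hermite) to the required endpoint, emulating a midcourse feedback
#' correction. A short terminal dwell is appended so the offset detector has
#' a below-threshold tail.
#'
#' @param imv_deg,ep_angle_deg Target angles, |angle| < 90.
#' @param correction_onset_cm Forward distance at which the correction blends
#'   in (default 5, the midpoint).
#' @param dt Sample interval in seconds (default 0.005, i.e. 200 Hz).
#' @param duration_s Movement duration (default 0.6).
#' @param jitter_sd_cm Optional seeded positional wobble (per-axis peak SD,
#'   cm): smooth low-frequency (1-3 Hz) sinusoidal perturbations gated by the
#'   movement's speed profile — signal-dependent execution wobble rather than
#'   white sensor noise, which would be incompatible with unfiltered velocity
#'   thresholding.
#' @param seed Seed for the jitter.
#' @return A [trajectory()].
#' @export
make_trajectory <- function(imv_deg, ep_angle_deg, correction_onset_cm = 5,
                            dt = 0.005, duration_s = 0.6, jitter_sd_cm = 0,
                            seed = NULL) {
  if (abs(imv_deg) >= 90 || abs(ep_angle_deg) >= 90)
    stop("|angles| must be < 90 degrees", call. = FALSE)
  L <- 10
  tt <- seq(0, duration_s, by = dt)
  tau <- tt / duration_s
  fwd <- L * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)  # minimum-jerk progression
  ## lateral offset in the CCW-positive sense: lat = -x for a +y target
  s0 <- correction_onset_cm
  k1 <- tan(imv_deg * pi / 180)
  lat_end <- L * tan(ep_angle_deg * pi / 180)
  lat <- ifelse(fwd <= s0, fwd * k1, NA_real_)
  post <- which(fwd > s0)
  if (length(post)) {
    u <- (fwd[post] - s0) / (L - s0)
    h00 <- 2 * u^3 - 3 * u^2 + 1
    h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2
    h11 <- u^3 - u^2
    k_end <- (lat_end - s0 * k1) / (L - s0)  # chord slope of the second leg
    lat[post] <- h00 * (s0 * k1) + h10 * (L - s0) * k1 +
      h01 * lat_end + h11 * (L - s0) * k_end
  }
  ## terminal dwell: 50 ms stationary tail
  n_dwell <- max(2L, round(0.05 / dt))
  tt <- c(tt, tt[length(tt)] + dt * seq_len(n_dwell))
  fwd <- c(fwd, rep(fwd[length(fwd)], n_dwell))
  lat <- c(lat, rep(lat[length(lat)], n_dwell))
  x <- -lat
  y <- fwd
  if (jitter_sd_cm > 0) {
    vprof <- c(0, diff(fwd)) / dt
    gate <- vprof / max(vprof)   # signal-dependent: silent at rest
    wobble <- with_seed(seed, {
      lapply(1:2, function(ax) {
        f <- stats::runif(2L, 1, 3)
        ph <- stats::runif(2L, 0, 2 * pi)
        w <- sin(2 * pi * f[1] * tt + ph[1]) + sin(2 * pi * f[2] * tt + ph[2])
        gate * w * jitter_sd_cm / stats::sd(w)
      })
    })
    x <- x + wobble[[1L]]
    y <- y + wobble[[2L]]
  }
  trajectory(tt, x, y)
}

#' Write / read a trajectory as a delimited table
#'
#' @param traj A [trajectory()].
#' @param file Path.
#' @return `read_trajectory` returns a [trajectory()] (default start/target
#'   geometry).
#' @export
write_trajectory <- function(traj, file) {
  utils::write.table(data.frame(time_s = traj$time_s, x_cm = traj$x_cm,
                                y_cm = traj$y_cm),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE)
  trajectory(df$time_s, df$x_cm, df$y_cm)
}
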