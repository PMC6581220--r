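#' Platform bounds
#'
#' Extents of the horizontal platform the animal moves on (10 x 9 cm by
#' default); trajectories are reflected at `+/- extent/2`.
#'
#' @param x_extent,y_extent Platform extents in mm.
#' @export
platform_bounds <- function(x_extent = 100, y_extent = 90) {
  stopifnot(x_extent > 0, y_extent > 0)
  structure(list(x_extent = x_extent, y_extent = y_extent),
            class = "platform_bounds")
}

#' Single rigid-body pose
#'
#' A pose maps head-frame coordinates to scanner coordinates:
#' `x_scanner = R(q) x_head + translation`.
#'
#' @param t_ms Time stamp in ms (may be `NA` for a time-free pose).
#' @param quaternion Unit quaternion (w, x, y, z).
#' @param translation Translation in mm.
#' @param accepted Validation flag.
#' @export
rigid_pose <- function(t_ms = NA_real_, quaternion = c(1, 0, 0, 0),
                       translation = c(0, 0, 0), accepted = TRUE) {
  if (abs(sqrt(sum(quaternion^2)) - 1) > 1e-9)
    stop("quaternion must have unit norm")
  structure(list(t_ms = t_ms, quaternion = quaternion,
                 translation = as.numeric(translation),
                 rotation = quat_to_mat(quaternion),
                 accepted = isTRUE(accepted)),
            class = "rigid_pose")
}

#' Time-ordered rigid trajectory
#'
#' @param t_ms Strictly increasing pose times, ms.
#' @param quaternions n x 4 matrix of unit quaternions (w, x, y, z).
#' @param translations n x 3 matrix of translations, mm.
#' @param accepted Logical vector of per-pose validation flags.
#' @param frame_duration_ms Duration of the tracking frame each pose
#'   represents.
#' @export
trajectory <- function(t_ms, quaternions, translations, accepted = NULL,
                       frame_duration_ms = 32) {
  quaternions <- as.matrix(quaternions)
  translations <- as.matrix(translations)
  n <- length(t_ms)
  stopifnot(nrow(quaternions) == n, nrow(translations) == n,
            ncol(quaternions) == 4, ncol(translations) == 3)
  if (n > 1 && any(diff(t_ms) <= 0)) stop("pose times must strictly increase")
  if (any(abs(sqrt(rowSums(quaternions^2)) - 1) > 1e-9))
    stop("quaternions must have unit norm")
  if (is.null(accepted)) accepted <- rep(TRUE, n)
  structure(list(t_ms = as.numeric(t_ms), quaternions = quaternions,
                 translations = translations, accepted = as.logical(accepted),
                 frame_duration_ms = frame_duration_ms),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d poses over %.1f s, %.0f%% accepted\n",
              length(x$t_ms), diff(range(x$t_ms)) / 1000,
              100 * mean(x$accepted)))
  invisible(x)
}

# Discretised Ornstein-Uhlenbeck increments (stationary unit variance).
ou_series <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  b <- sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n)
  for (i in 2:n) x[i] <- a * x[i - 1] + b * innov[i]
  x
}

# Reflect coordinates into [-half, half].
reflect_into <- function(x, half) {
  if (half <= 0) return(x * 0)
  y <- (x + half) %% (4 * half)
  y[y < 0] <- y[y < 0] + 4 * half
  ifelse(y > 2 * half, 4 * half - y, y) - half
}

#' Sample a bounded random head trajectory
#'
#' Generates a smooth bounded random walk emulating a mouse exploring a
#' horizontal platform: planar velocity follows an Ornstein-Uhlenbeck
#' process, alternating rest/move bouts produce the sporadic locomotion seen
#' at baseline, positions are reflected at the platform limits, the head bobs
#' slightly in z, and rotation is yaw-dominant. Velocities are rescaled so
#' the time-averaged planar speed (including rests) equals `mean_speed`.
#'
#' @param duration_ms Scan duration, ms.
#' @param mean_speed Target average head speed, cm/s (the baseline regime is
#'   about 2 cm/s, the locomotor-challenge regime about 4 cm/s).
#' @param bounds A [platform_bounds()].
#' @param rotation_scale Yaw angular-velocity scale, degrees/s.
#' @param rest_fraction Fraction of time spent resting (0 = constant motion).
#' @param seed Optional RNG seed for reproducibility.
#' @param frame_duration_ms Pose spacing, ms (32 ms matches the tracking
#'   frame).
#' @param z_amplitude Std. dev. of vertical head bobbing, mm.
#' @return A [trajectory()] with one pose per frame covering
#'   `[0, duration_ms]`; all poses are flagged accepted (ground truth).
#' @export
sample_trajectory <- function(duration_ms, mean_speed = 2,
                              bounds = platform_bounds(),
                              rotation_scale = 30, rest_fraction = 0.4,
                              seed = NULL, frame_duration_ms = 32,
                              z_amplitude = 1.0) {
  if (mean_speed < 0) stop("mean_speed must be nonnegative")
  stopifnot(duration_ms > 0, rest_fraction >= 0, rest_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration_ms / frame_duration_ms) + 1
  t_ms <- (seq_len(n) - 1) * frame_duration_ms
  dt <- frame_duration_ms / 1000

  if (mean_speed == 0) {
    vx <- vy <- numeric(n)
    moving <- rep(FALSE, n)
  } else {
    vx <- ou_series(n, dt, tau = 0.5)
    vy <- ou_series(n, dt, tau = 0.5)
    if (rest_fraction > 0) {
      # two-state Markov bouts; mean rest bout ~2 s
      p_rm <- dt / 2
      p_mr <- p_rm * rest_fraction / (1 - rest_fraction)
      moving <- logical(n)
      moving[1] <- stats::runif(1) > rest_fraction
      u <- stats::runif(n)
      for (i in 2:n)
        moving[i] <- if (moving[i - 1]) u[i] > p_mr else u[i] < p_rm
    } else moving <- rep(TRUE, n)
    vx[!moving] <- 0
    vy[!moving] <- 0
    sp <- sqrt(vx^2 + vy^2)
    if (mean(sp) > 0) {
      sc <- mean_speed / mean(sp)
      vx <- vx * sc
      vy <- vy * sc
    }
  }
  # integrate (cm/s -> mm per frame) and reflect at the platform limits
  x <- reflect_into(cumsum(c(0, vx[-n])) * dt * 10, bounds$x_extent / 2)
  y <- reflect_into(cumsum(c(0, vy[-n])) * dt * 10, bounds$y_extent / 2)
  # smooth vertical bobbing: integrated OU velocity reflected into
  # +/- z_amplitude (position-level white jitter would inflate the speed)
  z <- if (mean_speed > 0 && z_amplitude > 0) {
    vz <- ou_series(n, dt, tau = 0.5) * 0.2   # ~2 mm/s vertical speed scale
    reflect_into(cumsum(c(0, vz[-n])) * dt * 10, z_amplitude)
  } else numeric(n)

  if (rotation_scale > 0 && mean_speed > 0) {
    wyaw <- ou_series(n, dt, tau = 0.7) * rotation_scale * pi / 180
    wyaw[!moving] <- 0
    yaw <- cumsum(c(0, wyaw[-n])) * dt
    pitch <- ou_series(n, dt, tau = 1) * 5 * pi / 180
    roll <- ou_series(n, dt, tau = 1) * 5 * pi / 180
  } else yaw <- pitch <- roll <- numeric(n)

  qz <- cbind(cos(yaw / 2), 0, 0, sin(yaw / 2))
  qy <- cbind(cos(pitch / 2), 0, sin(pitch / 2), 0)
  qx <- cbind(cos(roll / 2), sin(roll / 2), 0, 0)
  Q <- quat_normalize(quat_mul_rows(qz, quat_mul_rows(qy, qx)))

  trajectory(t_ms, Q, cbind(x, y, z), rep(TRUE, n), frame_duration_ms)
}

# Row-wise Hamilton product of quaternion matrices.
quat_mul_rows <- function(A, B) {
  w <- A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4]
  x <- A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3]
  y <- A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2]
  z <- A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1]
  cbind(w, x, y, z)
}

#' Interpolate poses at arbitrary times
#'
#' Linear interpolation of translations and spherical-linear (slerp)
#' interpolation of rotations between the bracketing *accepted* poses. Times
#' falling in a gap between accepted poses longer than `max_gap_ms` are
#' flagged not-ok; if `fallback_nearest_ms > 0`, such times within that
#' distance of an accepted pose take the nearest accepted pose instead.
#'
#' @param traj A [trajectory()].
#' @param t_ms Vector of query times, ms.
#' @param max_gap_ms Longest accepted-pose gap that is still interpolated.
#' @param fallback_nearest_ms Snap distance for times in long gaps.
#' @return List with `quaternions`, `translations` and logical `ok`.
#' @export
interpolate_poses <- function(traj, t_ms, max_gap_ms = Inf,
                              fallback_nearest_ms = 0) {
  acc <- which(traj$accepted)
  if (!length(acc)) stop("trajectory has no accepted poses")
  ta <- traj$t_ms[acc]
  Qa <- traj$quaternions[acc, , drop = FALSE]
  Ta <- traj$translations[acc, , drop = FALSE]
  m <- length(t_ms)
  na <- length(ta)

  i <- findInterval(t_ms, ta)
  lo <- pmax(i, 1)
  hi <- pmin(i + 1, na)
  alpha <- numeric(m)
  ok <- rep(TRUE, m)

  inside <- i >= 1 & i < na
  gap <- ta[hi] - ta[lo]
  alpha[inside] <- (t_ms[inside] - ta[lo[inside]]) / gap[inside]
  long <- inside & gap > max_gap_ms
  before <- i < 1
  after <- i >= na
  # clamp edges: beyond the span, only the nearest pose is available
  edge_far <- (before & (ta[1] - t_ms) > max_gap_ms) |
    (after & (t_ms - ta[na]) > max_gap_ms)
  ok[long | edge_far] <- FALSE
  alpha[before] <- 0
  alpha[after] <- 0
  lo[after] <- na
  hi[after] <- na

  if (fallback_nearest_ms > 0 && any(!ok)) {
    bad <- which(!ok)
    d_lo <- abs(t_ms[bad] - ta[lo[bad]])
    d_hi <- abs(ta[hi[bad]] - t_ms[bad])
    near <- ifelse(d_lo <= d_hi, lo[bad], hi[bad])
    dist <- pmin(d_lo, d_hi)
    snap <- dist <= fallback_nearest_ms
    if (any(snap)) {
      idx <- bad[snap]
      lo[idx] <- near[snap]
      hi[idx] <- near[snap]
      alpha[idx] <- 0
      ok[idx] <- TRUE
    }
  }

  Q <- quat_slerp_rows(Qa[lo, , drop = FALSE], Qa[hi, , drop = FALSE], alpha)
  Tr <- (1 - alpha) * Ta[lo, , drop = FALSE] + alpha * Ta[hi, , drop = FALSE]
  list(quaternions = Q, translations = Tr, ok = ok)
}

#' Interpolate a single pose
#'
#' @inheritParams interpolate_poses
#' @return A [rigid_pose()], or `NULL` if `t_ms` falls in a gap longer than
#'   `max_gap_ms` (the caller is expected to drop events there).
#' @export
interpolate_pose <- function(traj, t_ms, max_gap_ms = Inf) {
  r <- interpolate_poses(traj, t_ms, max_gap_ms)
  if (!r$ok[1]) return(NULL)
  rigid_pose(t_ms, quat_normalize(r$quaternions[1, ]), r$translations[1, ])
}
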