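#' List-mode coincidence event stream
#'
#' Events are timestamped detector-pair coincidences. Timestamps are stored
#' in integer microseconds (as doubles) so that 32-ms framing is exact.
#'
#' @param t_us Nondecreasing event times, integer microseconds.
#' @param crystal_a,crystal_b 1-based crystal indices (distinct per event).
#' @param geom_name Scanner geometry name the indices refer to.
#' @param duration_ms Scan duration.
#' @param rate_cps Emission rate used for simulation (counts/s), if known.
#' @param n_emitted Number of emitted decays behind the stream, if known.
#' @export
event_stream <- function(t_us, crystal_a, crystal_b, geom_name = "desk",
                         duration_ms = NA_real_, rate_cps = NA_real_,
                         n_emitted = NA_real_) {
  t_us <- as.numeric(t_us)
  crystal_a <- as.integer(crystal_a)
  crystal_b <- as.integer(crystal_b)
  n <- length(t_us)
  stopifnot(length(crystal_a) == n, length(crystal_b) == n)
  if (n > 1 && any(diff(t_us) < 0)) stop("event times must be nondecreasing")
  if (any(crystal_a == crystal_b)) stop("coincidence crystals must be distinct")
  if (any(crystal_a < 1) || any(crystal_b < 1))
    stop("crystal indices are 1-based")
  structure(list(t_us = t_us, crystal_a = crystal_a, crystal_b = crystal_b,
                 geom_name = geom_name, duration_ms = duration_ms,
                 rate_cps = rate_cps, n_emitted = n_emitted),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events over %.1f s (geometry '%s')\n",
              length(x$t_us), x$duration_ms / 1000, x$geom_name))
  invisible(x)
}

#' Number of events in a stream
#' @param x An `event_stream`.
#' @export
n_events <- function(x) length(x$t_us)

# Subset a stream by event index, preserving the header.
subset_events <- function(ev, idx) {
  event_stream(ev$t_us[idx], ev$crystal_a[idx], ev$crystal_b[idx],
               ev$geom_name, ev$duration_ms, ev$rate_cps, ev$n_emitted)
}

#' Simulate a list-mode acquisition
#'
#' Monte-Carlo forward model of the acquisition: decays occur as a Poisson
#' process at `rate_cps`; each decay originates either from the phantom
#' (voxel sampled proportional to activity, position uniform within the
#' voxel) or from a fiducial marker (position drawn from an isotropic
#' Gaussian blob whose FWHM equals the marker diameter, which avoids
#' sub-voxel aliasing); the emission point is mapped to scanner coordinates
#' by the pose interpolated at the decay time; an annihilation direction is
#' drawn isotropically and the event is kept only if both photons intersect
#' the detector cylinder within the axial extent, on two distinct crystals.
#' If an attenuation map is supplied, events are thinned with survival
#' probability `exp(-integral of mu along the LOR)` through the (moving)
#' body. Scatter, randoms, positron range and depth-of-interaction are not
#' modelled.
#'
#' @param activity A [voxel_image()] of activity (kBq/cm^3) in the head
#'   frame, or `NULL` for markers only.
#' @param markers A [marker_model()], or `NULL` for a marker-free phantom.
#' @param traj A [trajectory()] covering `[0, duration_ms]`.
#' @param geom A [scanner_geometry()].
#' @param mumap Optional [mu_map()] in the head frame.
#' @param duration_ms Scan duration, ms.
#' @param rate_cps Decay (emission) rate in counts per second; the detected
#'   rate is lower by the geometric acceptance fraction.
#' @param seed Optional RNG seed; fixed seeds give bit-identical streams.
#' @param chunk_size Number of decays processed per chunk (memory control).
#' @return List with `events` (an [event_stream()]) and `truth` (the input
#'   trajectory, i.e. the ground-truth poses).
#' @export
simulate_listmode <- function(activity, markers, traj, geom, mumap = NULL,
                              duration_ms, rate_cps, seed = NULL,
                              chunk_size = 2e6) {
  stopifnot(inherits(geom, "scanner_geometry"), inherits(traj, "trajectory"))
  if (rate_cps <= 0) stop("rate_cps must be positive")
  if (max(traj$t_ms) < duration_ms - traj$frame_duration_ms)
    stop("trajectory does not cover the scan duration")
  if (!is.null(seed)) set.seed(seed)

  act_total <- if (is.null(activity)) 0 else
    sum(activity$values) * voxel_volume_cm3(activity$grid)
  mark_total <- if (is.null(markers)) 0 else sum(markers$activities)
  if (act_total + mark_total <= 0)
    stop("nothing to emit: phantom and markers carry no activity")
  p_marker <- mark_total / (act_total + mark_total)

  n_emit <- stats::rpois(1, rate_cps * duration_ms / 1000)
  t_all <- sort(stats::runif(n_emit, 0, duration_ms))

  nc <- geom$n_crystals_per_ring
  nr <- geom$n_rings
  R <- geom$ring_radius
  pitch <- geom$crystal_axial_pitch
  zc0 <- -(nr - 1) / 2 * pitch          # centre of ring 0
  marker_sigma <- if (is.null(markers)) 0 else markers$diameter / 2.355

  out_t <- list(); out_a <- list(); out_b <- list(); nseg <- 0
  start <- 1
  while (start <= n_emit) {
    stop_i <- min(start + chunk_size - 1, n_emit)
    tt <- t_all[start:stop_i]
    m <- length(tt)

    is_mark <- stats::runif(m) < p_marker
    pos <- matrix(0, m, 3)
    if (any(!is_mark) && !is.null(activity)) {
      np <- sum(!is_mark)
      vox <- sample.int(length(activity$values), np, replace = TRUE,
                        prob = as.vector(activity$values))
      s <- activity$grid$shape
      i3 <- arrayInd(vox, s) - 1L
      jit <- matrix(stats::runif(3 * np), np, 3)
      pos[!is_mark, ] <- rep(activity$grid$origin, each = np) +
        (i3 + jit) * rep(activity$grid$voxel_size, each = np)
    }
    if (any(is_mark)) {
      nm <- sum(is_mark)
      mk <- sample.int(4, nm, replace = TRUE, prob = markers$activities)
      pos[is_mark, ] <- markers$points[mk, , drop = FALSE] +
        matrix(stats::rnorm(3 * nm, sd = marker_sigma), nm, 3)
    }

    ip <- interpolate_poses(traj, tt)
    pos_s <- rotate_rows_quat(ip$quaternions, pos) + ip$translations

    # isotropic annihilation direction
    cz <- stats::runif(m, -1, 1)
    phi <- stats::runif(m, 0, 2 * pi)
    st <- sqrt(1 - cz^2)
    d <- cbind(st * cos(phi), st * sin(phi), cz)

    # intersect the full line with the detector cylinder
    a2 <- d[, 1]^2 + d[, 2]^2
    b2 <- 2 * (pos_s[, 1] * d[, 1] + pos_s[, 2] * d[, 2])
    c2 <- pos_s[, 1]^2 + pos_s[, 2]^2 - R^2
    disc <- b2^2 - 4 * a2 * c2
    okg <- disc > 0 & a2 > 1e-12
    sq <- sqrt(pmax(disc, 0))
    s1 <- (-b2 - sq) / (2 * a2)
    s2 <- (-b2 + sq) / (2 * a2)
    okg <- okg & s1 < 0 & s2 > 0       # source must lie between the photons

    z1 <- pos_s[, 3] + s1 * d[, 3]
    z2 <- pos_s[, 3] + s2 * d[, 3]
    r1 <- round((z1 - zc0) / pitch)
    r2 <- round((z2 - zc0) / pitch)
    okg <- okg & r1 >= 0 & r1 < nr & r2 >= 0 & r2 < nr

    ang1 <- atan2(pos_s[, 2] + s1 * d[, 2], pos_s[, 1] + s1 * d[, 1])
    ang2 <- atan2(pos_s[, 2] + s2 * d[, 2], pos_s[, 1] + s2 * d[, 1])
    c1 <- (round(ang1 / (2 * pi / nc))) %% nc
    c2i <- (round(ang2 / (2 * pi / nc))) %% nc
    id1 <- as.integer(r1 * nc + c1 + 1)
    id2 <- as.integer(r2 * nc + c2i + 1)
    okg <- okg & id1 != id2
    okg[is.na(okg)] <- FALSE

    keep <- which(okg)
    if (length(keep) && !is.null(mumap)) {
      # attenuate along the LOR through the moving body: transform the
      # crystal endpoints into the head frame and integrate mu there
      cpos <- crystal_positions(geom)
      qc <- cbind(ip$quaternions[keep, 1], -ip$quaternions[keep, 2:4])
      e1 <- rotate_rows_quat(qc, cpos[id1[keep], , drop = FALSE] -
                               ip$translations[keep, , drop = FALSE])
      e2 <- rotate_rows_quat(qc, cpos[id2[keep], , drop = FALSE] -
                               ip$translations[keep, , drop = FALSE])
      g <- mumap$grid
      integ <- cpp_line_integrals(e1, e2, g$shape, g$voxel_size, g$origin,
                                  as.vector(mumap$mu))
      surv <- exp(-integ / 10)          # mu is cm^-1, lengths are mm
      keep <- keep[stats::runif(length(keep)) < surv]
    }

    if (length(keep)) {
      nseg <- nseg + 1
      out_t[[nseg]] <- round(tt[keep] * 1000)
      out_a[[nseg]] <- id1[keep]
      out_b[[nseg]] <- id2[keep]
    }
    start <- stop_i + 1
  }

  ev <- event_stream(
    t_us = if (nseg) unlist(out_t) else numeric(0),
    crystal_a = if (nseg) unlist(out_a) else integer(0),
    crystal_b = if (nseg) unlist(out_b) else integer(0),
    geom_name = geom$name, duration_ms = duration_ms,
    rate_cps = rate_cps, n_emitted = n_emit)
  list(events = ev, truth = traj)
}
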