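#' Reconstruction configuration
#'
#' Defaults follow the production protocol: 16 subsets, 8 iterations,
#' image-space Gaussian resolution modelling. `psf_sigma_mm = NA` resolves to
#' half the transaxial crystal pitch of the geometry in use.
#'
#' @param n_subsets Number of ordered subsets (events are assigned by event
#'   index modulo `n_subsets`).
#' @param n_iterations Number of full iterations.
#' @param psf_sigma_mm Isotropic Gaussian resolution-model sigma, mm; 0
#'   disables resolution modelling, `NA` uses half the crystal pitch.
#' @param outline_threshold_frac Fraction of the robust maximum used for body
#'   outline masking.
#' @param nonneg_floor Values below this are clamped to it after
#'   reconstruction.
#' @export
recon_config <- function(n_subsets = 16, n_iterations = 8,
                         psf_sigma_mm = NA_real_,
                         outline_threshold_frac = 0.10, nonneg_floor = 0) {
  stopifnot(n_subsets >= 1, n_iterations >= 1,
            outline_threshold_frac > 0, outline_threshold_frac < 1)
  if (!is.na(psf_sigma_mm) && psf_sigma_mm < 0)
    stop("psf_sigma_mm must be >= 0")
  structure(list(n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations),
                 psf_sigma_mm = psf_sigma_mm,
                 outline_threshold_frac = outline_threshold_frac,
                 nonneg_floor = nonneg_floor),
            class = "recon_config")
}

resolve_psf <- function(cfg, geom) {
  if (!is.na(cfg$psf_sigma_mm)) return(cfg$psf_sigma_mm)
  pitch <- 2 * pi * geom$ring_radius / geom$n_crystals_per_ring
  pitch / 2
}

#' Siddon ray trace through a voxel grid
#'
#' Exact intersection lengths of the segment `p1 -> p2` with every voxel it
#' crosses. A segment missing the grid returns zero rows.
#'
#' @param p1,p2 Endpoints, mm.
#' @param grid A [grid_spec()].
#' @return List with `index` (1-based column-major voxel indices) and
#'   `length_mm`.
#' @export
raytrace <- function(p1, p2, grid) {
  stopifnot(all(is.finite(p1)), all(is.finite(p2)))
  cpp_raytrace(as.numeric(p1), as.numeric(p2), grid$shape, grid$voxel_size,
               grid$origin)
}

#' Attenuation correction factor along a line of response
#'
#' `exp` of the line integral of the attenuation coefficient (cm^-1) along
#' the segment; always >= 1.
#'
#' @param mumap A [mu_map()].
#' @param p1,p2 LOR endpoints, mm.
#' @export
acf_lor <- function(mumap, p1, p2) {
  g <- mumap$grid
  integ <- cpp_line_integrals(matrix(as.numeric(p1), 1), matrix(as.numeric(p2), 1),
                              g$shape, g$voxel_size, g$origin,
                              as.vector(mumap$mu))
  exp(integ / 10)
}

all_crystal_pairs <- function(geom, crystal_step = 1L) {
  ids <- seq(1L, n_crystals(geom), by = crystal_step)
  n <- length(ids)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  cbind(ids[i], ids[j])
}

#' Scanner sensitivity image
#'
#' Backprojection over all (optionally subsampled) detector pairs of the
#' geometric weight times, when an attenuation map is given, the attenuation
#' survival `exp(-integral mu dl)`. This is the normalisation term of
#' list-mode MLEM; per-event attenuation factors cancel in the update ratio,
#' so attenuation enters the reconstruction through this image.
#'
#' @param geom A [scanner_geometry()].
#' @param grid Reconstruction [grid_spec()].
#' @param mumap Optional [mu_map()] on the same grid frame.
#' @param crystal_step Subsampling stride over crystals (1 = all pairs).
#' @param aperture Model the finite crystal aperture by offsetting each LOR
#'   endpoint within the crystal pitch (deterministic low-discrepancy
#'   offsets). Centre-to-centre backprojection (the default) matches the
#'   discrete LORs events actually arrive on and is self-consistent for
#'   static reconstruction, but it carries discrete-LOR aliasing — the
#'   sensitivity oscillates voxel to voxel — which breaks interpolation;
#'   the aperture model produces the smooth sensitivity needed when the
#'   image is resampled under motion.
#' @return A [voxel_image()] holding the sensitivity as a per-mm^3 density;
#'   positive inside the field of view.
#' @export
compute_sensitivity <- function(geom, grid, mumap = NULL, crystal_step = 1L,
                                aperture = FALSE) {
  cpos <- crystal_positions(geom)
  pr <- all_crystal_pairs(geom, crystal_step)
  P1 <- cpos[pr[, 1], , drop = FALSE]
  P2 <- cpos[pr[, 2], , drop = FALSE]
  if (aperture) {
    np <- nrow(pr)
    # Weyl sequences give reproducible, well-spread sub-crystal offsets
    u <- cbind((seq_len(np) * sqrt(2)) %% 1, (seq_len(np) * sqrt(3)) %% 1,
               (seq_len(np) * sqrt(5)) %% 1, (seq_len(np) * sqrt(7)) %% 1) - 0.5
    pt <- 2 * pi * geom$ring_radius / geom$n_crystals_per_ring
    pz <- geom$crystal_axial_pitch
    jit <- function(P, ut, uz) {
      phi <- atan2(P[, 2], P[, 1])
      P + cbind(-sin(phi), cos(phi), 0) * (ut * pt) + cbind(0, 0, uz * pz)
    }
    P1 <- jit(P1, u[, 1], u[, 2])
    P2 <- jit(P2, u[, 3], u[, 4])
  }
  w <- rep(1, nrow(pr))
  if (!is.null(mumap)) {
    g <- mumap$grid
    integ <- cpp_line_integrals(P1, P2, g$shape, g$voxel_size, g$origin,
                                as.vector(mumap$mu))
    w <- exp(-integ / 10)
  }
  s <- cpp_backproject(P1, P2, w, grid$shape, grid$voxel_size, grid$origin)
  if (all(s == 0))
    stop("grid is entirely outside the scanner field of view")
  # normalise to a per-mm^3 density so sensitivities computed on different
  # voxel sizes agree pointwise (needed when resampling under motion)
  voxel_image(grid, s / prod(grid$voxel_size))
}

event_endpoints <- function(events, geom) {
  cpos <- crystal_positions(geom)
  if (length(events$crystal_a) &&
      (max(events$crystal_a, events$crystal_b) > nrow(cpos)))
    stop("event crystal indices exceed the geometry")
  list(P1 = cpos[events$crystal_a, , drop = FALSE],
       P2 = cpos[events$crystal_b, , drop = FALSE])
}

osem_core <- function(P1, P2, grid, cfg, sens_values, psf_sigma,
                      weights = NULL, init = NULL) {
  s <- sens_values
  if (psf_sigma > 0)
    s <- cpp_gauss_blur(s, grid$shape, grid$voxel_size, psf_sigma)
  x <- cpp_osem(P1, P2, grid$shape, grid$voxel_size, grid$origin, s,
                cfg$n_subsets, cfg$n_iterations, psf_sigma, init, weights)
  x
}

#' List-mode OSEM reconstruction
#'
#' Ordered-subsets expectation maximisation operating directly on list-mode
#' events. Subsets are formed by event index modulo `n_subsets`; the forward
#' model per event is the Siddon trace convolved (in image space) with an
#' isotropic Gaussian of `psf_sigma_mm`; updates are multiplicative, so the
#' result is nonnegative and, for one subset with no resolution model,
#' `sum(image * sensitivity)` equals the event count after every full
#' iteration. The provided sensitivity image is blurred with the same kernel
#' internally when resolution modelling is on.
#'
#' @param events An [event_stream()].
#' @param geom A [scanner_geometry()].
#' @param grid Reconstruction [grid_spec()].
#' @param cfg A [recon_config()].
#' @param sensitivity A [voxel_image()] from [compute_sensitivity()]
#'   (computed on demand when `NULL`).
#' @param weights Optional per-event multiplicities.
#' @param init Optional initial image ([voxel_image()]).
#' @return A [voxel_image()].
#' @export
osem_listmode <- function(events, geom, grid, cfg = recon_config(),
                          sensitivity = NULL, weights = NULL, init = NULL) {
  if (!n_events(events)) stop("empty event stream")
  if (is.null(sensitivity)) sensitivity <- compute_sensitivity(geom, grid)
  if (!same_grid(sensitivity$grid, grid)) stop("sensitivity grid mismatch")
  ep <- event_endpoints(events, geom)
  psf <- resolve_psf(cfg, geom)
  x <- osem_core(ep$P1, ep$P2, grid, cfg, as.vector(sensitivity$values), psf,
                 weights, if (!is.null(init)) as.vector(init$values))
  x <- pmax(x, cfg$nonneg_floor)
  voxel_image(grid, x)
}

#' Number of short frames in a scan
#'
#' Frames are half-open intervals `[k * frame_ms, (k + 1) * frame_ms)`.
#' @param duration_ms Scan duration, ms.
#' @param frame_ms Frame duration, ms (32 ms default).
#' @export
n_short_frames <- function(duration_ms, frame_ms = 32) {
  as.integer(ceiling(duration_ms / frame_ms))
}

frame_index <- function(t_us, frame_ms = 32) {
  as.integer(t_us %/% (frame_ms * 1000))
}

#' Short-time-frame reconstructions
#'
#' Partitions the stream into half-open 32-ms frames and reconstructs each
#' with a fast configuration on a coarse grid; these frames are the substrate
#' of point-source tracking. Empty frames yield (shared) zero images.
#'
#' @param events An [event_stream()].
#' @param geom A [scanner_geometry()].
#' @param grid_coarse Coarse [grid_spec()] covering the field of view.
#' @param frame_ms Frame duration, ms.
#' @param quick_cfg Fast [recon_config()] (few iterations, no PSF).
#' @param sensitivity Optional precomputed sensitivity on `grid_coarse`; by
#'   default a *flat* sensitivity is used — point detection only needs local
#'   maxima, and the true sensitivity correction amplifies noise at the FOV
#'   edge in 32-ms frames.
#' @return List of `list(frame_start_ms, image)` of length
#'   `n_short_frames(duration)`.
#' @export
short_frame_images <- function(events, geom,
                               grid_coarse = grid_preset("desk-coarse"),
                               frame_ms = 32,
                               quick_cfg = recon_config(n_subsets = 1,
                                                        n_iterations = 6,
                                                        psf_sigma_mm = 0),
                               sensitivity = NULL) {
  stopifnot(frame_ms > 0)
  if (is.null(sensitivity))
    sensitivity <- voxel_image(grid_coarse, array(1, grid_coarse$shape))
  nf <- n_short_frames(events$duration_ms, frame_ms)
  fidx <- frame_index(events$t_us, frame_ms)
  zero_img <- voxel_image(grid_coarse, array(0, grid_coarse$shape))
  ep <- event_endpoints(events, geom)
  sv <- as.vector(sensitivity$values)
  psf <- resolve_psf(quick_cfg, geom)
  out <- vector("list", nf)
  split_idx <- split(seq_along(fidx), factor(fidx, levels = 0:(nf - 1)))
  for (k in seq_len(nf)) {
    idx <- split_idx[[k]]
    img <- if (length(idx)) {
      voxel_image(grid_coarse,
                  osem_core(ep$P1[idx, , drop = FALSE],
                            ep$P2[idx, , drop = FALSE],
                            grid_coarse, quick_cfg, sv, psf))
    } else zero_img
    out[[k]] <- list(frame_start_ms = (k - 1) * frame_ms, image = img)
  }
  out
}

is_identity_trajectory <- function(traj) {
  acc <- traj$accepted
  all(acc) &&
    all(abs(traj$translations) < 1e-12) &&
    all(abs(abs(traj$quaternions[, 1]) - 1) < 1e-12)
}

#' Motion-corrected list-mode reconstruction
#'
#' Event-by-event motion correction: each event's LOR endpoints are
#' transformed by the inverse of the pose interpolated at the event time,
#' bringing the data into the head reference frame before the OSEM update.
#' Events in gaps between accepted poses longer than `max_gap_ms` are
#' excluded. The sensitivity image is the exposure-time-weighted average of
#' the static sensitivity resampled through the accepted poses.
#'
#' @param events An [event_stream()].
#' @param traj A [trajectory()] with at least one accepted pose.
#' @param geom A [scanner_geometry()].
#' @param grid Head-frame reconstruction [grid_spec()].
#' @param cfg A [recon_config()].
#' @param sensitivity Optional precomputed *static* sensitivity on `grid`
#'   (used only for the identity-trajectory shortcut).
#' @param fov_sensitivity Optional precomputed static sensitivity on an
#'   FOV-wide grid (see [fov_sensitivity_grid()]); computed on demand. The
#'   moving-head sensitivity is obtained by resampling this image through
#'   each sampled pose, so it must cover the head grid under every pose.
#' @param max_gap_ms Longest pose gap that is still interpolated; defaults
#'   to 5 tracking frames.
#' @param n_pose_samples Number of accepted poses used to discretise the
#'   time-weighted sensitivity average.
#' @return A [voxel_image()] in the head frame.
#' @export
motion_corrected_recon <- function(events, traj, geom, grid,
                                   cfg = recon_config(), sensitivity = NULL,
                                   fov_sensitivity = NULL,
                                   max_gap_ms = 5 * 32, n_pose_samples = 64) {
  if (!any(traj$accepted)) stop("trajectory has no accepted poses")
  psf <- resolve_psf(cfg, geom)

  if (is_identity_trajectory(traj))
    return(osem_listmode(events, geom, grid, cfg, sensitivity))

  ip <- interpolate_poses(traj, events$t_us / 1000, max_gap_ms,
                          fallback_nearest_ms = traj$frame_duration_ms / 2)
  keep <- which(ip$ok)
  if (!length(keep)) stop("no events with a usable pose")
  ev <- subset_events(events, keep)
  ep <- event_endpoints(ev, geom)
  qc <- cbind(ip$quaternions[keep, 1], -ip$quaternions[keep, 2:4, drop = FALSE])
  Tr <- ip$translations[keep, , drop = FALSE]
  P1 <- rotate_rows_quat(qc, ep$P1 - Tr)
  P2 <- rotate_rows_quat(qc, ep$P2 - Tr)

  # exposure-weighted average of the pose-transformed static sensitivity:
  # resample an FOV-wide sensitivity (so that shifted poses never sample
  # outside the computed support) through each sampled pose
  acc <- which(traj$accepted)
  take <- acc[unique(round(seq(1, length(acc),
                               length.out = min(n_pose_samples, length(acc)))))]
  if (is.null(fov_sensitivity)) {
    gf <- fov_sensitivity_grid(geom, grid, traj)
    fov_sensitivity <- compute_sensitivity(geom, gf, aperture = TRUE)
  }
  gf <- fov_sensitivity$grid
  fv <- as.vector(fov_sensitivity$values)
  smoco <- numeric(prod(grid$shape))
  for (i in take) {
    R <- quat_to_mat(traj$quaternions[i, ])
    smoco <- smoco + cpp_resample_rigid(fv, gf$shape, gf$voxel_size, gf$origin,
                                        grid$shape, grid$voxel_size,
                                        grid$origin, R,
                                        traj$translations[i, ])
  }
  smoco <- smoco / length(take)

  x <- osem_core(P1, P2, grid, cfg, smoco, psf)
  voxel_image(grid, pmax(x, cfg$nonneg_floor))
}

#' FOV-wide grid for the moving-head sensitivity
#'
#' A coarse (2 mm) grid that covers the head-frame reconstruction grid under
#' every pose of the trajectory (with a safety margin), on which the static
#' sensitivity is evaluated before being resampled pose-by-pose.
#'
#' @param geom A [scanner_geometry()].
#' @param grid Head-frame reconstruction grid.
#' @param traj The [trajectory()] whose translations must be covered.
#' @param voxel_mm Voxel sizes of the coverage grid; 1 mm axially because
#'   the axial sensitivity profile is strongly curved on short scanners.
#' @export
fov_sensitivity_grid <- function(geom, grid, traj, voxel_mm = c(2, 2, 1)) {
  half <- grid$shape * grid$voxel_size / 2
  acc <- traj$accepted
  tmax <- apply(abs(traj$translations[acc, , drop = FALSE]), 2, max)
  half_fov <- pmin(half + tmax + 4, c(geom$ring_radius, geom$ring_radius,
                                      geom$axial_fov / 2 + 2))
  shape <- pmax(2L, as.integer(ceiling(2 * half_fov / voxel_mm)))
  grid_spec(shape, voxel_mm)
}

#' Attenuation map from the body activity outline
#'
#' Estimates the body mask from an uncorrected reconstruction: voxels above
#' `outline_threshold_frac` of the robust (99th-percentile) maximum, largest
#' 6-connected component, morphological closing and hole filling. The mask is
#' filled with the soft-tissue coefficient 0.097 cm^-1.
#'
#' @param uncorrected A [voxel_image()] with positive values.
#' @param cfg A [recon_config()] providing `outline_threshold_frac`.
#' @return A [mu_map()]; attribute `quality` holds the mask voxel count and a
#'   `near_empty` flag.
#' @export
body_outline_mumap <- function(uncorrected, cfg = recon_config()) {
  v <- as.vector(uncorrected$values)
  if (all(v <= 0)) stop("uncorrected image has no positive values")
  robust_max <- stats::quantile(v[v > 0], 0.99, names = FALSE)
  mask <- v >= cfg$outline_threshold_frac * robust_max
  g <- uncorrected$grid
  mask <- cpp_largest_component(mask, g$shape)
  mask <- cpp_binary_close(mask, g$shape)
  mask <- cpp_fill_holes(mask, g$shape)
  nvox <- sum(mask)
  mm <- mu_map(g, ifelse(mask, MU_SOFT_TISSUE, 0))
  attr(mm, "quality") <- list(n_voxels = nvox,
                              near_empty = nvox < 10)
  mm
}
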