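#' Tracker configuration
#'
#' @param frame_ms Short-frame duration, ms.
#' @param residual_tol_mm Pose-validation tolerance: frames with any marker
#'   farther than this from the rigid model are discarded (2 mm rule;
#'   residuals exactly at the tolerance are accepted).
#' @param max_candidates Maximum point-source candidates kept per frame
#'   (brightest first).
#' @param detect_threshold_frac Detection threshold as a fraction of the
#'   frame maximum. The default 0.12 keeps the dimmest marker detectable at
#'   unfavourable axial positions and under motion blur; the extra decoy
#'   candidates a low threshold admits are rejected by the geometric
#'   matching.
#' @param min_markers_required Candidates needed to attempt a match (fixed at
#'   4 in practice; 3-marker fallback poses are not computed).
#' @param max_gap_frames Longest run of rejected frames that event-time pose
#'   interpolation will bridge.
#' @param score_cap Matches with similarity score above this are rejected;
#'   defaults to `4 * residual_tol_mm^2`.
#' @export
tracker_config <- function(frame_ms = 32, residual_tol_mm = 2,
                           max_candidates = 12, detect_threshold_frac = 0.12,
                           min_markers_required = 4, max_gap_frames = 5,
                           score_cap = NULL) {
  stopifnot(residual_tol_mm > 0, max_candidates >= 4, frame_ms > 0,
            detect_threshold_frac > 0, detect_threshold_frac < 1)
  if (is.null(score_cap)) score_cap <- 4 * residual_tol_mm^2
  structure(list(frame_ms = frame_ms, residual_tol_mm = residual_tol_mm,
                 max_candidates = as.integer(max_candidates),
                 detect_threshold_frac = detect_threshold_frac,
                 min_markers_required = as.integer(min_markers_required),
                 max_gap_frames = as.integer(max_gap_frames),
                 score_cap = score_cap),
            class = "tracker_config")
}

#' Detect point-source candidates in a short frame
#'
#' Local maxima (26-neighbourhood) above `detect_threshold_frac` times the
#' frame maximum, refined by the intensity-weighted centroid of the 3^3-voxel
#' neighbourhood; at most `max_candidates` are returned, brightest first.
#'
#' @param frame A [voxel_image()] (nonnegative).
#' @param cfg A [tracker_config()].
#' @return k x 3 matrix of candidate positions, mm; zero rows for an
#'   empty/flat frame.
#' @export
detect_candidates <- function(frame, cfg = tracker_config()) {
  v <- frame$values
  mx <- max(v)
  if (mx <= 0) return(matrix(numeric(0), 0, 3))
  g <- frame$grid
  peaks <- cpp_local_maxima(as.vector(v), g$shape, cfg$detect_threshold_frac * mx)
  if (!nrow(peaks)) return(matrix(numeric(0), 0, 3))
  peaks <- peaks[seq_len(min(nrow(peaks), cfg$max_candidates)), , drop = FALSE]
  out <- matrix(0, nrow(peaks), 3)
  s <- g$shape
  for (r in seq_len(nrow(peaks))) {
    ijk <- peaks[r, 1:3]
    rng <- lapply(1:3, function(a) max(1, ijk[a] - 1):min(s[a], ijk[a] + 1))
    w <- v[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    cw <- function(a) {
      centers <- g$origin[a] + (rng[[a]] - 0.5) * g$voxel_size[a]
      ax <- sweep(array(0, dim(w)), a, centers, "+")
      sum(ax * w) / sum(w)
    }
    out[r, ] <- c(cw(1), cw(2), cw(3))
  }
  out
}

#' Geometric similarity score of an ordered candidate quadruple
#'
#' Sum over the six unordered pairs of the squared discrepancy between the
#' candidate inter-point distances and the model inter-point distances. The
#' score is invariant under any rigid transform of the candidates (it uses
#' only the relative geometry of the points) and is zero iff the candidate
#' distances reproduce the model distances in the given ordering.
#'
#' @param points 4 x 3 matrix of ordered candidate positions, mm.
#' @param model A [marker_model()].
#' @return Nonnegative score (mm^2); `Inf` for duplicate points.
#' @export
similarity_score <- function(points, model) {
  points <- as.matrix(points)
  if (nrow(points) != 4) stop("similarity score requires exactly 4 points")
  d <- pair_distances(points)
  if (any(d < 1e-9)) return(Inf)
  sum((d - model$pair_dist)^2)
}

# All 24 permutations of 1:4 (fixed order).
perm4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4), ])
  dimnames(p) <- NULL
  p
}

#' Match candidates to the marker model
#'
#' Exhaustive search over all 4-subsets of the candidates and all 24
#' orderings (at most C(10,4) * 24 = 5040 evaluations at defaults) for the
#' ordered quadruple minimising the similarity score. Returns `NULL` when
#' fewer than `min_markers_required` candidates are available or the best
#' score exceeds `score_cap`.
#'
#' @param candidates k x 3 matrix from [detect_candidates()].
#' @param model A [marker_model()].
#' @param cfg A [tracker_config()].
#' @return `NULL` (no match) or a list with `points` (4 x 3, in model
#'   order), `order` (candidate indices) and `score`.
#' @export
match_markers <- function(candidates, model, cfg = tracker_config()) {
  candidates <- as.matrix(candidates)
  k <- nrow(candidates)
  if (k < cfg$min_markers_required || k < 4) return(NULL)
  D <- as.matrix(stats::dist(candidates))
  subsets <- utils::combn(k, 4)
  P <- perm4()
  # ordered tuples: for each subset column, apply all 24 permutations
  tuples <- matrix(0L, ncol(subsets) * nrow(P), 4)
  for (c_i in seq_len(ncol(subsets)))
    tuples[(c_i - 1) * nrow(P) + seq_len(nrow(P)), ] <-
      matrix(subsets[, c_i][P], nrow(P), 4)
  pairs <- utils::combn(4, 2)
  dm <- model$pair_dist
  sc <- numeric(nrow(tuples))
  for (pp in seq_len(6)) {
    dd <- D[cbind(tuples[, pairs[1, pp]], tuples[, pairs[2, pp]])]
    sc <- sc + (dd - dm[pp])^2
  }
  best <- which.min(sc)
  if (sc[best] > cfg$score_cap) return(NULL)
  ord <- tuples[best, ]
  list(points = candidates[ord, , drop = FALSE], order = ord,
       score = sc[best])
}

#' Least-squares rigid pose from matched markers
#'
#' Kabsch/Umeyama fit: the rotation (det = +1, no scaling) and translation
#' minimising `sum || R m_i + t - p_i ||^2` over the four matched points.
#'
#' @param matched 4 x 3 matrix of detected positions in model order.
#' @param model A [marker_model()].
#' @return A [rigid_pose()] (time-free).
#' @export
fit_rigid_pose <- function(matched, model) {
  matched <- as.matrix(matched)
  stopifnot(nrow(matched) == 4)
  mc <- colMeans(model$points)
  pc <- colMeans(matched)
  M <- sweep(model$points, 2, mc)
  Pm <- sweep(matched, 2, pc)
  if (svd(Pm)$d[2] < 1e-8) stop("matched points are degenerate (collinear)")
  H <- t(M) %*% Pm
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- pc - as.vector(R %*% mc)
  rigid_pose(NA_real_, mat_to_quat(R), t_vec)
}

#' Validate a fitted pose against the rigid model
#'
#' Residual of marker i is `|| R m_i + t - p_i ||`; the pose is accepted iff
#' the largest residual is within `residual_tol_mm` (inclusive).
#'
#' @param matched 4 x 3 matched positions in model order.
#' @param model A [marker_model()].
#' @param pose A [rigid_pose()] from [fit_rigid_pose()].
#' @param cfg A [tracker_config()].
#' @return List with `accepted` and `residuals_mm`.
#' @export
validate_pose <- function(matched, model, pose, cfg = tracker_config()) {
  pred <- model$points %*% t(pose$rotation) +
    matrix(pose$translation, 4, 3, byrow = TRUE)
  res <- sqrt(rowSums((pred - as.matrix(matched))^2))
  list(accepted = max(res) <= cfg$residual_tol_mm, residuals_mm = res)
}

#' Track head motion from list-mode events
#'
#' Full point-source tracking pipeline: 32-ms short-frame reconstructions,
#' candidate detection, geometric marker matching, rigid pose fitting and
#' 2-mm residual validation, assembled into a trajectory with one pose per
#' frame (stamped at the frame centre).
#'
#' @param events An [event_stream()] from a scan containing marker activity.
#' @param model The [marker_model()].
#' @param geom A [scanner_geometry()].
#' @param cfg A [tracker_config()].
#' @param grid_coarse Coarse grid for the short-frame reconstructions.
#' @param quick_cfg Fast [recon_config()] for the short frames (flat
#'   sensitivity; see [short_frame_images()]).
#' @return List with `trajectory` (a [trajectory()]) and `tracks`
#'   (per-frame data frame: candidates found, match score, max residual,
#'   accepted flag). Errors if no frame yields an accepted pose.
#' @export
track_events <- function(events, model, geom, cfg = tracker_config(),
                         grid_coarse = grid_preset("desk-coarse"),
                         quick_cfg = recon_config(n_subsets = 1,
                                                  n_iterations = 6,
                                                  psf_sigma_mm = 0)) {
  if (!n_events(events)) stop("empty event stream")
  sens <- voxel_image(grid_coarse, array(1, grid_coarse$shape))
  nf <- n_short_frames(events$duration_ms, cfg$frame_ms)
  fidx <- frame_index(events$t_us, cfg$frame_ms)
  ep <- event_endpoints(events, geom)
  sv <- as.vector(sens$values)
  psf <- resolve_psf(quick_cfg, geom)
  split_idx <- split(seq_along(fidx), factor(fidx, levels = 0:(nf - 1)))

  t_ms <- (seq_len(nf) - 0.5) * cfg$frame_ms
  Q <- matrix(rep(c(1, 0, 0, 0), each = nf), nf, 4)
  Tr <- matrix(0, nf, 3)
  accepted <- logical(nf)
  n_cand <- integer(nf)
  score <- rep(NA_real_, nf)
  max_res <- rep(NA_real_, nf)

  for (k in seq_len(nf)) {
    idx <- split_idx[[k]]
    if (length(idx) < 4 * cfg$min_markers_required) { n_cand[k] <- 0L; next }
    img <- voxel_image(grid_coarse,
                       osem_core(ep$P1[idx, , drop = FALSE],
                                 ep$P2[idx, , drop = FALSE],
                                 grid_coarse, quick_cfg, sv, psf))
    cand <- detect_candidates(img, cfg)
    n_cand[k] <- nrow(cand)
    mt <- match_markers(cand, model, cfg)
    if (is.null(mt)) next
    pose <- fit_rigid_pose(mt$points, model)
    val <- validate_pose(mt$points, model, pose, cfg)
    Q[k, ] <- pose$quaternion
    Tr[k, ] <- pose$translation
    accepted[k] <- val$accepted
    score[k] <- mt$score
    max_res[k] <- max(val$residuals_mm)
  }

  if (!any(accepted))
    stop(sprintf(
      "tracking failed: 0 of %d frames accepted (median candidates %.0f)",
      nf, stats::median(n_cand)))

  traj <- trajectory(t_ms, Q, Tr, accepted, cfg$frame_ms)
  tracks <- data.frame(frame_start_ms = (seq_len(nf) - 1) * cfg$frame_ms,
                       n_candidates = n_cand, score = score,
                       max_residual_mm = max_res, accepted = accepted)
  attr(traj, "summary") <- list(fraction_accepted = mean(accepted),
                                mean_score = mean(score, na.rm = TRUE))
  list(trajectory = traj, tracks = tracks)
}
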