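#' Head-centroid track
#'
#' Maps the marker-centroid point (a point inside the head) through every
#' accepted pose, giving the head position over time.
#'
#' @param traj A [trajectory()] with at least one accepted pose.
#' @param model A [marker_model()].
#' @return Object of class `head_track`: `times_ms`, `positions` (n x 3 mm)
#'   and `frame_duration_ms`.
#' @export
head_track <- function(traj, model) {
  acc <- which(traj$accepted)
  if (!length(acc)) stop("trajectory has no accepted poses")
  ctr <- colMeans(model$points)
  Q <- traj$quaternions[acc, , drop = FALSE]
  P <- matrix(ctr, length(acc), 3, byrow = TRUE)
  pos <- rotate_rows_quat(Q, P) + traj$translations[acc, , drop = FALSE]
  structure(list(times_ms = traj$t_ms[acc], positions = pos,
                 frame_duration_ms = traj$frame_duration_ms),
            class = "head_track")
}

#' Average head speed and total distance travelled
#'
#' Distance is the polygonal path length over consecutive accepted frames
#' (gaps are bridged by a straight line and flagged); average speed divides
#' by the tracked (accepted) duration only.
#'
#' @param track A [head_track()].
#' @return List with `speed_cms` (cm/s), `distance_m` (m) and `n_gaps`
#'   (bridged gaps longer than one frame).
#' @export
speed_and_distance <- function(track) {
  n <- nrow(track$positions)
  if (n < 2) return(list(speed_cms = 0, distance_m = 0, n_gaps = 0L))
  steps <- diff(track$positions)
  dist_mm <- sum(sqrt(rowSums(steps^2)))
  dt <- diff(track$times_ms)
  n_gaps <- sum(dt > 1.5 * track$frame_duration_ms)
  tracked_s <- n * track$frame_duration_ms / 1000
  list(speed_cms = (dist_mm / 10) / tracked_s,
       distance_m = dist_mm / 1000, n_gaps = n_gaps)
}

#' Horizontal position heat map
#'
#' Dwell time per (x, y) bin over the platform, accumulated as one frame
#' duration per accepted sample. The rendering helper [plot_heatmap()]
#' applies a logarithmic colour scale in seconds.
#'
#' @param track A [head_track()].
#' @param bounds A [platform_bounds()].
#' @param n_bins Integer vector of bin counts in x and y.
#' @return Object of class `heatmap2d`: `x_edges`, `y_edges` (mm), `dwell_s`
#'   (matrix, seconds) and `total_tracked_s`.
#' @export
position_heatmap <- function(track, bounds = platform_bounds(),
                             n_bins = c(20, 18)) {
  n <- nrow(track$positions)
  if (!n) stop("empty track")
  hx <- bounds$x_extent / 2
  hy <- bounds$y_extent / 2
  xe <- seq(-hx, hx, length.out = n_bins[1] + 1)
  ye <- seq(-hy, hy, length.out = n_bins[2] + 1)
  xi <- pmin(pmax(findInterval(track$positions[, 1], xe,
                               rightmost.closed = TRUE), 1), n_bins[1])
  yi <- pmin(pmax(findInterval(track$positions[, 2], ye,
                               rightmost.closed = TRUE), 1), n_bins[2])
  frame_s <- track$frame_duration_ms / 1000
  dwell <- matrix(0, n_bins[1], n_bins[2])
  tb <- table(factor(xi, 1:n_bins[1]), factor(yi, 1:n_bins[2]))
  dwell <- unclass(tb) * frame_s
  structure(list(x_edges = xe, y_edges = ye, dwell_s = dwell,
                 total_tracked_s = n * frame_s),
            class = "heatmap2d")
}

#' Plot a position heat map
#'
#' @param hm A [position_heatmap()] result.
#' @param log Use a logarithmic time colour scale (seconds).
#' @param ... Passed to [graphics::image()].
#' @export
plot_heatmap <- function(hm, log = TRUE, ...) {
  z <- hm$dwell_s
  if (log) z <- log10(z + min(z[z > 0], Inf, na.rm = TRUE) / 10 + 1e-12)
  graphics::image(x = hm$x_edges, y = hm$y_edges, z = z,
                  xlab = "x (mm)", ylab = "y (mm)",
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  graphics::rect(min(hm$x_edges), min(hm$y_edges),
                 max(hm$x_edges), max(hm$y_edges), border = "white")
  invisible(hm)
}
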