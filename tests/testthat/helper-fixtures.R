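# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

desk_phantom <- function() cached("phantom", make_head_phantom())
desk_markers <- function() cached("markers", default_marker_model())
desk_geom <- function() cached("geom", scanner_preset("desk"))
desk_sens <- function()
  cached("sens", compute_sensitivity(desk_geom(), desk_phantom()$activity$grid))

# Tiny 2-D instance (one ring, 8x8 slice) for exact MLEM oracle work.
tiny_geom <- function() cached("tiny_geom",
                               scanner_geometry(12, 32, 1, 2, name = "tiny"))
tiny_grid <- function() cached("tiny_grid", grid_spec(c(8, 8, 1), c(1, 1, 2)))

tiny_events <- function(n_target = 1500, seed = 5) {
  key <- paste0("tiny_ev_", n_target, "_", seed)
  cached(key, {
    act <- array(0, c(8, 8, 1))
    act[3, 4, 1] <- 5
    act[6, 6, 1] <- 2
    tr <- sample_trajectory(1000, 0, rotation_scale = 0, seed = 1)
    simulate_listmode(voxel_image(tiny_grid(), act, TRUE), NULL, tr,
                      tiny_geom(), duration_ms = 1000,
                      rate_cps = n_target * 23, seed = seed)$events
  })
}

# Dense system matrix (events x voxels) for the tiny instance.
dense_system_matrix <- function(ev, geom, grid) {
  cp <- crystal_positions(geom)
  n <- n_events(ev)
  A <- matrix(0, n, prod(grid$shape))
  for (e in seq_len(n)) {
    rt <- raytrace(cp[ev$crystal_a[e], ], cp[ev$crystal_b[e], ], grid)
    A[e, rt$index] <- rt$length_mm
  }
  A
}

# Independent dense-matrix MLEM (plain R linear algebra).
dense_mlem <- function(A, S, n_iter) {
  x <- ifelse(S > 0, 1, 0)
  for (it in seq_len(n_iter)) {
    f <- as.vector(A %*% x)
    bp <- as.vector(t(A) %*% (1 / f))
    x <- ifelse(S > 0, x * bp / S, 0)
  }
  x
}

# Brute-force marker matching oracle: explicit nested enumeration of all
# 4-subsets and all orderings, scored one tuple at a time.
bf_match_markers <- function(candidates, model, score_cap = Inf) {
  k <- nrow(candidates)
  if (k < 4) return(NULL)
  best <- NULL
  best_score <- Inf
  subs <- utils::combn(k, 4)
  for (ci in seq_len(ncol(subs))) {
    s4 <- subs[, ci]
    for (p in asplit(perms4_oracle(), 1)) {
      ord <- s4[p]
      sc <- 0
      pts <- candidates[ord, , drop = FALSE]
      pairs <- utils::combn(4, 2)
      for (q in seq_len(6)) {
        dd <- sqrt(sum((pts[pairs[1, q], ] - pts[pairs[2, q], ])^2))
        sc <- sc + (dd - model$pair_dist[q])^2
      }
      if (sc < best_score) {
        best_score <- sc
        best <- ord
      }
    }
  }
  if (best_score > score_cap) return(NULL)
  list(order = best, score = best_score)
}

perms4_oracle <- function() {
  g <- expand.grid(1:4, 1:4, 1:4, 1:4)
  as.matrix(g[apply(g, 1, function(r) length(unique(r)) == 4), ])
}

# Random rigid transform.
random_pose <- function() {
  ax <- stats::rnorm(3)
  q <- quat_from_axis_angle(ax, stats::runif(1, 0, pi))
  list(q = q, R = quat_to_mat(q), t = stats::runif(3, -20, 20))
}

constant_trajectory <- function(duration_ms, q = c(1, 0, 0, 0),
                                tvec = c(0, 0, 0), frame_ms = 32) {
  n <- ceiling(duration_ms / frame_ms) + 1
  trajectory((seq_len(n) - 1) * frame_ms,
             matrix(rep(q, each = n), n, 4),
             matrix(rep(tvec, each = n), n, 3),
             rep(TRUE, n), frame_ms)
}

rotation_error_deg <- function(q1, q2) {
  2 * acos(pmin(1, abs(rowSums(q1 * q2)))) * 180 / pi
}

quat_angle_between_deg <- function(q1, q2) {
  2 * acos(min(1, abs(sum(q1 * q2)))) * 180 / pi
}
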