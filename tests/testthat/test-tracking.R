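test_that("candidate detection recovers sub-voxel blob positions", {
  g <- grid_spec(c(24, 24, 10), 1.5)
  ctr <- voxel_centers(g)
  truth <- c(2.3, -4.1, 1.2)
  blob <- exp(-rowSums(sweep(ctr, 2, truth)^2) / (2 * 1.5^2))
  img <- voxel_image(g, array(blob, g$shape))
  cand <- detect_candidates(img)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt(sum((cand[1, ] - truth)^2)), 0.2 * 1.5)

  # all-zero frame: no candidates
  expect_equal(nrow(detect_candidates(voxel_image(g, array(0, g$shape)))), 0)

  # two equal blobs 5 voxels apart: exactly two candidates
  p2 <- truth + c(5 * 1.5, 0, 0)
  two <- blob + exp(-rowSums(sweep(ctr, 2, p2)^2) / (2 * 1.5^2))
  cand2 <- detect_candidates(voxel_image(g, array(two, g$shape)))
  expect_equal(nrow(cand2), 2)
})

test_that("the similarity score is a rigid-invariant distance discrepancy", {
  mm <- desk_markers()
  set.seed(11)
  for (i in 1:20) {
    p <- random_pose()
    moved <- mm$points %*% t(p$R) + matrix(p$t, 4, 3, byrow = TRUE)
    expect_lt(similarity_score(moved, mm), 1e-12)
  }
  # a model whose reference distances differ from the candidates in exactly
  # one pair by 1 mm scores exactly 1 mm^2
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  md <- marker_model(pts,  # distances {10,10,10,14.14...}: not distinct,
                     distance_margin = 0)  # allowed with zero margin
  md$pair_dist[1] <- md$pair_dist[1] + 1
  expect_equal(similarity_score(pts, md), 1.0, tolerance = 1e-12)
  # duplicate points sentinel
  expect_equal(similarity_score(pts[c(1, 1, 2, 3), ], md), Inf)
})

test_that("marker matching finds the true subset among decoys", {
  mm <- desk_markers()
  cfg <- tracker_config()
  hits <- 0
  set.seed(21)
  for (i in 1:100) {
    p <- random_pose()
    truth <- mm$points %*% t(p$R) + matrix(p$t, 4, 3, byrow = TRUE)
    decoys <- cbind(stats::runif(6, -15, 15), stats::runif(6, -15, 15),
                    stats::runif(6, -10, 10)) +
      matrix(p$t, 6, 3, byrow = TRUE)
    cand <- rbind(truth, decoys)[sample(10), , drop = FALSE]
    mt <- match_markers(cand, mm, cfg)
    bf <- bf_match_markers(cand, mm, cfg$score_cap)
    # exhaustive search must agree with the brute-force oracle exactly
    expect_identical(mt$order, as.integer(bf$order))
    expect_equal(mt$score, bf$score, tolerance = 1e-12)
    if (!is.null(mt) && mt$score < 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("matching declines with too few candidates", {
  mm <- desk_markers()
  expect_null(match_markers(mm$points[1:3, ], mm))
  mt <- match_markers(mm$points, mm)
  expect_lt(mt$score, 1e-12)
})

test_that("rigid pose fitting recovers exact and noisy transforms", {
  mm <- desk_markers()
  # identity
  p0 <- fit_rigid_pose(mm$points, mm)
  expect_lt(max(abs(p0$translation)), 1e-12)
  expect_lt(quat_angle_between_deg(p0$quaternion, c(1, 0, 0, 0)), 1e-9)

  # 30 degrees about z plus a shift, noise-free
  q30 <- quat_from_axis_angle(c(0, 0, 1), 30 * pi / 180)
  R30 <- quat_to_mat(q30)
  moved <- mm$points %*% t(R30) + matrix(c(5, -3, 2), 4, 3, byrow = TRUE)
  p1 <- fit_rigid_pose(moved, mm)
  expect_equal(p1$translation, c(5, -3, 2), tolerance = 1e-9)
  expect_lt(quat_angle_between_deg(p1$quaternion, q30) , 1e-7)

  # Monte Carlo with isotropic noise: mean translation error stays small
  set.seed(31)
  errs <- replicate(1000, {
    noisy <- moved + matrix(stats::rnorm(12, sd = 0.1), 4, 3)
    sqrt(sum((fit_rigid_pose(noisy, mm)$translation - c(5, -3, 2))^2))
  })
  expect_lt(mean(errs), 0.15)

  # collinear points are rejected
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(fit_rigid_pose(line, mm), "degenerate")
})

test_that("pose validation applies the 2-mm rule inclusively", {
  mm <- desk_markers()
  cfg <- tracker_config()
  pose <- fit_rigid_pose(mm$points, mm)
  v0 <- validate_pose(mm$points, mm, pose, cfg)
  expect_true(v0$accepted)
  expect_equal(unname(v0$residuals_mm), rep(0, 4), tolerance = 1e-12)

  # displace one marker far enough that its residual exceeds 2 mm even
  # after the fit redistributes part of the displacement
  bad <- mm$points
  bad[2, ] <- bad[2, ] + c(4, 0, 0)
  pose_b <- fit_rigid_pose(bad, mm)
  vb <- validate_pose(bad, mm, pose_b, cfg)
  expect_gt(max(vb$residuals_mm), 2)
  expect_false(vb$accepted)

  # residuals exactly at the tolerance are accepted (inclusive rule)
  fake_pose <- rigid_pose(NA, c(1, 0, 0, 0), c(0, 0, 0))
  shifted <- mm$points + matrix(c(1.9, 0, 0), 4, 3, byrow = TRUE)
  vs <- validate_pose(shifted, mm, fake_pose, cfg)
  expect_equal(unname(vs$residuals_mm), rep(1.9, 4), tolerance = 1e-12)
  expect_true(vs$accepted)
})

test_that("lowering the residual tolerance never accepts more frames", {
  mm <- desk_markers()
  set.seed(41)
  pose <- rigid_pose(NA, c(1, 0, 0, 0), c(0, 0, 0))
  for (i in 1:50) {
    pts <- mm$points + matrix(stats::rnorm(12, sd = 1.2), 4, 3)
    tight <- validate_pose(pts, mm, pose, tracker_config(residual_tol_mm = 1))
    loose <- validate_pose(pts, mm, pose, tracker_config(residual_tol_mm = 2))
    expect_true(!tight$accepted || loose$accepted)
  }
})

test_that("end-to-end tracking of a static animal is tight and nearly complete", {
  ph <- desk_phantom()
  mm <- desk_markers()
  geom <- desk_geom()
  tr <- sample_trajectory(6000, 0, rotation_scale = 0, seed = 3)
  sim <- simulate_listmode(ph$activity, mm, tr, geom, duration_ms = 6000,
                           rate_cps = 1e6, seed = 4)
  trk <- track_events(sim$events, mm, geom)
  tj <- trk$trajectory
  expect_gte(mean(tj$accepted), 0.99)
  acc <- tj$accepted
  expect_lt(max(apply(tj$translations[acc, ], 2, stats::sd)), 0.5)
})

test_that("tracking fails loudly when no marker signal exists", {
  ph <- desk_phantom()
  geom <- desk_geom()
  tr <- sample_trajectory(1000, 0, rotation_scale = 0, seed = 3)
  sim <- simulate_listmode(ph$activity, NULL, tr, geom, duration_ms = 1000,
                           rate_cps = 5e4, seed = 5)
  expect_error(track_events(sim$events, desk_markers(), geom),
               "tracking failed")
})
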