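test_that("sensitivity behaves under zero attenuation, symmetry and mu", {
  geom <- tiny_geom()
  g <- tiny_grid()
  s_plain <- compute_sensitivity(geom, g)
  mu0 <- mu_map(g, array(0, g$shape))
  s_mu0 <- compute_sensitivity(geom, g, mumap = mu0)
  expect_identical(s_plain$values, s_mu0$values)

  # rotation by an integer number of crystal pitches leaves the sensitivity
  # of a symmetric ring unchanged within 1%; an odd grid keeps the symmetry
  # axes through voxel centres rather than boundaries
  g9 <- grid_spec(c(9, 9, 1), c(1, 1, 2))
  v <- compute_sensitivity(geom, g9)$values[, , 1]
  rot <- t(apply(v, 2, rev))   # 90 degrees = 8 crystal pitches here
  inside <- v > 0.25 * max(v)
  expect_lt(max(abs(rot[inside] - v[inside]) / v[inside]), 0.01)

  # a uniform attenuating cylinder strictly decreases central sensitivity
  mu <- mu_map(g, array(MU_SOFT_TISSUE, g$shape))
  s_mu <- compute_sensitivity(geom, g, mumap = mu)
  expect_lt(s_mu$values[4, 4, 1], s_plain$values[4, 4, 1])
  expect_true(all(s_mu$values <= s_plain$values + 1e-12))

  far <- grid_spec(c(4, 4, 1), 1, origin = c(500, 500, 0))
  expect_error(compute_sensitivity(geom, far), "outside")
})

test_that("list-mode MLEM matches a dense-matrix MLEM oracle", {
  geom <- tiny_geom()
  g <- tiny_grid()
  ev <- tiny_events()
  sens <- compute_sensitivity(geom, g)
  cfg <- recon_config(n_subsets = 1, n_iterations = 10, psf_sigma_mm = 0)
  x <- osem_listmode(ev, geom, g, cfg, sens)
  A <- dense_system_matrix(ev, geom, g)
  xo <- dense_mlem(A, as.vector(sens$values), 10)
  expect_lt(max(abs(as.vector(x$values) - xo) / pmax(xo, 1e-12)), 1e-6)
})

test_that("MLEM preserves counts and never decreases the log-likelihood", {
  geom <- tiny_geom()
  g <- tiny_grid()
  ev <- tiny_events()
  sens <- compute_sensitivity(geom, g)
  A <- dense_system_matrix(ev, geom, g)
  S <- as.vector(sens$values)
  ll <- numeric(6)
  for (it in 1:6) {
    xi <- osem_listmode(ev, geom, g, recon_config(1, it, 0), sens)
    xv <- as.vector(xi$values)
    # count preservation after each full iteration
    expect_equal(sum(xv * S), n_events(ev), tolerance = 1e-6)
    f <- as.vector(A %*% xv)
    ll[it] <- sum(log(f)) - sum(S * xv)
  }
  expect_true(all(diff(ll) > -1e-8))
})

test_that("duplicating every event exactly doubles the image", {
  geom <- tiny_geom()
  g <- tiny_grid()
  ev <- tiny_events()
  n <- n_events(ev)
  ev2 <- event_stream(rep(ev$t_us, each = 2), rep(ev$crystal_a, each = 2),
                      rep(ev$crystal_b, each = 2), ev$geom_name,
                      ev$duration_ms)
  cfg <- recon_config(n_subsets = 1, n_iterations = 5, psf_sigma_mm = 0)
  sens <- compute_sensitivity(geom, g)
  x1 <- osem_listmode(ev, geom, g, cfg, sens)
  x2 <- osem_listmode(ev2, geom, g, cfg, sens)
  expect_equal(x2$values, 2 * x1$values, tolerance = 1e-12)
})

test_that("a point source reconstructs at its true position", {
  geom <- desk_geom()
  g <- grid_spec(c(32, 32, 12), 1)
  # single hot voxel: the emission site is uniform within that voxel
  act <- array(0, g$shape)
  act[20, 14, 8] <- 100
  truth <- g$origin + (c(20, 14, 8) - 0.5) * g$voxel_size
  tr <- constant_trajectory(2000)
  sim <- simulate_listmode(voxel_image(g, act, TRUE), NULL, tr, geom,
                           duration_ms = 2000, rate_cps = 1e5, seed = 6)
  sens <- compute_sensitivity(geom, g)
  x <- osem_listmode(sim$events, geom, g, recon_config(4, 4, 0), sens)
  peak <- which(x$values == max(x$values), arr.ind = TRUE)[1, ]
  pos <- g$origin + (peak - 0.5) * g$voxel_size
  expect_lt(max(abs(pos - truth)), 1.001)
})

test_that("a uniform cylinder reconstructs with high contrast", {
  geom <- desk_geom()
  g <- grid_spec(c(48, 48, 10), 1.25)
  ctr <- voxel_centers(g)
  cyl <- ctr[, 1]^2 + ctr[, 2]^2 <= 18^2
  act <- voxel_image(g, array(as.numeric(cyl), g$shape), TRUE)
  tr <- constant_trajectory(2000)
  sim <- simulate_listmode(act, NULL, tr, geom, duration_ms = 2000,
                           rate_cps = 1.2e6, seed = 8)
  sens <- compute_sensitivity(geom, g)
  x <- osem_listmode(sim$events, geom, g, recon_config(8, 4, 0), sens)
  inside <- array(ctr[, 1]^2 + ctr[, 2]^2 <= 14^2, g$shape)
  annulus <- array(ctr[, 1]^2 + ctr[, 2]^2 >= 22^2 &
                     ctr[, 1]^2 + ctr[, 2]^2 <= 27^2, g$shape)
  expect_gte(mean(x$values[inside]) / max(mean(x$values[annulus]), 1e-12), 20)
})

test_that("short frames partition events with half-open boundaries", {
  expect_equal(n_short_frames(1200000, 32), 37500L)
  geom <- tiny_geom()
  g <- tiny_grid()
  # an event exactly at t = 32.000 ms belongs to frame 2 (index 1);
  # crystal pairs are diametral so every LOR crosses the grid
  ev <- event_stream(c(0, 31999, 32000, 95999), c(1, 2, 3, 4),
                     c(17, 18, 19, 20), duration_ms = 96)
  fr <- short_frame_images(ev, geom, g, frame_ms = 32)
  expect_length(fr, 3)
  counts <- vapply(fr, function(f) sum(f$image$values > 0), numeric(1))
  expect_true(counts[2] > 0)
  # partition: total events recovered from per-frame assignment
  fidx <- awakepet:::frame_index(ev$t_us, 32)
  expect_equal(as.integer(table(fidx)), c(2L, 1L, 1L))
  expect_equal(length(fidx), n_events(ev))
})

test_that("a long sparse stream yields the full frame ladder cheaply", {
  geom <- tiny_geom()
  g <- grid_spec(c(4, 4, 1), c(2, 2, 2))
  ev <- event_stream(seq(0, 1199999, length.out = 10) * 1000,
                     1:10, 21:30, duration_ms = 1200000)
  fr <- short_frame_images(ev, geom, g, frame_ms = 32)
  expect_length(fr, 37500)
  expect_equal(fr[[1]]$frame_start_ms, 0)
  expect_equal(fr[[37500]]$frame_start_ms, (37500 - 1) * 32)
})

test_that("motion correction with an identity trajectory equals plain OSEM", {
  geom <- tiny_geom()
  g <- tiny_grid()
  ev <- tiny_events()
  sens <- compute_sensitivity(geom, g)
  tr <- constant_trajectory(1000)
  a <- motion_corrected_recon(ev, tr, geom, g, recon_config(4, 2, 0), sens)
  b <- osem_listmode(ev, geom, g, recon_config(4, 2, 0), sens)
  expect_identical(a$values, b$values)
})

test_that("rejected frames exclude exactly their events", {
  geom <- tiny_geom()
  g <- tiny_grid()
  ev <- tiny_events()
  n <- 33
  acc <- rep(TRUE, n)
  acc[11:21] <- FALSE   # frames 10..20 rejected
  tmid <- ((1:n) - 0.5) * 32
  tr <- trajectory(tmid, matrix(rep(c(1, 0, 0, 0), each = n), n, 4),
                   matrix(0, n, 3), acc, 32)
  ip <- interpolate_poses(tr, ev$t_us / 1000, max_gap_ms = 5 * 32,
                          fallback_nearest_ms = 16)
  fidx <- awakepet:::frame_index(ev$t_us, 32)
  in_rejected <- fidx >= 10 & fidx <= 20
  expect_true(all(!ip$ok[in_rejected]))
  expect_true(all(ip$ok[!in_rejected]))
})

test_that("the body outline produces a plausible soft-tissue mu map", {
  geom <- desk_geom()
  g <- grid_spec(c(48, 48, 10), 1.25)
  ctr <- voxel_centers(g)
  cyl <- ctr[, 1]^2 + ctr[, 2]^2 <= 18^2
  act <- voxel_image(g, array(as.numeric(cyl), g$shape), TRUE)
  tr <- constant_trajectory(2000)
  sim <- simulate_listmode(act, NULL, tr, geom, duration_ms = 2000,
                           rate_cps = 1.2e6, seed = 8)
  sens <- compute_sensitivity(geom, g)
  x <- osem_listmode(sim$events, geom, g, recon_config(8, 4, 0), sens)
  mm <- body_outline_mumap(x)
  vol_true <- sum(cyl)
  vol_mask <- sum(mm$mu > 0)
  expect_lt(abs(vol_mask - vol_true) / vol_true, 0.10)
  expect_true(all(mm$mu[mm$mu > 0] == MU_SOFT_TISSUE))

  # a second blob 100x fainter is dropped by the largest-component rule
  v2 <- x$values
  v2[44:46, 44:46, 5] <- max(x$values) / 100
  mm2 <- body_outline_mumap(voxel_image(g, v2))
  expect_true(all(mm2$mu[44:46, 44:46, 5] == 0))

  # a degenerate threshold yields a near-empty mask flagged in quality
  mm3 <- body_outline_mumap(x, recon_config(outline_threshold_frac = 0.99))
  expect_true(attr(mm3, "quality")$near_empty)
  expect_error(body_outline_mumap(voxel_image(g, array(0, g$shape))),
               "positive")
})
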