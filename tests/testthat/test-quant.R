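test_that("regional means aggregate exactly over atlas labels", {
  ph <- desk_phantom()
  g <- ph$atlas$grid
  # constant image
  rm1 <- regional_means(voxel_image(g, array(3.25, g$shape)), ph$atlas)
  expect_equal(unname(rm1), rep(3.25, 5))
  # index-parity checkerboard of 0/2: the regional mean equals the exact
  # voxel-count oracle 2 * n_odd / n and sits near 1
  a0 <- array(0, g$shape)
  parity <- (slice.index(a0, 1) + slice.index(a0, 2) + slice.index(a0, 3)) %% 2
  chk <- parity * 2
  rm2 <- regional_means(voxel_image(g, chk), ph$atlas)
  oracle <- vapply(names(ph$atlas$region_names), function(nm) {
    sel <- ph$atlas$labels == ph$atlas$region_names[[nm]]
    2 * sum(parity[sel]) / sum(sel)
  }, numeric(1))
  expect_equal(rm2, oracle, tolerance = 1e-12)
  expect_true(all(abs(rm2 - 1) < 0.25))
  # grid mismatch is an error
  g2 <- grid_spec(c(8, 8, 8), 1)
  expect_error(regional_means(voxel_image(g2, array(1, g2$shape)), ph$atlas),
               "grids differ")
})

test_that("SUV arithmetic identities hold", {
  d <- dose_record(18500, 25)
  expect_equal(suv(18500 / 25, d, decay_correct = FALSE), 1.0)
  expect_equal(suv(740, d, decay_correct = FALSE), 1.0)
  d30 <- dose_record(18500, 25, injection_time_min = 0, scan_start_min = 30)
  ratio <- suv(740, d30) / suv(740, d30, decay_correct = FALSE)
  expect_equal(ratio, 2^(30 / 109.77), tolerance = 1e-12)
  expect_equal(ratio, 1.208, tolerance = 1e-3)
  expect_error(dose_record(0, 25), "positive")
  expect_error(dose_record(100, -2), "positive")
})

test_that("TAC slope tests match closed-form OLS", {
  t_min <- c(31, 35, 39, 43, 47)
  y <- 3 - 0.1 * t_min
  tac <- tac_set(t_min, rbind(cortex = y))
  r <- suppressWarnings(tac_slope_test(tac))  # exact line: summary.lm warns
  expect_equal(r$slope, -0.1, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-10)

  # hand-computed oracle on a 5-point example
  y2 <- c(2.9, 3.1, 3.0, 3.3, 3.2)
  tac2 <- tac_set(t_min, rbind(cortex = y2))
  r2 <- tac_slope_test(tac2)
  tm <- mean(t_min); ym <- mean(y2)
  sxx <- sum((t_min - tm)^2)
  b <- sum((t_min - tm) * (y2 - ym)) / sxx
  a <- ym - b * tm
  s2 <- sum((y2 - a - b * t_min)^2) / (5 - 2)
  se <- sqrt(s2 / sxx)
  p <- 2 * stats::pt(-abs(b / se), df = 3)
  expect_equal(r2$slope, b, tolerance = 1e-12)
  expect_equal(r2$se, se, tolerance = 1e-12)
  expect_equal(r2$p_value, p, tolerance = 1e-12)

  expect_error(tac_slope_test(tac_set(c(1, 2), rbind(a = c(1, 2)))),
               "3 frames")
})

test_that("coefficient of variation matches its formula", {
  expect_equal(cov_percent(c(4, 4, 4, 4)), 0)
  expect_equal(cov_percent(c(9, 10, 11)), 10.0)
  set.seed(2)
  for (i in 1:100) {
    v <- stats::rlnorm(sample(3:20, 1))
    expect_equal(cov_percent(v), 100 * stats::sd(v) / mean(v),
                 tolerance = 1e-12)
  }
  expect_error(cov_percent(5), "n >= 2")
})

test_that("ICC(A,1) matches an independent ANOVA-based computation", {
  bf_icc <- function(test, retest) {
    n <- length(test)
    d <- data.frame(y = c(test, retest),
                    subj = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]$`Mean Sq`
    MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
    (MSR - MSE) / (MSR + MSE + (2 / n) * (MSC - MSE))
  }
  set.seed(3)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    a <- stats::rnorm(n, 10, 2)
    b <- a + stats::rnorm(n, 0.2, 1)
    expect_equal(icc(a, b), bf_icc(a, b), tolerance = 1e-10)
  }
  # identical vectors: perfect agreement
  x <- stats::rnorm(10)
  expect_equal(icc(x, x), 1.0, tolerance = 1e-12)
  # independent draws: near zero
  set.seed(4)
  a <- stats::rnorm(1000); b <- stats::rnorm(1000)
  expect_lt(abs(icc(a, b)), 0.1)
  expect_error(icc(1:4, 1:5), "paired")
  expect_error(icc(1:2, 1:2), "at least 3")
})

test_that("ICC recovers the intraclass correlation of simulated cohorts", {
  set.seed(6)
  n <- 500
  subj <- stats::rnorm(n, sd = 1)       # sigma_b^2 = 1
  a <- subj + stats::rnorm(n, sd = 1)   # sigma_w^2 = 1
  b <- subj + stats::rnorm(n, sd = 1)
  expect_lt(abs(icc(a, b) - 0.5), 0.05)
})

test_that("Bland-Altman percent agreement matches brute force", {
  r0 <- bland_altman_percent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$bias_percent, 0)
  expect_equal(r0$bias_sd, 0)

  # two identical pairs built from published-scale SUVs
  r1 <- bland_altman_percent(c(2.51, 2.51), c(2.70, 2.70))
  expect_equal(r1$bias_percent, 100 * (2.51 - 2.70) / 2.605, tolerance = 1e-12)
  expect_equal(r1$bias_percent, -7.29, tolerance = 0.01)
  expect_equal(r1$bias_sd, 0)

  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:20, 1)
    a <- stats::rlnorm(n, 1); b <- stats::rlnorm(n, 1)
    r <- bland_altman_percent(a, b)
    d <- 100 * (a - b) / ((a + b) / 2)
    expect_equal(r$bias_percent, mean(d), tolerance = 1e-10)
    expect_equal(r$bias_sd, stats::sd(d), tolerance = 1e-10)
  }
  expect_error(bland_altman_percent(c(1, -1), c(1, 1)), "zero")
})

test_that("test-retest variability is the mean absolute percent difference", {
  expect_equal(variability_percent(c(2, 3), c(2, 3)), 0)
  v <- variability_percent(c(2.0, 3.0), c(2.2, 2.7))
  expect_equal(v, mean(c(100 * 0.2 / 2.1, 100 * 0.3 / 2.85)), tolerance = 1e-12)
  expect_equal(v, 10.025, tolerance = 1e-3)
  # always at least the absolute Bland-Altman bias
  set.seed(8)
  for (i in 1:50) {
    a <- stats::rlnorm(6); b <- stats::rlnorm(6)
    expect_gte(variability_percent(a, b) + 1e-12,
               abs(bland_altman_percent(a, b)$bias_percent))
  }
})

test_that("challenge percent change is exact and scale-invariant", {
  tab <- expand.grid(subject = "s1", group = "awake",
                     condition = c("test", "retest", "memantine"),
                     region = BRAIN_REGIONS, stringsAsFactors = FALSE)
  tab$suv <- 2
  r0 <- memantine_percent_change(suv_table(tab), "awake")
  expect_equal(unname(r0$per_region), rep(0, 5))
  expect_equal(r0$average, 0)

  tab2 <- tab
  tab2$suv[tab2$condition == "memantine"] <- 4
  r2 <- memantine_percent_change(suv_table(tab2), "awake")
  expect_equal(unname(r2$per_region), rep(100, 5))

  tab3 <- tab2
  tab3$suv <- tab3$suv * 7.3
  r3 <- memantine_percent_change(suv_table(tab3), "awake")
  expect_equal(r3$per_region, r2$per_region, tolerance = 1e-12)

  expect_error(memantine_percent_change(
    suv_table(tab2[tab2$condition != "memantine", ]), "awake"), "memantine")
})

test_that("blur-equivalence sigma is recovered by golden-section search", {
  g <- grid_spec(c(24, 24, 10), 1)
  set.seed(9)
  base <- array(0, g$shape)
  base[8:17, 8:17, 3:8] <- 1
  base <- base + array(stats::rnorm(prod(g$shape), sd = 0.02), g$shape)
  ref <- voxel_image(g, base)
  blurred <- voxel_image(g, array(
    awakepet:::cpp_gauss_blur(as.vector(base), g$shape, g$voxel_size, 0.6),
    g$shape))
  expect_equal(estimate_blur_sigma(ref, blurred), 0.60, tolerance = 0.01)
  expect_equal(estimate_blur_sigma(ref, ref), 0, tolerance = 1e-9)

  # agrees with an exhaustive grid search on random phantoms
  for (i in 1:10) {
    sig <- stats::runif(1, 0.2, 1.5)
    ph <- array(stats::rlnorm(prod(g$shape), sd = 0.5), g$shape)
    refi <- voxel_image(g, ph)
    degi <- voxel_image(g, array(
      awakepet:::cpp_gauss_blur(as.vector(ph), g$shape, g$voxel_size, sig),
      g$shape))
    est <- estimate_blur_sigma(refi, degi)
    grid_sigmas <- seq(0, 2, by = 0.01)
    mses <- vapply(grid_sigmas, function(s) {
      b <- awakepet:::cpp_gauss_blur(as.vector(ph), g$shape, g$voxel_size, s)
      mean((b - as.vector(degi$values))^2)
    }, numeric(1))
    expect_lt(abs(est - grid_sigmas[which.min(mses)]), 0.011)
  }
  z <- voxel_image(g, array(0, g$shape))
  expect_error(estimate_blur_sigma(z, z), "zero")
})
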