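#' Regional mean uptake
#'
#' Arithmetic mean of the image over each labelled atlas region.
#'
#' @param image A [voxel_image()].
#' @param atlas A [brain_atlas()] on the same grid.
#' @return Named vector of regional means (kBq/cm^3 for calibrated images).
#' @export
regional_means <- function(image, atlas) {
  if (!same_grid(image$grid, atlas$grid)) stop("image and atlas grids differ")
  out <- vapply(names(atlas$region_names), function(nm) {
    sel <- atlas$labels == atlas$region_names[[nm]]
    if (!any(sel)) stop("atlas region '", nm, "' is empty")
    mean(image$values[sel])
  }, numeric(1))
  out
}

#' Injected dose record
#'
#' @param injected_dose_kbq Injected activity, kBq.
#' @param body_weight_g Body weight, g.
#' @param injection_time_min,scan_start_min Clock times in minutes; the
#'   difference is the uptake delay used for decay correction.
#' @export
dose_record <- function(injected_dose_kbq, body_weight_g,
                        injection_time_min = 0, scan_start_min = 0) {
  if (injected_dose_kbq <= 0) stop("injected dose must be positive")
  if (body_weight_g <= 0) stop("body weight must be positive")
  structure(list(injected_dose_kbq = injected_dose_kbq,
                 body_weight_g = body_weight_g,
                 injection_time_min = injection_time_min,
                 scan_start_min = scan_start_min),
            class = "dose_record")
}

#' Standardised uptake value
#'
#' `SUV = concentration / (dose / weight)` with tissue density 1 g/cm^3.
#' With decay correction (default), the injected dose is decayed to the scan
#' start with the 18F half-life of 109.77 min, which increases the SUV by
#' `2^(delay / 109.77)` relative to the uncorrected value.
#'
#' @param concentration_kbq_cm3 Tissue concentration, kBq/cm^3.
#' @param dose A [dose_record()].
#' @param decay_correct Decay-correct the dose to scan start.
#' @param half_life_min Radionuclide half-life, min.
#' @export
suv <- function(concentration_kbq_cm3, dose, decay_correct = TRUE,
                half_life_min = 109.77) {
  stopifnot(inherits(dose, "dose_record"))
  d <- dose$injected_dose_kbq
  if (decay_correct) {
    delay <- dose$scan_start_min - dose$injection_time_min
    d <- d * 2^(-delay / half_life_min)
  }
  concentration_kbq_cm3 / (d / dose$body_weight_g)
}

#' Regional time-activity curves from a list-mode scan
#'
#' Reconstructs independent fixed-duration frames (2 min by default) with
#' the same algorithm as the static reconstruction — motion-corrected when a
#' trajectory is supplied — and extracts regional means per frame.
#'
#' @param events An [event_stream()].
#' @param traj Optional [trajectory()] for motion-corrected frames.
#' @param atlas A [brain_atlas()]; its grid is the reconstruction grid.
#' @param geom A [scanner_geometry()].
#' @param cfg A [recon_config()].
#' @param frame_s Frame duration, s.
#' @param t0_min Time of scan start post-injection (min), added to the frame
#'   midpoints.
#' @return Object of class `tac_set`: `times_min` (frame midpoints) and
#'   `uptake` (regions x frames matrix).
#' @export
tac_extract <- function(events, traj = NULL, atlas, geom,
                        cfg = recon_config(), frame_s = 120, t0_min = 30) {
  nf <- floor(events$duration_ms / (frame_s * 1000))
  if (nf < 2) stop("scan shorter than two frames")
  sens <- compute_sensitivity(geom, atlas$grid)
  fidx <- as.integer(events$t_us %/% (frame_s * 1e6))
  up <- matrix(NA_real_, length(atlas$region_names), nf,
               dimnames = list(names(atlas$region_names), NULL))
  for (k in seq_len(nf)) {
    ev <- subset_events(events, which(fidx == k - 1))
    img <- if (is.null(traj))
      osem_listmode(ev, geom, atlas$grid, cfg, sens)
    else
      motion_corrected_recon(ev, traj, geom, atlas$grid, cfg, sens)
    up[, k] <- regional_means(img, atlas)
  }
  structure(list(times_min = t0_min + (seq_len(nf) - 0.5) * frame_s / 60,
                 uptake = up),
            class = "tac_set")
}

#' Construct a TAC set from values
#' @param times_min Frame midpoints, minutes.
#' @param uptake Regions x frames matrix (rownames are regions).
#' @export
tac_set <- function(times_min, uptake) {
  uptake <- as.matrix(uptake)
  stopifnot(length(times_min) == ncol(uptake), ncol(uptake) >= 2)
  structure(list(times_min = times_min, uptake = uptake), class = "tac_set")
}

#' Test TAC slopes against zero
#'
#' Ordinary least squares of uptake on time per region with a two-sided
#' t-test on the slope (n - 2 degrees of freedom).
#'
#' @param tac A `tac_set` with at least 3 frames.
#' @return Data frame with `region`, `slope`, `se`, `p_value`.
#' @export
tac_slope_test <- function(tac) {
  if (ncol(tac$uptake) < 3) stop("slope test needs at least 3 frames")
  t_min <- tac$times_min
  out <- lapply(rownames(tac$uptake), function(nm) {
    fit <- stats::lm(tac$uptake[nm, ] ~ t_min)
    cf <- summary(fit)$coefficients
    data.frame(region = nm, slope = cf[2, 1], se = cf[2, 2],
               p_value = cf[2, 4])
  })
  do.call(rbind, out)
}

#' Coefficient of variation, percent
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation.
#' @param values Numeric vector, n >= 2, nonzero mean.
#' @export
cov_percent <- function(values) {
  if (length(values) < 2) stop("coefficient of variation needs n >= 2")
  m <- mean(values)
  if (m == 0) stop("mean is zero")
  100 * stats::sd(values) / m
}

#' Intraclass correlation coefficient
#'
#' Computed from two-way ANOVA mean squares. The default variant is
#' ICC(A,1): two-way mixed effects, absolute agreement, single measurement —
#' the usual choice for test-retest agreement of a quantitative reading.
#' `"consistency"` gives ICC(C,1). Variants differ; the variant used should
#' always be reported.
#'
#' @param test,retest Paired per-subject values (n >= 3).
#' @param variant `"agreement"` (ICC(A,1)) or `"consistency"` (ICC(C,1)).
#' @export
icc <- function(test, retest, variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  if (length(test) != length(retest)) stop("test/retest must be paired")
  n <- length(test)
  if (n < 3) stop("ICC needs at least 3 subjects")
  X <- cbind(test, retest)
  k <- 2
  grand <- mean(X)
  SSR <- k * sum((rowMeans(X) - grand)^2)
  SSC <- n * sum((colMeans(X) - grand)^2)
  SSE <- sum((X - grand)^2) - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (variant == "agreement")
    (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  else
    (MSR - MSE) / (MSR + (k - 1) * MSE)
}

#' Bland-Altman agreement on percent differences
#'
#' Per-subject difference `d = 100 * (test - retest) / pair mean`; the bias
#' is `mean(d)` and the bias SD is the sample SD of `d`. With this sign
#' convention, retest readings exceeding test readings give a negative bias.
#'
#' @param test,retest Paired values (n >= 2), no pair mean of zero.
#' @return List with `bias_percent` and `bias_sd`.
#' @export
bland_altman_percent <- function(test, retest) {
  if (length(test) != length(retest)) stop("test/retest must be paired")
  if (length(test) < 2) stop("Bland-Altman needs n >= 2")
  m <- (test + retest) / 2
  if (any(m == 0)) stop("a pair mean is zero")
  d <- 100 * (test - retest) / m
  list(bias_percent = mean(d), bias_sd = stats::sd(d))
}

#' Test-retest variability, percent
#'
#' Mean over subjects of the absolute percent difference
#' `100 * |test - retest| / pair mean`; always at least `|bias|` from
#' [bland_altman_percent()] on the same data.
#'
#' @param test,retest Paired values, no pair mean of zero.
#' @export
variability_percent <- function(test, retest) {
  if (length(test) != length(retest)) stop("test/retest must be paired")
  m <- (test + retest) / 2
  if (any(m == 0)) stop("a pair mean is zero")
  mean(100 * abs(test - retest) / m)
}

#' Challenge-induced percent change in regional SUV
#'
#' For each region, `100 * (SUV_challenge - baseline) / baseline` with the
#' baseline defined as the mean of the test and retest SUVs; the summary is
#' the unweighted mean over the five regions. Scale-invariant: multiplying
#' all SUVs by a constant leaves the percentages unchanged.
#'
#' @param table A [suv_table()] data frame (columns subject, group,
#'   condition, region, suv) containing test, retest and memantine rows for
#'   the group.
#' @param group `"awake"` or `"anesthetized"`.
#' @return List with `per_region` (named percent changes) and `average`.
#' @export
memantine_percent_change <- function(table, group) {
  tb <- table[table$group == group, ]
  if (!nrow(tb)) stop("no rows for group '", group, "'")
  regions <- unique(tb$region)
  need <- c("test", "retest", "memantine")
  if (!all(need %in% tb$condition))
    stop("table must contain test, retest and memantine conditions")
  per <- vapply(regions, function(r) {
    g <- function(cond) {
      v <- tb$suv[tb$region == r & tb$condition == cond]
      if (!length(v)) stop("missing condition '", cond, "' for region ", r)
      mean(v)
    }
    base <- (g("test") + g("retest")) / 2
    100 * (g("memantine") - base) / base
  }, numeric(1))
  names(per) <- regions
  list(per_region = per, average = mean(per))
}

#' Validate an SUV table
#'
#' @param df Data frame with columns `subject`, `group`, `condition`,
#'   `region`, `suv`; SUVs positive, (subject, condition, region) unique.
#' @export
suv_table <- function(df) {
  need <- c("subject", "group", "condition", "region", "suv")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$suv <= 0)) stop("SUVs must be positive")
  key <- paste(df$subject, df$condition, df$region)
  if (anyDuplicated(key)) stop("(subject, condition, region) must be unique")
  df
}

#' Equivalent Gaussian blur between two reconstructions
#'
#' The sigma for which Gaussian filtering of the reference image best
#' matches (least squares) the degraded image, found by golden-section
#' search on [0, 2] mm. Used to express the resolution loss of
#' motion-corrected awake images relative to motion-free ones.
#'
#' @param reference,degraded [voxel_image()]s on a common grid.
#' @param sigma_range Search interval, mm.
#' @param tol Convergence tolerance on sigma, mm.
#' @return Estimated sigma, mm.
#' @export
estimate_blur_sigma <- function(reference, degraded, sigma_range = c(0, 2),
                                tol = 0.001) {
  if (!same_grid(reference$grid, degraded$grid)) stop("grids differ")
  rv <- as.vector(reference$values)
  dv <- as.vector(degraded$values)
  if (all(rv == 0) && all(dv == 0)) stop("both images are identically zero")
  g <- reference$grid
  f <- function(s) {
    b <- if (s > 0) cpp_gauss_blur(rv, g$shape, g$voxel_size, s) else rv
    mean((b - dv)^2)
  }
  gr <- (sqrt(5) - 1) / 2
  a <- sigma_range[1]; b <- sigma_range[2]
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > tol) {
    if (fc < fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- f(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- f(d1)
    }
  }
  # the boundary sigma = 0 is a legitimate minimiser (identical images)
  mid <- (a + b) / 2
  if (f(sigma_range[1]) <= f(mid)) sigma_range[1] else mid
}
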