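test_that("track velocity is the OLS slope with exact edge cases", {
  expect_equal(velocity_of_track(0:9, rep(5, 10))$v, 0)
  v <- velocity_of_track(0:9, 100 * (0:9))
  expect_equal(v$v, 100)
  expect_equal(v$r2, 1)
  expect_error(velocity_of_track(0:2, 1:3), "insufficient")
  # equivariance: adding c * t adds exactly c to the slope
  set.seed(3)
  s <- stats::rnorm(20, sd = 30)
  t <- 0:19
  v0 <- velocity_of_track(t, s)$v
  v1 <- velocity_of_track(t, s + 17 * t)$v
  expect_equal(v1 - v0, 17, tolerance = 1e-10)
})

test_that("mean speed of noisy processive tracks is recovered within 5%", {
  set.seed(7)
  v_true <- 100
  est <- replicate(100, {
    t <- 0:19
    s <- v_true * t + stats::rnorm(20, sd = 30)
    velocity_of_track(t, s)$v
  })
  expect_lt(abs(mean(est) - v_true) / v_true, 0.05)
})

test_that("velocity summaries apply filters and handle edge sizes", {
  one <- summarize_velocities(data.frame(v = 88, r2 = 0.99,
                                         duration = 20))
  expect_equal(one$mean, 88)
  expect_true(is.na(one$sd))
  expect_equal(one$n, 1L)
  three <- summarize_velocities(data.frame(v = c(100, 100, 100),
                                           r2 = 1, duration = 10))
  expect_equal(c(three$mean, three$sd, three$n), c(100, 0, 3))
  none <- summarize_velocities(data.frame(v = 10, r2 = 0.2,
                                          duration = 10), min_r2 = 0.8)
  expect_equal(none$n, 0L)
  # a 42-molecule cohort with log-normal speeds: recovered mean within
  # the Monte-Carlo 95% CI of the generating mean (101 +/- 53 regime)
  mu <- 101; sdv <- 53
  sdlog <- sqrt(log(1 + (sdv / mu)^2))
  mulog <- log(mu) - sdlog^2 / 2
  set.seed(11)
  est <- replicate(42, {
    vt <- stats::rlnorm(1, mulog, sdlog)
    t <- 0:19
    velocity_of_track(t, vt * t + stats::rnorm(20, sd = 30))$v
  })
  sm <- summarize_velocities(data.frame(v = est, r2 = 1, duration = 19))
  expect_lt(abs(sm$mean - mu), 1.96 * sdv / sqrt(42))
})

test_that("step detection finds clean steps exactly and resists noise", {
  s <- c(rep(0, 10), rep(150, 10))
  sf <- detect_steps(0:19, s)
  expect_equal(length(sf$steps), 1)
  expect_equal(sf$steps, 150)
  expect_equal(sf$changepoints, 10)
  # translation invariance
  sf2 <- detect_steps(0:19, s + 1234)
  expect_equal(sf2$changepoints, sf$changepoints)
  expect_equal(sf2$steps, sf$steps)
  expect_error(detect_steps(0:4, rnorm(5)), "short")
  # false positives on flat noisy series
  set.seed(13)
  fp <- sum(replicate(100,
    length(detect_steps(0:49, stats::rnorm(50, sd = 20))$steps) > 0))
  expect_lte(fp, 5)
})

test_that("staircases in the 100-200 nm regime are recovered", {
  set.seed(17)
  hits <- 0; total <- 0; errs <- c()
  for (r in 1:20) {
    sizes <- stats::runif(5, 100, 200)
    s <- rep(cumsum(c(0, sizes)), each = 6) + stats::rnorm(36, sd = 30)
    sf <- detect_steps(0:35, s, noise_scale = 30)
    total <- total + 5
    hits <- hits + min(length(sf$steps), 5)
    if (length(sf$steps) == 5) errs <- c(errs, abs(sf$steps - sizes))
  }
  expect_gte(hits / total, 0.8)
  expect_lt(mean(errs), 30)
})

test_that("MSD analysis matches closed forms", {
  t <- 0:19
  m <- msd_curve(t, 100 * t)
  expect_equal(m$alpha, 2, tolerance = 0.05)
  expect_equal(m$msd, (100 * m$lag_s)^2, tolerance = 1e-9)
  set.seed(19)
  D <- 1e4
  s <- cumsum(c(0, stats::rnorm(199, sd = sqrt(2 * D))))
  m2 <- msd_curve(0:199, s)
  expect_lt(abs(m2$D - D) / D, 0.3)
  # static + localization noise plateaus at 2 sigma^2
  set.seed(23)
  m3 <- msd_curve(0:199, stats::rnorm(200, sd = 30))
  expect_lt(abs(mean(m3$msd) - 2 * 30^2) / (2 * 30^2), 0.15)
  expect_error(msd_curve(0:5, 1:6), "short")
})

test_that("motility classification is rule-based and deterministic", {
  t <- 0:29
  expect_equal(classify_motility(t, rep(100, 30))$mode, "static")
  expect_equal(classify_motility(t, 100 * t)$mode, "processive")
  set.seed(29)
  s <- cumsum(c(0, stats::rnorm(29, sd = sqrt(2 * 2e4)))) +
    stats::rnorm(30, sd = 30)
  c1 <- classify_motility(t, s)
  c2 <- classify_motility(t, s)
  expect_identical(c1$mode, c2$mode)
  short <- classify_motility(0:3, c(1, 2, 3, 4))
  expect_equal(short$mode, "unclassified")
})

test_that("bleaching survival is the censored exponential MLE", {
  b <- bleaching_survival(rep(20, 12))
  expect_equal(b$rate, 1 / 20)
  expect_error(bleaching_survival(rep(5, 12), censored = rep(TRUE, 12)),
               "censored")
  expect_error(bleaching_survival(1:5), "tracks")
  set.seed(31)
  d <- stats::rexp(400, 0.05)
  cen <- d > 60
  d[cen] <- 60
  b2 <- bleaching_survival(d, cen)
  expect_lt(abs(b2$rate - 0.05) / 0.05, 0.15)
  # cross-check against the survival package's parametric fit
  sr <- survival::survreg(survival::Surv(d, !cen) ~ 1,
                          dist = "exponential")
  expect_equal(b2$rate, 1 / exp(unname(stats::coef(sr))),
               tolerance = 1e-6)
  expect_true(all(diff(b2$survival$S) <= 1e-12))
})

test_that("per-track kinetics tables cover every track", {
  b <- benchmark_tracks(n_per_mode = 3, n_frames = 40, seed = 5)
  kin <- track_kinetics(b$tracks, sigma_loc = 30)
  expect_equal(nrow(kin), 12)
  expect_true(all(c("track_id", "mode", "v", "r2", "n_steps",
                    "duration_s") %in% names(kin)))
})
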