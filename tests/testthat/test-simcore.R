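test_that("configuration and geometry invariants are enforced", {
  expect_error(sim_config(exposure = 2, frame_interval = 1), "exposure")
  expect_error(sim_config(pixel_size = -1), "pixel_size")
  expect_error(sim_config(background_rate = -5), "background_rate")
  expect_error(stereocilium_geometry(c(0, 0), c(0, 0)), "differ")
  expect_error(stereocilium_geometry(c(0, 0), c(1, 0), radius = -1),
               "radius")
  expect_error(motility_model("processive", speed = -10), "speed")
  expect_error(photophysics_model(0), "n_fluorophores")
  geo <- stereocilium_geometry(c(0, 0), c(8000, 0))
  cfg <- sim_config(n_frames = 3)
  expect_error(
    simulate_movie(cfg, geo, list(emitter(motility_model("static"),
                                          start = 9000))),
    "outside geometry")
  expect_error(sample_trajectory(motility_model("static"), geo, -5, 10, 1),
               "outside")
})

test_that("a pure-background movie matches the camera model mean", {
  geo <- stereocilium_geometry(c(0, 0), c(8000, 0))
  cfg <- sim_config(image_shape = c(48, 48), n_frames = 10,
                    background_rate = 7, camera_offset = 60,
                    camera_gain = 1, read_noise_sd = 2, seed = 3)
  sim <- simulate_movie(cfg, geo, list())
  vals <- as.vector(sim$movie$data)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 67), 3 * se)
})

test_that("trajectories follow their kinematic models exactly", {
  geo <- stereocilium_geometry(c(0, 0), c(2000, 0))
  expect_equal(sample_trajectory(motility_model("static"), geo, 700, 8, 1,
                                 seed = 4),
               rep(700, 8))
  s <- sample_trajectory(motility_model("processive", speed = 100), geo,
                         0, 10, 1, seed = 1)
  expect_identical(s[1:5], c(0, 100, 200, 300, 400))
  # absorbed at the tip, never beyond
  s2 <- sample_trajectory(motility_model("processive", speed = 500), geo,
                          0, 10, 1, seed = 1)
  expect_true(all(s2 <= 2000))
  expect_true(all(diff(s2) >= 0))
  # step-wise: piecewise constant with jumps of exactly step_size
  st <- sample_trajectory(motility_model("stepwise", step_size = 150,
                                         step_rate = 0.2),
                          long_axis(), 5e5, 50, 1, seed = 7)
  jumps <- diff(st)
  expect_true(all(abs(jumps) < 1e-9 | abs(jumps - 150) < 1e-9 |
                    jumps > 150))
  expect_error(sample_trajectory(structure(list(mode = "warp"),
                                           class = "motility_model"),
                                 geo, 0, 5, 1),
               "unknown")
})

test_that("diffusive increments match the analytic variance", {
  D <- 1e5
  s <- sample_trajectory(motility_model("diffusive", diffusion_coeff = D),
                         long_axis(), 5e5, 10001, 1, seed = 11)
  expect_lt(abs(stats::var(diff(s)) - 2 * D) / (2 * D), 0.05)
})

test_that("photobleaching is absorbing and follows exponential survival", {
  geo <- stereocilium_geometry(c(0, 0), c(8000, 0))
  k_b <- 0.05
  n <- 500
  nf <- 80
  # ground-truth lifetimes across many single-fluorophore emitters
  cfg <- sim_config(image_shape = c(16, 16), n_frames = nf, seed = 21)
  lifetimes <- numeric(n); censored <- logical(n)
  for (i in seq_len(n)) {
    vis <- kymotor:::sample_photophysics(
      photophysics_model(1, bleach_rate = k_b), nf, 1, seed = 1000 + i)
    expect_true(all(diff(vis[, 1]) <= 0))     # absorbing: never re-emits
    alive <- sum(vis[, 1])
    lifetimes[i] <- alive
    censored[i] <- alive == nf
  }
  # closed-form censored ML oracle: events / total observed time
  rate_oracle <- sum(!censored) / sum(lifetimes)
  expect_lt(abs(rate_oracle - k_b) / k_b, 0.15)
})

test_that("a lossless static emitter is visible in every frame", {
  geo <- stereocilium_geometry(c(0, 0), c(8000, 0))
  cfg <- sim_config(image_shape = c(32, 48), n_frames = 25, seed = 5)
  sim <- simulate_movie(cfg, geo,
                        list(emitter(motility_model("static"),
                                     photophysics_model(1, bleach_rate = 0),
                                     start = 4000)))
  expect_true(all(sim$truth$emitters[[1]]$visible_any))
  expect_equal(length(sim$truth$emitters[[1]]$axial_nm), 25)
})

test_that("the same seed reproduces movie and ground truth bit for bit", {
  geo <- stereocilium_geometry(c(500, 2600), c(7500, 2600))
  cfg <- sim_config(image_shape = c(32, 48), n_frames = 12, seed = 99,
                    drift = drift_model(velocity = c(1, -0.5),
                                        random_walk_sd = 2))
  ems <- list(emitter(motility_model("diffusive"), start = 3000),
              emitter(motility_model("stepwise"), start = 1000))
  a <- simulate_movie(cfg, geo, ems)
  b <- simulate_movie(cfg, geo, ems)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$drift_nm, b$truth$drift_nm)
  expect_identical(a$truth$emitters[[1]]$axial_nm,
                   b$truth$emitters[[1]]$axial_nm)
})

test_that("summed intensity is linear in fluorophore count", {
  set.seed(31)
  counts <- 1:4
  S <- list()
  for (cnt in counts) {
    vals <- replicate(60, {
      fr <- noisy_spot_frame(cbind(20.3, 20.6, 400 * cnt), ny = 40,
                             nx = 40, background = 5, read_noise = 1)
      sum_intensity(fr, 20.3, 20.6)$S
    })
    S[[cnt]] <- vals
  }
  df <- data.frame(count = rep(counts, each = 60), S = unlist(S))
  fit <- summary(stats::lm(S ~ count, data = df))
  expect_gt(fit$r.squared, 0.99)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- sim_config(n_frames = 7, quantal_yield = 123,
                    drift = drift_model(velocity = c(3, -2),
                                        random_walk_sd = 1))
  tf <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, tf)
  cfg2 <- read_sim_config(tf)
  expect_equal(cfg2$n_frames, 7L)
  expect_equal(cfg2$quantal_yield, 123)
  expect_equal(cfg2$drift$velocity, c(3, -2))
  unlink(tf)
})

test_that("ground truth exports are written and internally consistent", {
  geo <- stereocilium_geometry(c(0, 1600), c(8000, 1600))
  cfg <- sim_config(image_shape = c(24, 56), n_frames = 6, seed = 2)
  sim <- simulate_movie(cfg, geo,
                        list(emitter(motility_model("processive",
                                                    speed = 200),
                                     start = 100)))
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, jf, cf)
  gt <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(gt$n_frames, 6)
  expect_equal(gt$emitters$mode, "processive")
  csv <- utils::read.csv(cf)
  expect_equal(nrow(csv), 6)
  expect_equal(csv$s_nm, sim$truth$emitters[[1]]$axial_nm)
  unlink(c(jf, cf))
})
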