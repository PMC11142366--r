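test_that("blank frames produce almost no false detections at 5 sigma", {
  set.seed(17)
  fp <- sum(replicate(100, {
    fr <- noisy_spot_frame(NULL)
    nrow(detect_puncta(fr, threshold_sd = 5)) > 0
  }))
  expect_lte(fp, 5)
})

test_that("a single punctum is localized to subpixel accuracy", {
  set.seed(23)
  fr <- noisy_spot_frame(cbind(30.3, 20.7, 400))  # SNR ~ 10 over background
  d <- detect_puncta(fr, psf_sigma_px = 1)
  expect_equal(nrow(d), 1)
  expect_lt(max(abs(c(d$x - 30.3, d$y - 20.7))), 0.5)
})

test_that("well-separated identical puncta are both found", {
  set.seed(29)
  fr <- noisy_spot_frame(cbind(c(25, 35), c(30, 30), 400))
  d <- detect_puncta(fr)
  expect_equal(nrow(d), 2)
})

test_that("summed intensity recovers the rendered mass and cancels background", {
  fr <- clean_spot_frame(cbind(31.2, 28.6, 500), baseline = 40)
  m <- sum_intensity(fr, 31.2, 28.6, window_radius = 3)
  expect_lt(abs(m$S - 500) / 500, 0.02)
  expect_equal(m$b, 40, tolerance = 1e-6)
  # window-radius invariance beyond 3 sigma of the PSF
  for (r in 4:5) {
    mr <- sum_intensity(fr, 31.2, 28.6, window_radius = r,
                        annulus = c(r + 2, r + 4))
    expect_lt(abs(mr$S - m$S) / m$S, 0.02)
  }
  # pure background: E[S] = 0 within 3 standard errors
  set.seed(41)
  S0 <- replicate(100, {
    bg <- noisy_spot_frame(NULL, ny = 32, nx = 32)
    sum_intensity(bg, 15, 15)$S
  })
  expect_lt(abs(mean(S0)), 3 * stats::sd(S0) / sqrt(length(S0)))
})

test_that("two-fluorophore puncta are twice as bright as one-fluorophore", {
  set.seed(43)
  S1 <- replicate(80, sum_intensity(noisy_spot_frame(cbind(20, 20, 400),
                                                     ny = 40, nx = 40),
                                    20, 20)$S)
  S2 <- replicate(80, sum_intensity(noisy_spot_frame(cbind(20, 20, 800),
                                                     ny = 40, nx = 40),
                                    20, 20)$S)
  expect_lt(abs(mean(S2) / mean(S1) - 2), 0.1)
})

test_that("the two-population classifier separates quantal intensities", {
  # population parameters as printed for the labelling-control experiment
  set.seed(47)
  x <- c(stats::rnorm(16, 34, 10), stats::rnorm(12, 76, 10))
  truth <- rep(1:2, c(16, 12))
  fit <- classify_populations(x)
  expect_gte(mean(fit$assignment == truth), 0.9)
  expect_true(fit$bimodal)
  expect_lt(fit$means[1], fit$means[2])
  # mean ratio of a mu / 2 mu mixture within 10% of 2
  set.seed(53)
  y <- c(stats::rnorm(100, 40, 10), stats::rnorm(100, 80, 10))
  expect_lt(abs(classify_populations(y)$ratio - 2) / 2, 0.1)
})

test_that("classifier agrees with an independent mixture fit", {
  suppressMessages(library(mclust))
  set.seed(59)
  x <- c(stats::rnorm(60, 35, 9), stats::rnorm(50, 78, 9))
  fit <- classify_populations(x)
  mc <- Mclust(x, G = 2, modelNames = "E", verbose = FALSE)
  ours <- sort(fit$means)
  theirs <- sort(as.numeric(mc$parameters$mean))
  expect_lt(max(abs(ours - theirs) / theirs), 0.05)
})

test_that("degenerate and unimodal inputs are handled", {
  expect_error(classify_populations(c(1, 2, 3)), "insufficient")
  same <- classify_populations(rep(5, 10))
  expect_false(same$bimodal)
  expect_true(all(same$assignment == 1L))
  set.seed(61)
  flags <- replicate(100, classify_populations(stats::rnorm(40, 50, 8))$bimodal)
  expect_gte(mean(!flags), 0.95)
})

test_that("line scans profile the PSF at the expected width", {
  fr <- clean_spot_frame(cbind(30.0, 25.0, 800), sigma_px = 1.5,
                         baseline = 5)
  p <- line_scan(fr, c(30, 25), c(1, 0), 8)
  expect_equal(which.max(p$intensity), (length(p$pos) + 1) / 2)
  g <- fit_gaussian_profile(p$pos, p$intensity)
  # pixel integration widens sigma to sqrt(1.5^2 + 1/12)
  expect_lt(abs(g$fwhm - 2.355 * 1.5) / (2.355 * 1.5), 0.05)
  expect_error(line_scan(fr, c(2, 2), c(1, 0), 8), "outside")
})

test_that("averaging line scans reduces noise", {
  set.seed(67)
  profiles <- lapply(1:10, function(i) {
    fr <- noisy_spot_frame(cbind(30, 25, 600), sigma_px = 1.5)
    line_scan(fr, c(30, 25), c(1, 0), 7)
  })
  clean <- line_scan(clean_spot_frame(cbind(30, 25, 600), sigma_px = 1.5,
                                      baseline = 110),
                     c(30, 25), c(1, 0), 7)
  avg <- average_line_scan(profiles)
  rms <- function(p) sqrt(mean((p$intensity - clean$intensity)^2))
  expect_lt(rms(avg), min(vapply(profiles, rms, numeric(1))))
})

test_that("PSF comparison flags point sources and extended sources", {
  model <- gaussian_profile(1.5, 8)
  ident <- compare_to_psf(model, model)
  expect_lt(ident$nrms, 1e-9)
  expect_equal(ident$width_ratio, 1, tolerance = 1e-9)
  expect_true(ident$point_source)
  # extended source: model convolved with a disc of radius 2 sigma
  sigma <- 1.5
  pos <- seq(-8, 8, by = 1)
  disc_halfwidth <- 2 * sigma
  wide <- vapply(pos, function(x) {
    stats::integrate(function(u)
      exp(-(x - u)^2 / (2 * sigma^2)) / (2 * disc_halfwidth),
      -disc_halfwidth, disc_halfwidth)$value
  }, numeric(1))
  ext <- compare_to_psf(list(pos = pos, intensity = wide), model)
  expect_gt(ext$width_ratio, 1.25)
  expect_false(ext$point_source)
  set.seed(71)
  noise <- list(pos = pos, intensity = stats::rnorm(length(pos)))
  expect_false(compare_to_psf(noise, model)$is_punctum)
})
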