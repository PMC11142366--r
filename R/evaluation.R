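# Reproducible evaluation studies: each evaluate_*() builds its synthetic
# inputs from a seed, runs the relevant pipeline stages from scratch, and
# returns the measured quantities. These back the package's validation
# suite and the acceptance script.

# Independent exhaustive oracle for translation estimation: sum of squared
# differences between frame_a and frame_b resampled on a dense shift grid.
# Deliberately brute-force; shares no code path with the estimators.
ssd_grid_search <- function(frame_a, frame_b, center, half_window = 0.6,
                            step = 0.01) {
  ny <- nrow(frame_a); nx <- ncol(frame_a)
  # interior region so every candidate shift stays in-bounds
  margin <- ceiling(abs(center[1]) + abs(center[2]) + half_window) + 2
  rows <- (margin + 1):(ny - margin)
  cols <- (margin + 1):(nx - margin)
  interp_at <- function(dx, dy) {
    # direct bilinear interpolation of frame_b at (col-1+dx, row-1+dy)
    x <- outer(rep(1, length(rows)), cols - 1) + dx
    y <- outer(rows - 1, rep(1, length(cols))) + dy
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    v00 <- frame_b[cbind(as.vector(y0 + 1), as.vector(x0 + 1))]
    v01 <- frame_b[cbind(as.vector(y0 + 1), as.vector(x0 + 2))]
    v10 <- frame_b[cbind(as.vector(y0 + 2), as.vector(x0 + 1))]
    v11 <- frame_b[cbind(as.vector(y0 + 2), as.vector(x0 + 2))]
    (1 - as.vector(fy)) * ((1 - as.vector(fx)) * v00 + as.vector(fx) * v01) +
      as.vector(fy) * ((1 - as.vector(fx)) * v10 + as.vector(fx) * v11)
  }
  a_ref <- as.vector(frame_a[rows, cols])
  dxs <- seq(center[1] - half_window, center[1] + half_window, by = step)
  dys <- seq(center[2] - half_window, center[2] + half_window, by = step)
  best <- c(NA, NA); best_ssd <- Inf
  for (dy in dys) for (dx in dxs) {
    ssd <- sum((interp_at(dx, dy) - a_ref)^2)
    if (ssd < best_ssd) { best_ssd <- ssd; best <- c(dx, dy) }
  }
  # a minimum on the grid border means the basin lies outside the window
  on_border <- best[1] %in% range(dxs) || best[2] %in% range(dys)
  attr(best, "on_border") <- on_border
  best
}

# A static-rich registration scene: irregularly placed bright static
# molecules (plus optional extra emitters) on a stereocilium axis.
.registration_scene <- function(seed, drift, n_frames = 100,
                                quantal_yield = 1500, n_spots = 14,
                                extra = list()) {
  geo <- stereocilium_geometry(c(800, 5200), c(9600, 5200))
  starts <- with_seed(seed + 1, sort(stats::runif(n_spots, 200, 8600)))
  ems <- c(lapply(starts, function(s)
    emitter(motility_model("static"), photophysics_model(1), start = s)),
    extra)
  cfg <- sim_config(image_shape = c(64, 64), n_frames = n_frames,
                    quantal_yield = quantal_yield, drift = drift,
                    seed = seed)
  simulate_movie(cfg, geo, ems)
}

#' Quantal-ratio study: one- vs two-fluorophore puncta
#'
#' Simulates a field of well-separated static puncta carrying one or two
#' fluorophores, measures background-subtracted summed intensities on an
#' average projection, classifies them into two populations, and reports
#' the Pop2/Pop1 mean-intensity ratio (expected: 2, the quantal logic of
#' fluorophore counting).
#'
#' @param seed random seed.
#' @param n1,n2 number of one- and two-fluorophore puncta.
#' @return list with `ratio`, `pop1_mean`, `pop2_mean`, `label_accuracy`
#'   (against ground truth), `bimodal`, `n`.
#' @export
evaluate_quantal_ratio <- function(seed = 1, n1 = 32, n2 = 28) {
  n <- n1 + n2
  # jittered grid keeps puncta >= 12 px apart on a 162.5 nm/px frame
  cols_n <- ceiling(sqrt(n))
  rows_n <- ceiling(n / cols_n)
  pitch_px <- 12
  margin_px <- 10
  side_y <- (rows_n - 1) * pitch_px + 2 * margin_px
  side_x <- (cols_n - 1) * pitch_px + 2 * margin_px
  px <- 162.5
  geo <- stereocilium_geometry(c(margin_px, margin_px) * px,
                               c(side_x - margin_px, margin_px) * px,
                               radius = 0)
  # place puncta by hand across the grid (geometry axis unused for statics)
  idx <- seq_len(n) - 1
  gx <- margin_px + (idx %% cols_n) * pitch_px
  gy <- margin_px + (idx %/% cols_n) * pitch_px
  jit <- with_seed(seed + 7, matrix(stats::runif(2 * n, -1.5, 1.5), n, 2))
  n_fluor <- c(rep(1L, n1), rep(2L, n2))
  cfg <- sim_config(image_shape = c(side_y, side_x), pixel_size = px,
                    n_frames = 8, quantal_yield = 400,
                    background_rate = 10, seed = seed)
  # render via the simulator one emitter at a time along a per-row axis
  sig <- array(0, dim = c(side_y, side_x, cfg$n_frames))
  sigma_px <- cfg$psf_sigma / px
  for (i in seq_len(n)) {
    for (f in seq_len(cfg$n_frames)) {
      sig[, , f] <- render_gaussian_spot(sig[, , f], gx[i] + jit[i, 1],
                                         gy[i] + jit[i, 2], sigma_px,
                                         cfg$quantal_yield * n_fluor[i])
    }
  }
  frames <- with_seed(seed + 11, {
    out <- array(0, dim = dim(sig))
    for (f in seq_len(cfg$n_frames)) {
      lam <- sig[, , f] + cfg$background_rate
      out[, , f] <- cfg$camera_offset +
        matrix(stats::rpois(length(lam), lam), side_y, side_x) +
        matrix(stats::rnorm(length(lam), sd = cfg$read_noise_sd),
               side_y, side_x)
    }
    out
  })
  movie <- Movie(frames, px, cfg$frame_interval)
  # average projection, as for a volume scan, then detect and measure
  proj <- apply(movie$data, c(1, 2), mean)
  det <- detect_puncta(proj, psf_sigma_px = sigma_px)
  meas <- vapply(seq_len(nrow(det)), function(k)
    sum_intensity(proj, det$x[k], det$y[k])$S, numeric(1))
  fit <- classify_populations(meas)
  # match detections back to ground-truth fluorophore counts
  truth_pop <- vapply(seq_len(nrow(det)), function(k) {
    i <- which.min((gx + jit[, 1] - det$x[k])^2 + (gy + jit[, 2] - det$y[k])^2)
    n_fluor[i]
  }, integer(1))
  list(ratio = fit$ratio, pop1_mean = fit$means[1],
       pop2_mean = fit$means[2],
       label_accuracy = mean(fit$assignment == truth_pop),
       bimodal = fit$bimodal, n = fit$n)
}

#' Drift-recovery study
#'
#' Simulates 100-frame movies of a static-rich scene under three drift
#' regimes (integer-scale linear, subpixel linear, random walk), runs
#' [correct_movie()], and reports the RMS error of the recovered
#' cumulative shifts against the simulator's ground truth, together with
#' the antisymmetry and composition residuals of the shift estimator on
#' clean frame pairs.
#'
#' @param seed random seed.
#' @return list with `rms_linear_px`, `rms_subpixel_px`,
#'   `rms_random_walk_px`, `max_rms_px`, `antisymmetry_px`,
#'   `composition_px`, `n_frames`.
#' @export
evaluate_drift_recovery <- function(seed = 1) {
  regimes <- list(
    linear = drift_model(velocity = c(8.125, -4.0625)),      # 0.05 px/s
    subpixel = drift_model(velocity = c(0.5, -0.3)),         # nm/s
    random_walk = drift_model(random_walk_sd = 5))
  rms <- vapply(seq_along(regimes), function(k) {
    sim <- .registration_scene(seed + k, regimes[[k]])
    cc <- correct_movie(sim$movie)
    true_px <- sweep(sim$truth$drift_nm, 2, sim$truth$drift_nm[1, ]) /
      sim$movie$pixel_size
    sqrt(mean((cbind(cc$trace$dx_px, cc$trace$dy_px) - true_px)^2))
  }, numeric(1))
  # invariants on clean pairs drawn from one movie
  sim <- .registration_scene(seed + 9, drift_model(velocity = c(10, 6)),
                             n_frames = 9)
  f <- function(i) get_frame(sim$movie, i)
  anti <- comp <- 0
  for (i in c(1, 4)) {
    s_ab <- estimate_shift(f(i), f(i + 2))$shift
    s_ba <- estimate_shift(f(i + 2), f(i))$shift
    anti <- max(anti, max(abs(s_ab + s_ba)))
    s_ac <- estimate_shift(f(i), f(i + 4))$shift
    s_bc <- estimate_shift(f(i + 2), f(i + 4))$shift
    comp <- max(comp, max(abs(s_ac - (s_ab + s_bc))))
  }
  list(rms_linear_px = rms[1], rms_subpixel_px = rms[2],
       rms_random_walk_px = rms[3], max_rms_px = max(rms),
       antisymmetry_px = anti, composition_px = comp, n_frames = 100)
}

#' Subpixel oracle-equivalence study
#'
#' Renders noise-free frame pairs at known subpixel shifts, estimates each
#' shift with the full cascade (phase correlation, closed-form refinement,
#' least-squares matching), and compares against an exhaustive
#' sum-of-squared-differences grid search at 0.01 px resolution.
#'
#' @param seed random seed (spot placement).
#' @return list with `max_abs_diff_px` (estimator vs grid oracle),
#'   `max_err_truth_px` (estimator vs true shift), `n_cases`.
#' @export
evaluate_subpixel_agreement <- function(seed = 1) {
  shifts <- list(c(2.4, -1.6), c(0.5, 0.5), c(-1.3, 0.7), c(0.2, 0.1))
  spots <- with_seed(seed, cbind(stats::runif(25, 8, 56),
                                 stats::runif(25, 8, 56)))
  render <- function(dx, dy) {
    m <- matrix(0, 64, 64)
    for (k in seq_len(nrow(spots)))
      m <- render_gaussian_spot(m, spots[k, 1] + dx, spots[k, 2] + dy,
                                1.3, 600)
    m + 20
  }
  a <- render(0, 0)
  diffs <- errs <- numeric(length(shifts))
  for (j in seq_along(shifts)) {
    d <- shifts[[j]]
    b <- render(d[1], d[2])
    est <- estimate_shift(a, b, smooth_sigma = 0)$shift
    oracle <- ssd_grid_search(a, b, center = est, half_window = 0.2)
    diffs[j] <- if (isTRUE(attr(oracle, "on_border"))) Inf
                else max(abs(est - oracle))
    errs[j] <- max(abs(est - d))
  }
  list(max_abs_diff_px = max(diffs), max_err_truth_px = max(errs),
       n_cases = length(shifts))
}

# shared driver: simulate movies of one motility mode and return the
# projected tracks plus ground truth
.recovery_movies <- function(seed, mode_builder, n_movies, n_emitters,
                             spacing_px, n_frames, frame_interval = 1,
                             quantal_yield = 400, margin_px = 10,
                             headroom_px = 0) {
  px <- 162.5
  # headroom keeps directed runs clear of the absorbing tip and diffusive
  # walkers clear of the reflecting ends
  len_px <- (n_emitters - 1) * spacing_px + 2 * margin_px + headroom_px
  all_tracks <- list(); truths <- list()
  for (m in seq_len(n_movies)) {
    geo <- stereocilium_geometry(c(margin_px, 16) * px,
                                 c(len_px - margin_px, 16) * px)
    starts <- (headroom_px / 2 + (seq_len(n_emitters) - 1) * spacing_px) * px
    ems <- lapply(seq_len(n_emitters), function(i)
      mode_builder(start = starts[i], index = i, movie = m))
    cfg <- sim_config(image_shape = c(32, len_px), pixel_size = px,
                      frame_interval = frame_interval,
                      n_frames = n_frames, quantal_yield = quantal_yield,
                      seed = seed + 137 * m)
    sim <- simulate_movie(cfg, geo, ems)
    det <- detect_movie(sim$movie, psf_sigma_px = cfg$psf_sigma / px)
    trk <- link_tracks(det, pixel_size = px)
    path <- organelle_path(rbind(geo$base_point, geo$tip_point) / px,
                           half_width = 2, pixel_size = px)
    trk <- project_to_axis(trk, path, frame_interval = frame_interval)
    trk$track_id <- trk$track_id + 10000 * m
    all_tracks[[m]] <- as.data.frame(trk)
    truths[[m]] <- sim$truth
  }
  list(tracks = do.call(rbind, all_tracks), truths = truths)
}

#' End-to-end parameter-recovery study
#'
#' Simulates movies of processive, step-wise, diffusive and bleaching
#' emitters, runs the full image pipeline (detection, linking, axial
#' projection), and recovers each generating parameter with the kinetics
#' module: processive speed (truth 100 nm/s), step sizes (truth drawn from
#' 100-200 nm), diffusion coefficient (truth 1e4 nm^2/s) and
#' photobleaching rate (truth 0.05 /s).
#'
#' @param seed random seed.
#' @return list with recovered values, relative errors, and problem sizes.
#' @export
evaluate_parameter_recovery <- function(seed = 1) {
  px <- 162.5
  ## processive speed: 5 movies x 20 emitters at 100 nm/s
  proc <- .recovery_movies(seed, function(start, index, movie)
    emitter(motility_model("processive", speed = 100), start = start),
    n_movies = 5, n_emitters = 20, spacing_px = 10, n_frames = 20,
    headroom_px = 16)
  kin <- track_kinetics(proc$tracks, sigma_loc = 20)
  vs <- kin$v[kin$n >= 10 & !is.na(kin$v)]
  speed_mean <- mean(vs)

  ## step sizes: 4 movies x 15 emitters, steps of 100-200 nm
  step_truth <- new.env()
  assign("sizes", list(), envir = step_truth)
  stp <- .recovery_movies(seed + 1000, function(start, index, movie) {
    sz <- with_seed(seed + 1000 + 31 * movie + index,
                    stats::runif(1, 100, 200))
    key <- sprintf("m%d_i%d", movie, index)
    assign(key, sz, envir = step_truth)
    emitter(motility_model("stepwise", step_size = sz, step_rate = 0.08),
            start = start)
  }, n_movies = 4, n_emitters = 15, spacing_px = 14, n_frames = 60,
    headroom_px = 10)
  found <- 0; expected <- 0; size_err <- c()
  for (m in seq_along(stp$truths)) {
    truth <- stp$truths[[m]]
    for (i in seq_along(truth$emitters)) {
      true_s <- truth$emitters[[i]]$axial_nm
      true_steps <- sum(diff(true_s) > 1)
      if (true_steps < 1) next
      # locate this emitter's track by its start position
      start_nm <- true_s[1]
      cand <- stp$tracks[abs(stp$tracks$s_nm - start_nm) < 7 * px / 2 &
                           stp$tracks$track_id %/% 10000 == m, ]
      if (nrow(cand) == 0) next
      id <- cand$track_id[which.min(abs(cand$s_nm - start_nm))]
      tr <- stp$tracks[stp$tracks$track_id == id, ]
      if (nrow(tr) < 10) next
      sf <- detect_steps(tr$t_s, tr$s_nm, noise_scale = 20)
      expected <- expected + true_steps
      found <- found + min(length(sf$steps), true_steps)
      true_sizes <- diff(true_s)[diff(true_s) > 1]
      est_sizes <- sf$steps
      for (k in seq_len(min(length(est_sizes), length(true_sizes))))
        size_err <- c(size_err, abs(est_sizes[k] - true_sizes[k]))
    }
  }

  ## diffusion: 3 movies x 12 emitters, D = 1e4 nm^2/s
  dif <- .recovery_movies(seed + 2000, function(start, index, movie)
    emitter(motility_model("diffusive", diffusion_coeff = 1e4),
            start = start),
    n_movies = 3, n_emitters = 12, spacing_px = 18, n_frames = 60,
    headroom_px = 14)
  ids <- unique(dif$tracks$track_id)
  Dhat <- vapply(ids, function(id) {
    tr <- dif$tracks[dif$tracks$track_id == id, ]
    if (nrow(tr) < 30) return(NA_real_)
    msd_curve(tr$t_s, tr$s_nm)$D
  }, numeric(1))
  Dhat <- Dhat[!is.na(Dhat)]
  D_mean <- mean(Dhat)

  ## photobleaching: 4 movies x 25 static emitters, k_b = 0.05 /s
  blc <- .recovery_movies(seed + 3000, function(start, index, movie)
    emitter(motility_model("static"),
            photophysics_model(1, bleach_rate = 0.05), start = start),
    n_movies = 4, n_emitters = 25, spacing_px = 8, n_frames = 100)
  ids <- unique(blc$tracks$track_id)
  durs <- t(vapply(ids, function(id) {
    fr <- blc$tracks$frame[blc$tracks$track_id == id]
    c(max(fr) - min(fr) + 1, max(fr) >= 100)
  }, numeric(2)))
  keep <- durs[, 1] >= 1
  bs <- bleaching_survival(durs[keep, 1], censored = durs[keep, 2] > 0)

  list(speed_mean_nm_s = speed_mean,
       speed_err_pct = 100 * abs(speed_mean - 100) / 100,
       speed_n = length(vs),
       step_detection_rate = found / max(expected, 1),
       step_size_mae_nm = mean(size_err),
       step_n = expected,
       diffusion_D_nm2_s = D_mean,
       diffusion_err_pct = 100 * abs(D_mean - 1e4) / 1e4,
       diffusion_n = length(Dhat),
       bleach_rate_per_s = bs$rate,
       bleach_err_pct = 100 * abs(bs$rate - 0.05) / 0.05,
       bleach_n = bs$n)
}

#' Control-phenotype study: static and freely diffusing molecules
#'
#' Reproduces the two imaging-control behaviours: (i) static molecules in
#' a drifting movie give, after drift correction, kymograph trajectories
#' parallel to the time axis (per-track |slope| below a few nm/s); (ii)
#' molecules diffusing as fast as an unfused cytosolic tag yield mostly
#' single-frame tracks at 1 s frame intervals.
#'
#' @param seed random seed.
#' @param D_free diffusion coefficient of the free tag, nm^2/s (default
#'   25 um^2/s, typical of a small unfused cytosolic protein).
#' @return list with `max_static_speed_nm_s`, `single_frame_fraction`,
#'   `n_static_tracks`, `n_free_tracks`.
#' @export
evaluate_control_phenotypes <- function(seed = 1, D_free = 2.5e7) {
  ## static molecules + drift, corrected
  sim <- .registration_scene(seed, drift_model(velocity = c(4, -2.5),
                                               random_walk_sd = 3),
                             n_frames = 60)
  cc <- correct_movie(sim$movie)
  px <- sim$movie$pixel_size
  det <- detect_movie(cc$movie, psf_sigma_px = 152 / px)
  trk <- link_tracks(det, pixel_size = px)
  path <- organelle_path(rbind(c(800, 5200), c(9600, 5200)) / px,
                         half_width = 3, pixel_size = px)
  trk <- project_to_axis(trk, path, frame_interval = 1)
  ids <- unique(trk$track_id)
  slopes <- vapply(ids, function(id) {
    d <- trk[trk$track_id == id, ]
    if (nrow(d) < 30) return(NA_real_)
    velocity_of_track(d$t_s, d$s_nm)$v
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]

  ## free diffusion at 1 s intervals: sparse fast diffusers
  lens <- integer(0)
  for (m in 1:3) {
    geo <- stereocilium_geometry(c(1600, 2600), c(50400, 2600))
    ems <- lapply(seq(6000, 46000, length.out = 5), function(s)
      emitter(motility_model("diffusive", diffusion_coeff = D_free),
              start = s))
    cfg <- sim_config(image_shape = c(32, 320), n_frames = 40,
                      frame_interval = 1, seed = seed + 5 + m)
    simf <- simulate_movie(cfg, geo, ems)
    detf <- detect_movie(simf$movie, psf_sigma_px = 152 / 162.5)
    trkf <- link_tracks(detf, pixel_size = 162.5)
    lens <- c(lens, unname(table(trkf$track_id)))
  }
  list(max_static_speed_nm_s = max(abs(slopes)),
       single_frame_fraction = mean(lens == 1),
       n_static_tracks = length(slopes),
       n_free_tracks = length(lens))
}

#' Motility-classifier benchmark
#'
#' Runs [classify_motility()] over the labelled four-mode track benchmark
#' from [benchmark_tracks()] and reports per-mode accuracies.
#'
#' @param seed random seed.
#' @param n_per_mode tracks per mode.
#' @return list with per-mode accuracies, `min_accuracy`, `n`.
#' @export
evaluate_classifier <- function(seed = 1, n_per_mode = 100) {
  b <- benchmark_tracks(n_per_mode = n_per_mode, n_frames = 100,
                        sigma_loc = 30, seed = seed)
  ids <- unique(b$tracks$track_id)
  ok <- vapply(ids, function(id) {
    d <- b$tracks[b$tracks$track_id == id, ]
    classify_motility(d$t_s, d$s_nm, sigma_loc = 30)$mode == d$mode[1]
  }, logical(1))
  acc <- tapply(ok, b$modes, mean)
  list(static = unname(acc["static"]),
       diffusive = unname(acc["diffusive"]),
       processive = unname(acc["processive"]),
       stepwise = unname(acc["stepwise"]),
       min_accuracy = min(acc), n = length(ids))
}
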