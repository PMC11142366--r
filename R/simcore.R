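# Synthetic single-plane time-lapse movies of emitters confined to a
# stereocilium axis, with full ground truth for parameter-recovery tests.

#' Simulation configuration
#'
#' Describes the virtual microscope and camera. Defaults emulate light-sheet
#' single-plane time-lapse imaging of stereocilia: 100 ms exposures at 0.1-1 s
#' frame intervals, an sCMOS-class camera behind a 40x objective
#' (162.5 nm pixels) and a Gaussian PSF of width sigma ~ 152 nm
#' (0.21 * lambda / NA at lambda = 580 nm, NA = 0.8).
#'
#' @param image_shape frame size in pixels, `c(rows, cols)`.
#' @param pixel_size pixel size, nm/pixel.
#' @param frame_interval time between frames, s.
#' @param n_frames number of frames (>= 1).
#' @param exposure exposure time per frame, s (<= frame_interval).
#' @param psf_sigma Gaussian PSF width, nm.
#' @param quantal_yield expected photons per fluorophore per frame.
#' @param background_rate background photons per pixel per frame.
#' @param read_noise_sd camera read noise, counts (Gaussian SD).
#' @param camera_gain counts per photon.
#' @param camera_offset camera baseline, counts.
#' @param drift a [drift_model()].
#' @param seed master random seed; all substreams derive from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(image_shape = c(64, 64), pixel_size = 162.5,
                       frame_interval = 1, n_frames = 50, exposure = 0.1,
                       psf_sigma = 152, quantal_yield = 400,
                       background_rate = 10, read_noise_sd = 2,
                       camera_gain = 1, camera_offset = 100,
                       drift = drift_model(), seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (exposure > frame_interval)
    stop("exposure must not exceed frame_interval")
  for (nm in c("quantal_yield", "background_rate", "read_noise_sd",
               "camera_gain")) {
    if (get(nm) < 0) stop(nm, " must be >= 0")
  }
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), exposure = exposure,
                 psf_sigma = psf_sigma, quantal_yield = quantal_yield,
                 background_rate = background_rate,
                 read_noise_sd = read_noise_sd, camera_gain = camera_gain,
                 camera_offset = camera_offset, drift = drift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Stereocilium geometry: a straight confinement axis in the image plane
#'
#' @param base_point,tip_point axis end points in nm, `c(x, y)`. The axial
#'   coordinate runs from 0 at the base to the axis length at the tip.
#' @param radius lateral confinement half-width, nm; 0 places emitters
#'   exactly on the axis.
#' @export
stereocilium_geometry <- function(base_point, tip_point, radius = 0) {
  base_point <- as.numeric(base_point); tip_point <- as.numeric(tip_point)
  len <- sqrt(sum((tip_point - base_point)^2))
  if (len <= 0) stop("base_point and tip_point must differ")
  if (radius < 0) stop("radius must be >= 0")
  u <- (tip_point - base_point) / len
  structure(list(base_point = base_point, tip_point = tip_point,
                 radius = radius, length = len, axis_unit = u,
                 normal_unit = c(-u[2], u[1])),
            class = "stereocilium_geometry")
}

#' Motility model for one emitter
#'
#' @param mode one of `"static"`, `"diffusive"`, `"processive"`,
#'   `"stepwise"`, `"intermittent"`.
#' @param speed tip-ward speed v, nm/s (processive, intermittent).
#' @param diffusion_coeff diffusion coefficient D, nm^2/s (diffusive).
#' @param step_size jump size, nm (stepwise).
#' @param step_rate step events per second (stepwise).
#' @param duty_on,duty_off switching rates (1/s) out of the paused and
#'   moving phases, respectively (intermittent).
#' @export
motility_model <- function(mode = c("static", "diffusive", "processive",
                                    "stepwise", "intermittent"),
                           speed = 100, diffusion_coeff = 1e4,
                           step_size = 150, step_rate = 0.15,
                           duty_on = 0.5, duty_off = 0.5) {
  mode <- match.arg(mode)
  need_pos <- switch(mode,
    diffusive = c(diffusion_coeff = diffusion_coeff),
    processive = c(speed = speed),
    stepwise = c(step_size = step_size, step_rate = step_rate),
    intermittent = c(speed = speed, duty_on = duty_on, duty_off = duty_off),
    NULL)
  if (length(need_pos) && any(need_pos <= 0))
    stop("mode-relevant parameters must be > 0: ",
         paste(names(need_pos)[need_pos <= 0], collapse = ", "))
  structure(list(mode = mode, speed = speed,
                 diffusion_coeff = diffusion_coeff, step_size = step_size,
                 step_rate = step_rate, duty_on = duty_on,
                 duty_off = duty_off),
            class = "motility_model")
}

#' Photophysics model for one emitter
#'
#' @param n_fluorophores fluorophores per emitter (1 or 2 typical).
#' @param bleach_rate per-fluorophore photobleaching rate, 1/s (absorbing).
#' @param dark_on_rate,dark_off_rate blinking rates, 1/s (bright -> dark and
#'   dark -> bright); 0 disables blinking.
#' @export
photophysics_model <- function(n_fluorophores = 1, bleach_rate = 0,
                               dark_on_rate = 0, dark_off_rate = 0) {
  if (n_fluorophores < 1) stop("n_fluorophores must be >= 1")
  if (bleach_rate < 0 || dark_on_rate < 0 || dark_off_rate < 0)
    stop("photophysics rates must be >= 0")
  structure(list(n_fluorophores = as.integer(n_fluorophores),
                 bleach_rate = bleach_rate, dark_on_rate = dark_on_rate,
                 dark_off_rate = dark_off_rate),
            class = "photophysics_model")
}

#' Stage drift model
#'
#' @param velocity linear drift `c(vx, vy)`, nm/s.
#' @param random_walk_sd per-frame random-walk step SD, nm.
#' @export
drift_model <- function(velocity = c(0, 0), random_walk_sd = 0) {
  if (random_walk_sd < 0) stop("random_walk_sd must be >= 0")
  structure(list(velocity = as.numeric(velocity),
                 random_walk_sd = random_walk_sd),
            class = "drift_model")
}

#' Emitter specification for the simulator
#'
#' @param motility a [motility_model()].
#' @param photophysics a [photophysics_model()].
#' @param start axial start position, nm from the base.
#' @export
emitter <- function(motility, photophysics = photophysics_model(),
                    start = 0) {
  structure(list(motility = motility, photophysics = photophysics,
                 start = start),
            class = "emitter")
}

#' Sample an axial trajectory for one motility mode
#'
#' Positions are confined to \[0, axis length\]: diffusive paths are
#' reflected at both ends; directed modes are absorbed at the tip
#' (accumulation at the tip).
#'
#' @param model a [motility_model()].
#' @param geometry a [stereocilium_geometry()].
#' @param start start position, nm from the base, within \[0, length\].
#' @param n_frames number of time points.
#' @param frame_interval time step, s.
#' @param seed optional seed; `NULL` uses (and advances) the current RNG.
#' @return numeric vector of axial positions in nm, one per frame.
#' @export
sample_trajectory <- function(model, geometry, start, n_frames,
                              frame_interval, seed = NULL) {
  L <- geometry$length
  if (start < 0 || start > L)
    stop(sprintf("start position %.1f nm outside axis [0, %.1f]", start, L))
  t <- (seq_len(n_frames) - 1) * frame_interval
  with_seed(seed, switch(model$mode,
    static = rep(start, n_frames),
    processive = pmin(start + model$speed * t, L),
    diffusive = {
      inc <- c(0, stats::rnorm(n_frames - 1,
                               sd = sqrt(2 * model$diffusion_coeff *
                                           frame_interval)))
      s <- start + cumsum(inc)
      p <- s %% (2 * L)                      # reflect into [0, L]
      ifelse(p > L, 2 * L - p, p)
    },
    stepwise = {
      T_end <- t[n_frames]
      ev <- numeric(0); tt <- 0
      repeat {
        tt <- tt + stats::rexp(1, model$step_rate)
        if (tt > T_end) break
        ev <- c(ev, tt)
      }
      counts <- vapply(t, function(x) sum(ev <= x), numeric(1))
      pmin(start + model$step_size * counts, L)
    },
    intermittent = {
      # alternating paused/moving phases; moving advances at `speed`
      T_end <- t[n_frames]
      sw <- numeric(0); tt <- 0; moving <- FALSE
      states <- logical(0)
      repeat {
        rate <- if (moving) model$duty_off else model$duty_on
        tt <- tt + stats::rexp(1, rate)
        if (tt > T_end) break
        sw <- c(sw, tt); moving <- !moving
        states <- c(states, moving)
      }
      moving_time <- function(x) {
        # total time spent moving in [0, x]; starts paused
        edges <- c(0, sw[sw <= x], x)
        phase_moving <- (seq_len(length(edges) - 1) %% 2) == 0
        sum(diff(edges)[phase_moving])
      }
      mt <- vapply(t, moving_time, numeric(1))
      pmin(start + model$speed * mt, L)
    },
    stop("unknown motility mode: ", model$mode)))
}

# Per-fluorophore emission schedule: bleach time (absorbing) plus optional
# bright/dark blinking. Returns a n_frames x n_fluorophores logical matrix.
sample_photophysics <- function(photo, n_frames, frame_interval,
                                seed = NULL) {
  t <- (seq_len(n_frames) - 1) * frame_interval
  with_seed(seed, {
    vis <- matrix(FALSE, n_frames, photo$n_fluorophores)
    bleach_t <- numeric(photo$n_fluorophores)
    for (j in seq_len(photo$n_fluorophores)) {
      tb <- if (photo$bleach_rate > 0)
        stats::rexp(1, photo$bleach_rate) else Inf
      bleach_t[j] <- tb
      bright <- rep(TRUE, n_frames)
      if (photo$dark_on_rate > 0 && photo$dark_off_rate > 0) {
        T_end <- t[n_frames]
        tt <- 0; state <- TRUE
        state_at <- rep(TRUE, n_frames)
        repeat {
          rate <- if (state) photo$dark_on_rate else photo$dark_off_rate
          tt <- tt + stats::rexp(1, rate)
          if (tt > T_end) break
          state <- !state
          state_at[t >= tt] <- state
        }
        bright <- state_at
      }
      vis[, j] <- bright & (t < tb)
    }
    attr(vis, "bleach_time") <- bleach_t
    vis
  })
}

#' Simulate a single-plane time-lapse movie with ground truth
#'
#' Renders each emitter's fluorophores as pixel-integrated Gaussian PSF spots
#' at their drifted positions, then applies the camera model
#' `counts = offset + gain * Poisson(signal + background) + N(0, read_noise)`.
#' Motion, blinking and bleaching are updated once per frame (no
#' intra-exposure blur). One master seed drives deterministic per-emitter
#' substreams, so the same configuration reproduces the movie bit for bit.
#'
#' @param config a [sim_config()].
#' @param geometry a [stereocilium_geometry()].
#' @param emitters list of [emitter()] objects.
#' @return list with elements `movie` (a [Movie()]) and `truth`
#'   (a `GroundTruth` list: per-emitter true positions, per-fluorophore
#'   visibility and bleach frames, and per-frame cumulative drift in nm).
#' @export
simulate_movie <- function(config, geometry, emitters = list()) {
  stopifnot(inherits(config, "sim_config"),
            inherits(geometry, "stereocilium_geometry"))
  nf <- config$n_frames
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  t <- (seq_len(nf) - 1) * config$frame_interval
  ne <- length(emitters)
  seeds <- derive_stream_seeds(config$seed, 2 + 3 * max(ne, 1))
  drift_seed <- seeds[1]; camera_seed <- seeds[2]

  # cumulative stage drift, nm, relative to the first frame
  drift_nm <- with_seed(drift_seed, {
    rw <- if (config$drift$random_walk_sd > 0)
      apply(matrix(stats::rnorm(2 * (nf - 1),
                                sd = config$drift$random_walk_sd),
                   ncol = 2), 2, cumsum)
    else matrix(0, max(nf - 1, 0), 2)
    rbind(c(0, 0), rw) + outer(t, config$drift$velocity)
  })

  truth_emitters <- vector("list", ne)
  signal <- array(0, dim = c(ny, nx, nf))
  for (i in seq_len(ne)) {
    em <- emitters[[i]]
    if (em$start < 0 || em$start > geometry$length)
      stop(sprintf("emitter %d start (%.1f nm) outside geometry [0, %.1f nm]",
                   i, em$start, geometry$length))
    s_nm <- sample_trajectory(em$motility, geometry, em$start, nf,
                              config$frame_interval, seed = seeds[3 * i])
    lat <- if (geometry$radius > 0)
      with_seed(seeds[3 * i + 1],
                stats::runif(nf, -geometry$radius, geometry$radius))
    else rep(0, nf)
    vis <- sample_photophysics(em$photophysics, nf, config$frame_interval,
                               seed = seeds[3 * i + 2])
    bleach_time <- attr(vis, "bleach_time")
    bleach_frame <- vapply(bleach_time, function(tb) {
      k <- which(t >= tb)
      if (length(k)) k[1] else NA_integer_
    }, integer(1))
    pos_nm <- matrix(geometry$base_point, nf, 2, byrow = TRUE) +
      s_nm %o% geometry$axis_unit + lat %o% geometry$normal_unit
    img_nm <- pos_nm + drift_nm
    x_px <- img_nm[, 1] / config$pixel_size
    y_px <- img_nm[, 2] / config$pixel_size
    n_vis <- rowSums(vis)
    sigma_px <- config$psf_sigma / config$pixel_size
    for (f in seq_len(nf)) {
      if (n_vis[f] > 0)
        signal[, , f] <- render_gaussian_spot(
          signal[, , f], x_px[f], y_px[f], sigma_px,
          config$quantal_yield * n_vis[f])
    }
    truth_emitters[[i]] <- list(
      mode = em$motility$mode, motility = em$motility,
      photophysics = em$photophysics, start_nm = em$start,
      axial_nm = s_nm, x_px = x_px, y_px = y_px,
      visible = vis[, , drop = FALSE], visible_count = n_vis,
      visible_any = n_vis > 0, bleach_frame = bleach_frame)
  }

  frames <- with_seed(camera_seed, {
    out <- array(0, dim = c(ny, nx, nf))
    for (f in seq_len(nf)) {
      lambda <- signal[, , f] + config$background_rate
      photons <- matrix(stats::rpois(ny * nx, lambda), ny, nx)
      out[, , f] <- config$camera_offset + config$camera_gain * photons +
        if (config$read_noise_sd > 0)
          matrix(stats::rnorm(ny * nx, sd = config$read_noise_sd), ny, nx)
        else 0
    }
    out
  })

  truth <- structure(list(emitters = truth_emitters, drift_nm = drift_nm,
                          times_s = t, geometry = geometry, config = config),
                     class = "GroundTruth")
  list(movie = Movie(frames, config$pixel_size, config$frame_interval),
       truth = truth)
}

#' Synthetic track benchmark for motility classification
#'
#' Generates labelled axial trajectories with localization noise for the
#' four behavioural modes seen on kymographs of motors in stereocilia:
#' static molecules, freely diffusing molecules, processive movers, and
#' step-wise movers. Default kinetic parameters follow the motility
#' regimes the imaging distinguishes: processive speed 100 nm/s, steps of
#' 100-200 nm at 0.15 events/s, diffusion 2e4 nm^2/s, with 30 nm
#' localization noise at 1 s frame intervals.
#'
#' @param n_per_mode tracks per mode.
#' @param n_frames frames per track.
#' @param frame_interval s.
#' @param sigma_loc localization noise SD, nm.
#' @param speed,diffusion_coeff,step_rate,step_range generator kinetics.
#' @param seed master seed.
#' @return list with `tracks` (data.frame: track_id, mode, t_s, s_nm) and
#'   `modes` (true mode per track_id).
#' @export
benchmark_tracks <- function(n_per_mode = 100, n_frames = 100,
                             frame_interval = 1, sigma_loc = 30,
                             speed = 100, diffusion_coeff = 2e4,
                             step_rate = 0.15, step_range = c(100, 200),
                             seed = 1) {
  modes <- c("static", "diffusive", "processive", "stepwise")
  geo <- stereocilium_geometry(c(0, 0), c(1e6, 0))  # effectively unbounded
  seeds <- derive_stream_seeds(seed, 4 * n_per_mode + 1)
  t_s <- (seq_len(n_frames) - 1) * frame_interval
  rows <- list(); true_mode <- character(0)
  id <- 0L
  for (m in modes) {
    for (k in seq_len(n_per_mode)) {
      id <- id + 1L
      sd_i <- seeds[id]
      s <- with_seed(sd_i, {
        mdl <- switch(m,
          static = motility_model("static"),
          diffusive = motility_model("diffusive",
                                     diffusion_coeff = diffusion_coeff),
          processive = motility_model("processive", speed = speed),
          stepwise = motility_model("stepwise",
                                    step_size = stats::runif(1,
                                      step_range[1], step_range[2]),
                                    step_rate = step_rate))
        sample_trajectory(mdl, geo, 5e5, n_frames, frame_interval) +
          stats::rnorm(n_frames, sd = sigma_loc)
      })
      rows[[id]] <- data.frame(track_id = id, mode = m, t_s = t_s,
                               s_nm = s)
      true_mode <- c(true_mode, m)
    }
  }
  list(tracks = do.call(rbind, rows), modes = true_mode)
}

#' Write simulator ground truth to disk
#'
#' Writes a JSON file of per-emitter records (mode, parameters, bleach
#' frames) and a CSV of per-frame true positions and visibility.
#'
#' @param truth a `GroundTruth` from [simulate_movie()].
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @export
write_ground_truth <- function(truth, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    recs <- lapply(seq_along(truth$emitters), function(i) {
      e <- truth$emitters[[i]]
      list(emitter = i, mode = e$mode,
           n_fluorophores = e$photophysics$n_fluorophores,
           start_nm = e$start_nm,
           bleach_frame = as.list(e$bleach_frame))
    })
    jsonlite::write_json(list(n_frames = length(truth$times_s),
                              drift_nm = truth$drift_nm, emitters = recs),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(seq_along(truth$emitters), function(i) {
      e <- truth$emitters[[i]]
      data.frame(emitter = i, frame = seq_along(truth$times_s),
                 t_s = truth$times_s, s_nm = e$axial_nm,
                 x_px = e$x_px, y_px = e$y_px,
                 n_visible = e$visible_count)
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(truth)
}

#' Read / write a simulation configuration as YAML
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$drift <- unclass(x$drift)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  dr <- do.call(drift_model, x$drift %||% list())
  x$drift <- NULL
  do.call(sim_config, c(x, list(drift = dr)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
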