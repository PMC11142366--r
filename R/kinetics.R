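# Trajectory kinetics: velocities, change-point step detection, MSD
# analysis, motility-mode classification and photobleaching survival.

#' Velocity of a track by least-squares slope
#'
#' Ordinary least-squares slope of axial position against time over the
#' whole track; by the axial convention, tip-ward velocities are positive.
#'
#' @param t_s time points, s.
#' @param s_nm axial positions, nm.
#' @param min_frames minimum number of points (default 4).
#' @return list with `v` (nm/s), `se` (slope standard error), `r2`,
#'   `duration` (s) and `n`. A constant series returns `v = 0` with
#'   `r2 = NA`.
#' @export
velocity_of_track <- function(t_s, s_nm, min_frames = 4) {
  stopifnot(length(t_s) == length(s_nm))
  n <- length(t_s)
  if (n < min_frames)
    stop("insufficient data: need >= ", min_frames, " points, got ", n)
  # closed-form OLS (avoids summary.lm noise on perfect fits)
  tm <- t_s - mean(t_s); sm <- s_nm - mean(s_nm)
  stt <- sum(tm^2)
  v <- sum(tm * sm) / stt
  ss_tot <- sum(sm^2)
  rss <- ss_tot - v^2 * stt
  r2 <- if (ss_tot > 0) 1 - rss / ss_tot else NA_real_
  if (ss_tot == 0) v <- 0
  se <- if (n > 2) sqrt(max(rss, 0) / (n - 2) / stt) else NA_real_
  list(v = v, se = se, r2 = r2, duration = max(t_s) - min(t_s), n = n)
}

#' Summarize per-track velocities
#'
#' Applies directed-run filters (minimum duration, minimum linear-fit R
#' squared, direction) and reports the sample mean, standard deviation and
#' a histogram of the surviving velocities.
#'
#' @param estimates data.frame with columns `v`, `r2`, `duration` (e.g. one
#'   row per [velocity_of_track()] result).
#' @param min_duration minimum track duration, s.
#' @param min_r2 minimum linear-fit R squared (0 disables).
#' @param direction `"any"`, `"tip"` (v > 0) or `"base"` (v < 0).
#' @param bin_width histogram bin width, nm/s (`NULL` for automatic).
#' @return list with `mean`, `sd` (`NA` when n = 1), `n`, `histogram`
#'   (from [graphics::hist()], not plotted) and the filtered `velocities`.
#'   When no estimate survives the filters, an empty summary with `n = 0`.
#' @export
summarize_velocities <- function(estimates, min_duration = 0, min_r2 = 0,
                                 direction = c("any", "tip", "base"),
                                 bin_width = NULL) {
  direction <- match.arg(direction)
  est <- as.data.frame(estimates)
  keep <- est$duration >= min_duration &
    (min_r2 <= 0 | (!is.na(est$r2) & est$r2 >= min_r2))
  keep <- keep & switch(direction, any = TRUE, tip = est$v > 0,
                        base = est$v < 0)
  v <- est$v[keep & !is.na(keep)]
  if (length(v) == 0)
    return(list(mean = NA_real_, sd = NA_real_, n = 0L, histogram = NULL,
                velocities = numeric(0)))
  breaks <- if (is.null(bin_width)) "Sturges" else
    seq(floor(min(v) / bin_width) * bin_width,
        ceiling(max(v) / bin_width) * bin_width + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       n = length(v), histogram = h, velocities = v)
}

# residual sum of squares of a constant fit on x[i..j]
.rss_const <- function(csum, csum2, i, j) {
  n <- j - i + 1
  s <- csum[j + 1] - csum[i]
  s2 <- csum2[j + 1] - csum2[i]
  max(s2 - s^2 / n, 0)
}

#' Detect steps in an axial trajectory
#'
#' Fits a piecewise-constant model by binary segmentation: candidate change
#' points are added greedily at the split giving the largest reduction in
#' residual sum of squares, and accepted while the reduction exceeds
#' `penalty * log(n) * sigma^2` (a modified-BIC stopping rule). Steps
#' smaller than `min_size` are then merged away, smallest first.
#'
#' @param t_s time points, s (only used for dwell times; may be `NULL`).
#' @param s_nm axial positions, nm (>= 6 points).
#' @param noise_scale localization noise SD, nm; estimated from the median
#'   absolute successive difference when `NULL`.
#' @param penalty per-change-point penalty multiplier on `log(n) * sigma^2`.
#' @param min_size minimum retained step size, nm (default `2 *
#'   noise_scale`).
#' @param min_seg minimum plateau length, points.
#' @return object of class `step_fit`: list with `changepoints` (indices of
#'   the last point of each plateau except the final one), `levels`
#'   (plateau means, nm), `steps` (signed step sizes, nm), `dwell_frames`,
#'   `dwell_s`, `sigma`, `penalty`, `n`.
#' @export
detect_steps <- function(t_s, s_nm, noise_scale = NULL, penalty = 3,
                         min_size = NULL, min_seg = 2) {
  x <- as.numeric(s_nm)
  n <- length(x)
  if (n < 6) stop("series too short for step detection (need >= 6 points)")
  if (is.null(t_s)) t_s <- seq_len(n) - 1
  sigma <- if (is.null(noise_scale))
    stats::mad(diff(x)) / sqrt(2) else noise_scale
  if (is.null(min_size)) min_size <- 2 * sigma
  thresh <- max(penalty * log(n) * sigma^2,
                .Machine$double.eps * sum(x^2) * n)
  csum <- c(0, cumsum(x)); csum2 <- c(0, cumsum(x^2))
  best_split <- function(i, j) {
    # best single change point within [i, j]; returns c(k, gain)
    if (j - i + 1 < 2 * min_seg) return(c(NA, 0))
    ks <- (i + min_seg - 1):(j - min_seg)
    if (length(ks) == 0) return(c(NA, 0))
    base <- .rss_const(csum, csum2, i, j)
    gains <- vapply(ks, function(k)
      base - .rss_const(csum, csum2, i, k) -
        .rss_const(csum, csum2, k + 1, j), numeric(1))
    kbest <- ks[which.max(gains)]
    c(kbest, max(gains))
  }
  cps <- integer(0)
  repeat {
    bounds <- c(0, sort(cps), n)
    cand <- matrix(NA_real_, 0, 2)
    for (b in seq_len(length(bounds) - 1)) {
      sp <- best_split(bounds[b] + 1, bounds[b + 1])
      if (!is.na(sp[1])) cand <- rbind(cand, sp)
    }
    if (nrow(cand) == 0) break
    top <- cand[which.max(cand[, 2]), ]
    if (top[2] <= thresh) break
    cps <- c(cps, as.integer(top[1]))
  }
  cps <- sort(cps)
  seg_means <- function(cps) {
    bounds <- c(0, cps, n)
    vapply(seq_len(length(bounds) - 1), function(b)
      mean(x[(bounds[b] + 1):bounds[b + 1]]), numeric(1))
  }
  # merge steps below the minimum size, smallest first
  repeat {
    if (length(cps) == 0) break
    lv <- seg_means(cps)
    st <- diff(lv)
    small <- which(abs(st) < min_size)
    if (length(small) == 0) break
    drop <- small[which.min(abs(st[small]))]
    cps <- cps[-drop]
  }
  lv <- seg_means(cps)
  bounds <- c(0, cps, n)
  dwell <- diff(bounds)
  structure(list(changepoints = cps, levels = lv, steps = diff(lv),
                 dwell_frames = dwell,
                 dwell_s = dwell * (if (n > 1) diff(t_s[1:2]) else 1),
                 sigma = sigma, penalty = penalty, n = n),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit: %d change point(s) over %d points; sigma %.1f nm\n",
              length(x$changepoints), x$n, x$sigma))
  if (length(x$steps))
    cat("  steps (nm):", paste(sprintf("%.0f", x$steps), collapse = ", "),
        "\n")
  invisible(x)
}

#' Time-averaged mean-squared displacement of a track
#'
#' MSD over lags up to a quarter of the track length; the anomalous
#' exponent alpha from a log-log fit restricted to the shortest decade of
#' lags (longer lags of a time-averaged single-track MSD are strongly
#' correlated and variance-dominated); and, from a linear fit
#' `MSD = 2 D lag + offset` over the first lags (one-dimensional axial
#' motion; the offset absorbs localization noise), the diffusion
#' coefficient.
#'
#' @param t_s time points, s (uniformly spaced).
#' @param s_nm axial positions, nm (>= 8 points).
#' @return list with `lag_s`, `msd` (nm^2), `alpha`, `D` (nm^2/s), `n`.
#' @export
msd_curve <- function(t_s, s_nm) {
  n <- length(s_nm)
  if (n < 8) stop("track too short for MSD analysis (need >= 8 points)")
  dt <- diff(t_s[1:2])
  lags <- seq_len(max(floor(n / 4), 2))
  msd <- vapply(lags, function(L)
    mean((s_nm[(1 + L):n] - s_nm[1:(n - L)])^2), numeric(1))
  lag_s <- lags * dt
  ka <- seq_len(min(max(4, floor(n / 10)), length(lags)))
  pos <- which(msd[ka] > 0)
  alpha <- if (length(pos) >= 2)
    unname(stats::coef(stats::lm(log(msd[ka][pos]) ~
                                   log(lag_s[ka][pos])))[2])
  else NA_real_
  # D from the first few lags only; long lags are variance-dominated
  kd <- seq_len(min(4, length(lags)))
  D <- if (length(kd) >= 2)
    unname(stats::coef(stats::lm(msd[kd] ~ lag_s[kd]))[2]) / 2
  else msd[1] / (2 * lag_s[1])
  list(lag_s = lag_s, msd = msd, alpha = alpha, D = D, n = n)
}

#' Classify the motility mode of a track
#'
#' Deterministic decision rules on an axial trajectory:
#' \enumerate{
#'   \item `static` - net displacement < `k_static * sigma_loc` and total
#'     excursion < `(k_static + 4) * sigma_loc` (the wider excursion
#'     factor covers the expected extremes of pure localization noise on
#'     long tracks);
#'   \item `stepwise` - the piecewise-constant step fit finds >= 2 steps
#'     with plateau dwells >= `dwell_min` frames, beats the straight-line
#'     fit by BIC, and leaves within-plateau residuals consistent with
#'     localization noise (RMS <= `2 * sigma_loc`; a diffusing molecule
#'     wanders within its plateaus and fails this);
#'   \item `processive` - linear fit with `r2 >= r2_min`, `|v| >= v_min`
#'     and a ballistic MSD exponent (`alpha >= alpha_ballistic`);
#'   \item `diffusive` - MSD exponent within `alpha_band`;
#'   \item otherwise `unclassified`.
#' }
#'
#' @param t_s,s_nm the track (time s, axial position nm).
#' @param sigma_loc localization noise SD, nm.
#' @param min_frames minimum track length for classification.
#' @param v_min minimum processive speed, nm/s.
#' @param r2_min minimum linear-fit R squared for a processive call.
#' @param dwell_min minimum plateau dwell, frames.
#' @param k_static net-displacement threshold multiplier for static calls.
#' @param alpha_band MSD-exponent range called diffusive.
#' @param alpha_ballistic minimum MSD exponent for a processive call.
#' @return object of class `motility_call`: list with `mode` and the
#'   supporting statistics (`v`, `r2`, `alpha`, `n_steps`, `reason`).
#' @export
classify_motility <- function(t_s, s_nm, sigma_loc = 30, min_frames = 8,
                              v_min = 20, r2_min = 0.8, dwell_min = 2,
                              k_static = 3, alpha_band = c(0.7, 1.3),
                              alpha_ballistic = 1.5) {
  n <- length(s_nm)
  call <- function(mode, reason = "", v = NA, r2 = NA, alpha = NA,
                   n_steps = NA)
    structure(list(mode = mode, v = v, r2 = r2, alpha = alpha,
                   n_steps = n_steps, n = n, reason = reason),
              class = "motility_call")
  if (n < min_frames)
    return(call("unclassified", reason = "track too short"))
  net <- abs(s_nm[n] - s_nm[1])
  excur <- diff(range(s_nm))
  if (net < k_static * sigma_loc && excur < (k_static + 4) * sigma_loc)
    return(call("static", v = 0))
  ve <- velocity_of_track(t_s, s_nm, min_frames = min(4, n))
  sf <- detect_steps(t_s, s_nm, noise_scale = sigma_loc)
  msd <- msd_curve(t_s, s_nm)
  # does a staircase beat a straight line, at matched BIC accounting?
  rss_lin <- sum(stats::resid(stats::lm(s_nm ~ t_s))^2)
  bounds <- c(0, sf$changepoints, n)
  rss_step <- sum(vapply(seq_len(length(bounds) - 1), function(b) {
    seg <- s_nm[(bounds[b] + 1):bounds[b + 1]]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
  bic_lin <- n * log(max(rss_lin, 1e-12) / n) + 2 * log(n)
  bic_step <- n * log(max(rss_step, 1e-12) / n) +
    (2 * length(sf$changepoints) + 1) * log(n)
  plateau_rms <- sqrt(rss_step / n)
  if (length(sf$steps) >= 2 && min(sf$dwell_frames) >= dwell_min &&
      bic_step < bic_lin && plateau_rms <= 2 * sigma_loc)
    return(call("stepwise", v = ve$v, r2 = ve$r2, alpha = msd$alpha,
                n_steps = length(sf$steps)))
  if (!is.na(ve$r2) && ve$r2 >= r2_min && abs(ve$v) >= v_min &&
      !is.na(msd$alpha) && msd$alpha >= alpha_ballistic)
    return(call("processive", v = ve$v, r2 = ve$r2, alpha = msd$alpha,
                n_steps = length(sf$steps)))
  if (!is.na(msd$alpha) && msd$alpha >= alpha_band[1] &&
      msd$alpha <= alpha_band[2])
    return(call("diffusive", v = ve$v, r2 = ve$r2, alpha = msd$alpha,
                n_steps = length(sf$steps)))
  call("unclassified", reason = "no rule matched", v = ve$v, r2 = ve$r2,
       alpha = msd$alpha, n_steps = length(sf$steps))
}

#' @export
print.motility_call <- function(x, ...) {
  cat(sprintf("Motility call: %s (v = %.1f nm/s, R2 = %.2f, alpha = %.2f)\n",
              x$mode, ifelse(is.na(x$v), 0, x$v),
              ifelse(is.na(x$r2), NA, x$r2),
              ifelse(is.na(x$alpha), NA, x$alpha)))
  invisible(x)
}

#' Photobleaching survival: censored exponential fit of track lifetimes
#'
#' Maximum-likelihood exponential rate for right-censored lifetimes
#' (`rate = events / total observed time`), with the empirical survival
#' curve.
#'
#' @param durations observed track durations, s.
#' @param censored logical; TRUE when the track was still alive at the end
#'   of the movie (right-censored).
#' @param min_tracks minimum number of tracks required.
#' @return list with `rate` (1/s), `mean_lifetime` (s), `n`, `n_events`,
#'   `survival` (data.frame `t`, `S` of the Kaplan-Meier-style empirical
#'   survival over uncensored spans).
#' @export
bleaching_survival <- function(durations, censored = NULL,
                               min_tracks = 10) {
  d <- as.numeric(durations)
  if (is.null(censored)) censored <- rep(FALSE, length(d))
  stopifnot(length(censored) == length(d))
  if (length(d) < min_tracks)
    stop("need >= ", min_tracks, " completed tracks, got ", length(d))
  n_events <- sum(!censored)
  if (n_events == 0) stop("all tracks censored: no events to fit")
  if (any(d < 0)) stop("durations must be >= 0")
  rate <- n_events / sum(d)
  ts <- sort(unique(d[!censored]))
  # empirical survival with censoring (product-limit estimator)
  at_risk <- vapply(ts, function(x) sum(d >= x), numeric(1))
  ev <- vapply(ts, function(x) sum(d == x & !censored), numeric(1))
  S <- cumprod(1 - ev / at_risk)
  list(rate = rate, mean_lifetime = 1 / rate, n = length(d),
       n_events = n_events, survival = data.frame(t = ts, S = S))
}

#' Per-track kinetics table
#'
#' Runs velocity estimation, step detection, MSD analysis and motility
#' classification for every track and assembles the per-track table used
#' by the pipeline export.
#'
#' @param tracks projected tracks (columns `track_id`, `t_s`, `s_nm`).
#' @param sigma_loc localization noise SD, nm.
#' @param min_frames minimum track length for the full analysis; shorter
#'   tracks appear with mode `"unclassified"`.
#' @param ... further arguments passed to [classify_motility()].
#' @return data.frame: track_id, mode, v, se, r2, alpha, n_steps,
#'   mean_step_nm, duration_s, n.
#' @export
track_kinetics <- function(tracks, sigma_loc = 30, min_frames = 8, ...) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tt <- tracks$t_s[tracks$track_id == id]
    ss <- tracks$s_nm[tracks$track_id == id]
    n <- length(ss)
    if (n < min_frames)
      return(data.frame(track_id = id, mode = "unclassified", v = NA,
                        se = NA, r2 = NA, alpha = NA, n_steps = NA,
                        mean_step_nm = NA,
                        duration_s = if (n > 1) max(tt) - min(tt) else 0,
                        n = n))
    ve <- velocity_of_track(tt, ss, min_frames = min(4, n))
    mc <- classify_motility(tt, ss, sigma_loc = sigma_loc,
                            min_frames = min_frames, ...)
    sf <- detect_steps(tt, ss, noise_scale = sigma_loc)
    data.frame(track_id = id, mode = mc$mode, v = ve$v, se = ve$se,
               r2 = ve$r2, alpha = mc$alpha,
               n_steps = length(sf$steps),
               mean_step_nm = if (length(sf$steps))
                 mean(abs(sf$steps)) else NA,
               duration_s = ve$duration, n = n)
  })
  do.call(rbind, rows)
}
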