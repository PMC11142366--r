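# Punctum detection, background-subtracted summed intensities, quantal
# (fluorophore-count) population classification, and PSF profile comparison.

#' Detect diffraction-limited puncta in one frame
#'
#' Band-passes the frame with a difference of Gaussians at the PSF scale,
#' finds local maxima above a robust threshold, merges detections closer
#' than `min_separation` (keeping the brighter), and refines each position
#' to subpixel precision by intensity-weighted centroid.
#'
#' @param frame numeric matrix.
#' @param psf_sigma_px PSF width in pixels (sets the band-pass scale).
#' @param min_separation minimum distance between detections, pixels.
#' @param threshold_sd detection threshold in robust SDs of the band-passed
#'   background (median + threshold_sd * MAD).
#' @param centroid_radius half-size of the centroid window, pixels.
#' @return data.frame with columns `x`, `y` (0-based subpixel pixel
#'   coordinates), `quality` (band-passed peak height) and `edge` flag;
#'   zero rows when nothing is found.
#' @export
detect_puncta <- function(frame, psf_sigma_px = 1, min_separation = 3,
                          threshold_sd = 5,
                          centroid_radius = max(2L, ceiling(2 * psf_sigma_px))) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  ny <- nrow(frame); nx <- ncol(frame)
  dog <- EBImage::gblur(frame, sigma = psf_sigma_px) -
    EBImage::gblur(frame, sigma = 2 * psf_sigma_px)
  # robust noise scale with a numerical floor for noise-free frames
  scale <- max(stats::mad(dog), 1e-9 * max(abs(dog)), .Machine$double.eps)
  thr <- stats::median(dog) + threshold_sd * scale
  # 3x3 local maxima strictly above all neighbours (ties broken by order)
  cand <- which(dog > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1]; c <- cand[k, 2]
    rr <- max(1, r - 1):min(ny, r + 1)
    cc <- max(1, c - 1):min(nx, c + 1)
    keep[k] <- dog[r, c] == max(dog[rr, cc])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), quality = numeric(0),
                      edge = logical(0)))
  q <- dog[cand]
  ord <- order(q, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; q <- q[ord]
  # merge near-duplicates, keeping the brighter
  taken <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!taken[k]) next
    if (k < nrow(cand)) {
      d2 <- (cand[(k + 1):nrow(cand), 1] - cand[k, 1])^2 +
        (cand[(k + 1):nrow(cand), 2] - cand[k, 2])^2
      taken[(k + 1):nrow(cand)][d2 < min_separation^2] <- FALSE
    }
  }
  cand <- cand[taken, , drop = FALSE]; q <- q[taken]
  # subpixel refinement: background-subtracted intensity-weighted centroid
  w <- centroid_radius
  xs <- numeric(nrow(cand)); ys <- numeric(nrow(cand))
  edge <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1]; c <- cand[k, 2]
    rr <- max(1, r - w):min(ny, r + w)
    cc <- max(1, c - w):min(nx, c + w)
    edge[k] <- length(rr) < 2 * w + 1 || length(cc) < 2 * w + 1
    patch <- frame[rr, cc, drop = FALSE] - stats::median(frame[rr, cc])
    patch[patch < 0] <- 0
    tot <- sum(patch)
    if (tot <= 0) { xs[k] <- c - 1; ys[k] <- r - 1; next }
    ys[k] <- sum(patch * (rr - 1)) / tot
    xs[k] <- sum(t(patch) * (cc - 1)) / tot
  }
  data.frame(x = xs, y = ys, quality = q, edge = edge)
}

#' Detect puncta in every frame of a movie
#'
#' @param movie a [Movie()].
#' @inheritParams detect_puncta
#' @return data.frame of detections with a `frame` column (1-based).
#' @export
detect_movie <- function(movie, psf_sigma_px = NULL, min_separation = 3,
                         threshold_sd = 5) {
  if (is.null(psf_sigma_px)) psf_sigma_px <- 1
  out <- lapply(seq_len(n_frames(movie)), function(i) {
    d <- detect_puncta(get_frame(movie, i), psf_sigma_px = psf_sigma_px,
                       min_separation = min_separation,
                       threshold_sd = threshold_sd)
    if (nrow(d)) cbind(frame = i, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      quality = numeric(0), edge = logical(0))
  out
}

#' Background-subtracted summed intensity of a punctum
#'
#' Adds all pixel values in a square window around the punctum and
#' subtracts the local background, estimated as the median of a square
#' annulus around the window, times the window area.
#'
#' @param frame numeric matrix.
#' @param x,y punctum position, 0-based pixel coordinates.
#' @param window_radius half-size of the summation window, pixels.
#' @param annulus inner and outer half-sizes of the background annulus.
#' @return list with `S` (summed intensity, counts), `b` (background,
#'   counts/pixel) and `clipped` (TRUE when the window ran off the frame).
#' @export
sum_intensity <- function(frame, x, y, window_radius = 3,
                          annulus = c(5, 7)) {
  ny <- nrow(frame); nx <- ncol(frame)
  cx <- round(x); cy <- round(y)
  w <- window_radius
  rr <- (cy - w):(cy + w); cc <- (cx - w):(cx + w)
  clipped <- any(rr < 0) || any(cc < 0) || any(rr > ny - 1) || any(cc > nx - 1)
  rr <- rr[rr >= 0 & rr <= ny - 1]; cc <- cc[cc >= 0 & cc <= nx - 1]
  win <- frame[rr + 1, cc + 1, drop = FALSE]
  a0 <- annulus[1]; a1 <- annulus[2]
  ar <- (cy - a1):(cy + a1); ac <- (cx - a1):(cx + a1)
  ring <- expand.grid(r = ar, c = ac)
  ring <- ring[pmax(abs(ring$r - cy), abs(ring$c - cx)) >= a0, ]
  ring <- ring[ring$r >= 0 & ring$r <= ny - 1 &
                 ring$c >= 0 & ring$c <= nx - 1, ]
  b <- if (nrow(ring)) stats::median(frame[cbind(ring$r + 1, ring$c + 1)])
       else stats::median(frame)
  list(S = sum(win) - b * length(win), b = b, clipped = clipped)
}

#' Quantify summed intensities for a table of detections
#'
#' @param movie a [Movie()].
#' @param detections data.frame from [detect_movie()] (or with columns
#'   `frame`, `x`, `y`).
#' @inheritParams sum_intensity
#' @return the detections data.frame with `S`, `b`, `clipped` appended.
#' @export
measure_intensities <- function(movie, detections, window_radius = 3,
                                annulus = c(5, 7)) {
  n <- nrow(detections)
  S <- numeric(n); b <- numeric(n); clipped <- logical(n)
  for (k in seq_len(n)) {
    m <- sum_intensity(get_frame(movie, detections$frame[k]),
                       detections$x[k], detections$y[k],
                       window_radius = window_radius, annulus = annulus)
    S[k] <- m$S; b[k] <- m$b; clipped[k] <- m$clipped
  }
  cbind(detections, S = S, b = b, clipped = clipped)
}

#' Classify punctum intensities into quantal populations
#'
#' Fits a two-component equal-variance Gaussian mixture to summed
#' intensities by expectation-maximization with deterministic moment-based
#' initialization (component means start at the lower/upper quartiles).
#' Pop1 is the lower-mean component; its mean is the quantal intensity, the
#' summed intensity of a single fluorophore. A punctum is assigned to the
#' component with higher posterior probability. The `bimodal` flag is set
#' when the two-component fit beats a single Gaussian by BIC; puncta above
#' `mean(Pop2) + 3 SD` are flagged as likely multi-fluorophore outliers.
#'
#' @param intensities numeric vector of summed intensities (>= 6 values).
#' @param max_iter,tol EM iteration controls.
#' @return object of class `quantal_fit`: list with `assignment` (1/2 per
#'   punctum), `means`, `sd`, `weights`, `q` (quantal intensity =
#'   Pop1 mean), `ratio` (Pop2/Pop1 mean ratio), `bimodal`, `outlier`
#'   (logical per punctum), `loglik`, `bic1`, `bic2`, `n`.
#' @export
classify_populations <- function(intensities, max_iter = 500, tol = 1e-10) {
  x <- as.numeric(intensities)
  if (length(x) < 6)
    stop("insufficient data: need at least 6 intensities, got ", length(x))
  n <- length(x)
  sd0 <- stats::sd(x)
  if (!is.finite(sd0) || sd0 < .Machine$double.eps * max(abs(x), 1)) {
    # degenerate unimodal sample
    return(structure(list(assignment = rep(1L, n), means = c(mean(x), NA),
                          sd = 0, weights = c(1, 0), q = mean(x),
                          ratio = NA_real_, bimodal = FALSE,
                          outlier = rep(FALSE, n), loglik = NA_real_,
                          bic1 = NA_real_, bic2 = NA_real_, n = n),
                     class = "quantal_fit"))
  }
  mu <- unname(stats::quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5) * sd0
  sdc <- sd0 / 2
  w <- c(0.5, 0.5)
  ll_old <- -Inf; ll <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sdc)
    d2 <- w[2] * stats::dnorm(x, mu[2], sdc)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    sdc <- sqrt((sum(g * (x - mu[1])^2) + sum((1 - g) * (x - mu[2])^2)) / n)
    sdc <- max(sdc, 1e-8 * sd0)
    w <- c(mean(g), 1 - mean(g))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); w <- rev(w) }
  d1 <- w[1] * stats::dnorm(x, mu[1], sdc)
  d2 <- w[2] * stats::dnorm(x, mu[2], sdc)
  assignment <- ifelse(d2 > d1, 2L, 1L)
  ll <- sum(log(pmax(d1 + d2, .Machine$double.xmin)))
  # single-Gaussian reference fit (2 parameters) vs mixture (4 parameters)
  ll1 <- sum(stats::dnorm(x, mean(x), stats::sd(x) * sqrt((n - 1) / n),
                          log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * ll + 4 * log(n)
  bimodal <- bic2 < bic1 && all(w > 1 / n)
  outlier <- x > mu[2] + 3 * sdc
  structure(list(assignment = assignment, means = mu, sd = sdc,
                 weights = w, q = mu[1], ratio = mu[2] / mu[1],
                 bimodal = bimodal, outlier = outlier, loglik = ll,
                 bic1 = bic1, bic2 = bic2, n = n),
            class = "quantal_fit")
}

#' @export
print.quantal_fit <- function(x, ...) {
  cat(sprintf(
    "Quantal fit (n = %d): Pop1 %.1f, Pop2 %.1f (SD %.1f), ratio %.2f, %s\n",
    x$n, x$means[1], x$means[2], x$sd, x$ratio,
    if (x$bimodal) "bimodal" else "unimodal"))
  invisible(x)
}

#' Write a quantal fit as JSON
#' @param fit a `quantal_fit`.
#' @param path output path.
#' @export
write_quantal_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Line-scan intensity profile through a punctum
#'
#' Samples the frame by bilinear interpolation at pixel-pitch steps along a
#' direction through a centre point.
#'
#' @param frame numeric matrix.
#' @param center `c(x, y)`, 0-based pixel coordinates.
#' @param direction direction vector (need not be normalized).
#' @param half_length scan half-length, pixels.
#' @return list with `pos` (signed offsets, px) and `intensity`.
#' @export
line_scan <- function(frame, center, direction, half_length) {
  u <- direction / sqrt(sum(direction^2))
  pos <- seq(-half_length, half_length, by = 1)
  xs <- center[1] + pos * u[1]
  ys <- center[2] + pos * u[2]
  v <- bilinear_sample(frame, xs, ys, fill = NA_real_)
  if (anyNA(v)) stop("line scan segment extends outside the frame")
  list(pos = pos, intensity = v)
}

#' Average line-scan profiles aligned on their centroids
#'
#' Each profile is shifted so its baseline-subtracted intensity centroid
#' sits at offset 0 (linear interpolation onto the common grid), then
#' profiles are averaged.
#'
#' @param profiles list of profiles from [line_scan()].
#' @return a profile (list with `pos`, `intensity`).
#' @export
average_line_scan <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  pos <- profiles[[1]]$pos
  aligned <- vapply(profiles, function(p) {
    v <- p$intensity
    wgt <- v - min(v)
    cen <- if (sum(wgt) > 0) sum(wgt * p$pos) / sum(wgt) else 0
    stats::approx(p$pos - cen, v, xout = pos, rule = 2)$y
  }, numeric(length(pos)))
  list(pos = pos, intensity = rowMeans(aligned))
}

#' Compare a punctum profile to a PSF model profile
#'
#' Both profiles are baseline-subtracted, peak-normalized and aligned on
#' their centroids, then compared by normalized RMS difference and by the
#' ratio of their full widths at half maximum. A punctum is flagged
#' point-source consistent when the width ratio falls inside `width_band`.
#'
#' @param profile measured profile (list with `pos`, `intensity`).
#' @param model PSF model profile on the same pitch (e.g.
#'   [gaussian_profile()]).
#' @param width_band acceptable profile/model FWHM ratio range.
#' @return list with `nrms` (normalized RMS difference), `width_ratio`,
#'   `point_source` flag and `is_punctum` flag (FALSE for flat or
#'   structureless profiles).
#' @export
compare_to_psf <- function(profile, model, width_band = c(0.8, 1.25)) {
  norm_prof <- function(p) {
    v <- p$intensity - stats::median(p$intensity[c(1, length(p$intensity))])
    pk <- max(v)
    list(pos = p$pos, v = v, peak = pk)
  }
  pp <- norm_prof(profile); mm <- norm_prof(model)
  spread <- stats::mad(diff(profile$intensity)) / sqrt(2)
  if (pp$peak <= 0 || (spread > 0 && pp$peak < 3 * spread))
    return(list(nrms = NA_real_, width_ratio = NA_real_,
                point_source = FALSE, is_punctum = FALSE))
  fw_p <- profile_fwhm(pp$pos, pp$v)
  fw_m <- profile_fwhm(mm$pos, mm$v)
  if (!is.finite(fw_p) || !is.finite(fw_m))
    return(list(nrms = NA_real_, width_ratio = NA_real_,
                point_source = FALSE, is_punctum = FALSE))
  vn <- pp$v / pp$peak
  vm <- mm$v / mm$peak
  cen <- function(pos, v) { w <- pmax(v, 0); sum(w * pos) / sum(w) }
  vp_al <- stats::approx(pp$pos - cen(pp$pos, vn), vn, xout = mm$pos,
                         rule = 2)$y
  vm_al <- stats::approx(mm$pos - cen(mm$pos, vm), vm, xout = mm$pos,
                         rule = 2)$y
  nrms <- sqrt(mean((vp_al - vm_al)^2))
  ratio <- fw_p / fw_m
  list(nrms = nrms, width_ratio = ratio,
       point_source = ratio >= width_band[1] && ratio <= width_band[2],
       is_punctum = TRUE)
}

#' Write detections as CSV
#' @param detections data.frame of detections (with or without intensities).
#' @param path output path.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
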