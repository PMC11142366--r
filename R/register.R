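# Lateral drift correction: phase-only correlation with subpixel peak
# refinement, then iterative least-squares image matching.
#
# Shift convention: estimate_shift(ref, moved) returns d = (dx, dy) such
# that moved(x) ~ ref(x - d), i.e. the content of `moved` is displaced by
# +d pixels relative to `ref`. Resampling `moved` at (x + d) undoes it.

#' Phase-only correlation between two frames
#'
#' Computes the normalized cross-power spectrum
#' `R = (F_b * Conj(F_a)) / |F_b * Conj(F_a)|` and inverse-transforms it;
#' the correlation surface peaks at the displacement of `frame_b` relative
#' to `frame_a`. The returned integer shift is the argmax mapped into
#' `(-N/2, N/2]` per axis; the peak height lies in \[0, 1\] and is ~1 for
#' identical frames.
#'
#' @param frame_a,frame_b numeric matrices of identical shape (>= 16 x 16).
#' @param window apply a raised-cosine (Hann) apodization before the
#'   transform. Default `FALSE`; the movie-level driver enables it.
#' @return list with `shift` (c(dx, dy), pixels), `peak` (height), and
#'   `surface` (the correlation matrix, for subpixel refinement).
#' @export
phase_only_correlation <- function(frame_a, frame_b, window = FALSE) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frames must have identical shape")
  if (any(dim(frame_a) < 16)) stop("frames must be at least 16 x 16 pixels")
  if (stats::sd(frame_a) == 0 || stats::sd(frame_b) == 0)
    stop("degenerate input: constant frame")
  a <- frame_a - mean(frame_a)
  b <- frame_b - mean(frame_b)
  if (window) {
    w <- hann2(nrow(a), ncol(a))
    a <- a * w; b <- b * w
  }
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cross <- Fb * Conj(Fa)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- 1
  R <- cross / mag
  surf <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  idx <- which.max(surf)
  py <- (idx - 1) %% nrow(surf)          # 0-based row (y displacement)
  px <- (idx - 1) %/% nrow(surf)         # 0-based col (x displacement)
  wrap <- function(p, n) if (p > n / 2) p - n else p
  list(shift = c(wrap(px, ncol(surf)), wrap(py, nrow(surf))),
       peak = surf[idx], surface = surf)
}

#' Subpixel refinement of a phase-correlation peak
#'
#' Closed-form refinement on the 3 x 3 neighbourhood of the integer peak,
#' using the side-lobe ratio of the correlation main lobe per axis
#' (`delta = r1 / (r0 + r1)`, exact for the ideal periodic-sinc peak of a
#' pure translation). An approximation to full subpixel matching; the
#' least-squares stage refines further.
#'
#' @param poc result of [phase_only_correlation()].
#' @return list with `shift` (fractional c(dx, dy)) and `border` flag (TRUE
#'   when the peak touched the surface border and only the integer shift is
#'   returned).
#' @export
subpixel_refine_poc <- function(poc) {
  surf <- poc$surface
  ny <- nrow(surf); nx <- ncol(surf)
  d <- poc$shift
  px <- d[1] %% nx; py <- d[2] %% ny     # back to 0-based array position
  at <- function(y, x) surf[(y %% ny) + 1, (x %% nx) + 1]
  r0 <- at(py, px)
  refine_axis <- function(rm, r0, rp) {
    rm <- max(rm, 0); rp <- max(rp, 0)
    if (rp >= rm) rp / (r0 + rp) else -rm / (r0 + rm)
  }
  fx <- refine_axis(at(py, px - 1), r0, at(py, px + 1))
  fy <- refine_axis(at(py - 1, px), r0, at(py + 1, px))
  # the true fractional part lies in (-0.5, 0.5]; clamp noise excursions
  fx <- min(max(fx, -0.5), 0.5)
  fy <- min(max(fy, -0.5), 0.5)
  list(shift = c(d[1] + fx, d[2] + fy), border = FALSE)
}

#' Least-squares image matching
#'
#' Gauss-Newton minimization of the summed squared intensity difference
#' between `frame_a` and `frame_b` resampled at a candidate translation,
#' starting from `initial`. Resampling is done in the Fourier domain
#' (exact phase; bilinear interpolation imposes a phase distortion that
#' biases fractional shifts), with a border margin excluded from the sum
#' to mask wrap-around. Gradients are the mean of both frames' central
#' differences, which cancels the first-order noise-gradient bias.
#' Converges when the update norm drops below `tol` pixels or after
#' `max_iter` iterations.
#'
#' @param frame_a,frame_b numeric matrices of identical shape.
#' @param initial starting shift `c(dx, dy)` in pixels.
#' @param tol convergence tolerance on the update norm, pixels.
#' @param max_iter maximum Gauss-Newton iterations.
#' @param robust downweight outlying residuals with Tukey's biweight
#'   (iteratively reweighted least squares). Keeps a minority of moving
#'   molecules from dragging the shift estimated off the static majority;
#'   with no outliers the weights are ~1 and the estimate matches plain
#'   least squares.
#' @return list with `shift`, `residual` (mean squared difference over the
#'   overlap), `iterations`, and `converged`.
#' @export
lsq_image_matching <- function(frame_a, frame_b, initial = c(0, 0),
                               tol = 1e-3, max_iter = 50, robust = FALSE) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frames must have identical shape")
  if (stats::sd(frame_a) == 0 || stats::sd(frame_b) == 0)
    stop("degenerate input: constant frame (no texture)")
  d <- as.numeric(initial)
  ny <- nrow(frame_a); nx <- ncol(frame_a)
  max_shift <- floor(min(ny, nx) / 4)
  best <- NULL
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    if (max(abs(d)) > max_shift)
      stop("overlap below 50% of the frame at shift (",
           d[1], ", ", d[2], ")")
    bs <- fourier_shift(frame_b, d[1], d[2])
    err <- bs - frame_a
    # symmetric gradients (mean of both frames): cancels the first-order
    # noise-gradient correlation that biases one-sided Gauss-Newton steps
    gsrc <- (bs + frame_a) / 2
    gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
    gx[, 2:(nx - 1)] <- (gsrc[, 3:nx] - gsrc[, 1:(nx - 2)]) / 2
    gy[2:(ny - 1), ] <- (gsrc[3:ny, ] - gsrc[1:(ny - 2), ]) / 2
    # mask the wrap-contaminated border
    mar <- min(ceiling(max(abs(d))) + 3, max_shift)
    ok <- matrix(FALSE, ny, nx)
    ok[(mar + 1):(ny - mar), (mar + 1):(nx - mar)] <- TRUE
    e <- err[ok]; jx <- gx[ok]; jy <- gy[ok]
    residual <- mean(e^2)
    if (is.null(best) || residual < best$residual)
      best <- list(shift = d, residual = residual)
    w <- 1
    if (robust) {
      # scale from residuals at structured pixels: a background-dominated
      # MAD would put even well-aligned spots outside the inlier band
      gmag <- sqrt(jx^2 + jy^2)
      hi <- gmag >= stats::quantile(gmag, 0.95)
      s <- stats::mad(e[hi])
      if (is.finite(s) && s > 0) {
        u <- e / (4.685 * s)
        w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      }
    }
    A <- matrix(c(sum(w * jx * jx), sum(w * jx * jy),
                  sum(w * jx * jy), sum(w * jy * jy)), 2, 2)
    if (abs(det(A)) < .Machine$double.eps * length(e))
      stop("degenerate input: flat overlap (zero gradient)")
    # err = b(x + d) - a(x); moving d by -delta reduces err along gradient
    delta <- solve(A, c(sum(w * jx * e), sum(w * jy * e)))
    d <- d - delta
    if (sqrt(sum(delta^2)) < tol) { converged <- TRUE; break }
  }
  bs <- fourier_shift(frame_b, d[1], d[2])
  mar <- min(ceiling(max(abs(d))) + 3, max_shift)
  err <- (bs - frame_a)[(mar + 1):(ny - mar), (mar + 1):(nx - mar)]
  residual <- mean(err^2, na.rm = TRUE)
  if (is.null(best) || residual <= best$residual)
    best <- list(shift = d, residual = residual)
  list(shift = best$shift, residual = best$residual, iterations = it,
       converged = converged)
}

#' Estimate the shift of one frame relative to another
#'
#' The full estimation cascade: integer phase-only correlation, closed-form
#' subpixel refinement, then least-squares image matching.
#'
#' @inheritParams phase_only_correlation
#' @param window apodize before the Fourier transform (recommended for
#'   non-periodic content).
#' @param smooth_sigma Gaussian pre-smoothing (pixels) applied to both
#'   frames before estimation; suppresses the shot-noise gradients that
#'   otherwise dominate sparse single-molecule frames. 0 disables.
#' @param robust use robust (Tukey-biweight) least-squares matching so a
#'   minority of moving molecules cannot drag the drift estimate.
#' @return list with `shift`, `peak`, `residual`, `converged`.
#' @export
estimate_shift <- function(frame_a, frame_b, window = TRUE,
                           smooth_sigma = 1, robust = TRUE) {
  if (smooth_sigma > 0) {
    frame_a <- EBImage::gblur(frame_a, sigma = smooth_sigma)
    frame_b <- EBImage::gblur(frame_b, sigma = smooth_sigma)
  }
  poc <- phase_only_correlation(frame_a, frame_b, window = window)
  sub <- subpixel_refine_poc(poc)
  lsq <- lsq_image_matching(frame_a, frame_b, initial = sub$shift,
                            robust = robust)
  list(shift = lsq$shift, peak = poc$peak, residual = lsq$residual,
       converged = lsq$converged)
}

#' Correct lateral drift across a movie
#'
#' Estimates frame-to-frame shifts (default) or shifts against a fixed
#' reference frame, accumulates them relative to the reference, and
#' resamples every frame by bilinear interpolation. Out-of-field pixels are
#' filled with the frame's median background and masked in the result.
#' Frames that fail estimation (e.g. constant frames) inherit the previous
#' per-step shift and are flagged.
#'
#' @param movie a [Movie()] with >= 2 frames.
#' @param reference `"first"` or a frame index; the reference frame has
#'   cumulative shift (0, 0).
#' @param chained estimate neighbour-to-neighbour and accumulate (robust to
#'   slow intensity decay, default) rather than each-frame-to-reference.
#' @param window apodize frames before the Fourier transform.
#' @param smooth_sigma Gaussian pre-smoothing (pixels) for shift estimation
#'   only; corrected frames are resampled from the raw data.
#' @return list with `movie` (corrected [Movie()]), `trace` (a `DriftTrace`
#'   data.frame: frame, dx_px, dy_px, peak, residual, flag) and `masks`
#'   (logical array of in-field pixels).
#' @export
correct_movie <- function(movie, reference = "first", chained = TRUE,
                          window = TRUE, smooth_sigma = 1) {
  nf <- n_frames(movie)
  if (nf < 2) stop("movie must have at least 2 frames")
  ref_idx <- if (identical(reference, "first")) 1L else as.integer(reference)
  stopifnot(ref_idx >= 1, ref_idx <= nf)
  step <- matrix(0, nf, 2)
  peak <- rep(NA_real_, nf); resid <- rep(NA_real_, nf)
  flag <- rep("", nf)
  for (i in 2:nf) {
    a <- if (chained) get_frame(movie, i - 1) else get_frame(movie, ref_idx)
    b <- get_frame(movie, i)
    est <- tryCatch(estimate_shift(a, b, window = window,
                                   smooth_sigma = smooth_sigma),
                    error = identity)
    if (inherits(est, "error")) {
      step[i, ] <- if (chained) step[i - 1, ] else step[i - 1, ]
      flag[i] <- "degenerate"
    } else {
      step[i, ] <- est$shift
      peak[i] <- est$peak; resid[i] <- est$residual
      if (!est$converged) flag[i] <- "not_converged"
    }
  }
  cum <- if (chained) apply(step, 2, cumsum) else step
  cum <- sweep(cum, 2, cum[ref_idx, ])
  corrected <- array(0, dim = dim(movie$data))
  masks <- array(TRUE, dim = dim(movie$data))
  for (i in seq_len(nf)) {
    fr <- get_frame(movie, i)
    bg <- stats::median(fr)
    rs <- resample_shift(fr, cum[i, 1], cum[i, 2], fill = bg)
    corrected[, , i] <- rs$img
    masks[, , i] <- rs$mask
  }
  trace <- data.frame(frame = seq_len(nf), dx_px = cum[, 1],
                      dy_px = cum[, 2], peak = peak, residual = resid,
                      flag = flag, stringsAsFactors = FALSE)
  class(trace) <- c("DriftTrace", "data.frame")
  list(movie = Movie(corrected, movie$pixel_size, movie$frame_interval),
       trace = trace, masks = masks)
}

#' Write a drift trace as CSV
#' @param trace a `DriftTrace` from [correct_movie()].
#' @param path output CSV path.
#' @export
write_drift_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
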