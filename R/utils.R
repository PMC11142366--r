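# Internal numerical helpers shared across modules.
#
# Coordinate convention (package-wide): pixel coordinates are 0-based with
# pixel centers at integer positions; x indexes columns, y indexes rows.
# Physical positions are x_nm = x_px * pixel_size.

#' Bilinear sampling of an image at fractional pixel coordinates
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param x,y numeric vectors of 0-based pixel coordinates.
#' @param fill value returned for samples outside the image domain.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y, fill = NA_real_) {
  ny <- nrow(img); nx <- ncol(img)
  ix <- floor(x); iy <- floor(y)
  fx <- x - ix; fy <- y - iy
  ok <- x >= 0 & y >= 0 & x <= nx - 1 & y <= ny - 1 & is.finite(x) & is.finite(y)
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  ix <- ix[ok]; iy <- iy[ok]; fx <- fx[ok]; fy <- fy[ok]
  # clamp the upper neighbour for samples exactly on the last row/column
  ix1 <- pmin(ix + 1L, nx - 1L); iy1 <- pmin(iy + 1L, ny - 1L)
  v00 <- img[cbind(iy + 1L, ix + 1L)]
  v01 <- img[cbind(iy + 1L, ix1 + 1L)]
  v10 <- img[cbind(iy1 + 1L, ix + 1L)]
  v11 <- img[cbind(iy1 + 1L, ix1 + 1L)]
  out[ok] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out
}

#' Resample an image at a translational offset
#'
#' Samples `img` at (x + dx, y + dy); this undoes a content shift of
#' (+dx, +dy) (i.e. if `img(x) = ref(x - d)`, the result approximates `ref`).
#'
#' @return list with `img` (resampled matrix) and `mask` (TRUE where the
#'   sample fell inside the source image).
#' @keywords internal
resample_shift <- function(img, dx, dy, fill = NA_real_) {
  ny <- nrow(img); nx <- ncol(img)
  xs <- rep(seq_len(nx) - 1, each = ny) + dx
  ys <- rep(seq_len(ny) - 1, times = nx) + dy
  v <- bilinear_sample(img, xs, ys, fill = NA_real_)
  mask <- matrix(!is.na(v), ny, nx)
  v[is.na(v)] <- fill
  list(img = matrix(v, ny, nx), mask = mask)
}

# Fourier-domain subpixel shift: samples img at (x + dx, y + dy), i.e.
# undoes a content shift of +d. Exact phase for band-limited content;
# wraps at the borders (callers mask a margin).
fourier_shift <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  ky <- c(0:floor((ny - 1) / 2), -(ceiling((ny - 1) / 2):1)) / ny
  kx <- c(0:floor((nx - 1) / 2), -(ceiling((nx - 1) / 2):1)) / nx
  ph <- outer(ky * dy, rep(1, nx)) + outer(rep(1, ny), kx * dx)
  Re(stats::fft(stats::fft(img) * exp(2i * pi * ph), inverse = TRUE)) /
    length(img)
}

# Circular shift of a matrix: content moves by (+dx, +dy) pixels.
circshift2 <- function(m, dx, dy) {
  ny <- nrow(m); nx <- ncol(m)
  ri <- ((seq_len(ny) - 1 - dy) %% ny) + 1
  ci <- ((seq_len(nx) - 1 - dx) %% nx) + 1
  m[ri, ci, drop = FALSE]
}

# Separable raised-cosine (Hann) apodization window.
hann2 <- function(ny, nx) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
  outer(wy, wx)
}

#' Render a pixel-integrated 2-D Gaussian spot into an image
#'
#' Adds a spot of total mass `total` centred at 0-based position (x, y) with
#' isotropic width `sigma_px`, integrating the Gaussian over each pixel's
#' unit square (exact via the normal CDF), restricted to a window of
#' +/- 5 sigma for speed.
#'
#' @keywords internal
render_gaussian_spot <- function(img, x, y, sigma_px, total) {
  ny <- nrow(img); nx <- ncol(img)
  w <- ceiling(5 * sigma_px) + 1
  x0 <- max(0L, floor(x - w)); x1 <- min(nx - 1L, ceiling(x + w))
  y0 <- max(0L, floor(y - w)); y1 <- min(ny - 1L, ceiling(y + w))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  mx <- stats::pnorm(xs + 0.5, x, sigma_px) - stats::pnorm(xs - 0.5, x, sigma_px)
  my <- stats::pnorm(ys + 0.5, y, sigma_px) - stats::pnorm(ys - 0.5, y, sigma_px)
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + total * (my %o% mx)
  img
}

# Deterministic substream seeds below 2^31, derived from one master seed.
derive_stream_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Evaluate expr with the RNG temporarily seeded (NULL seed = current stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

#' Reference Gaussian intensity profile
#'
#' One-dimensional pixel-pitch line profile of an isotropic Gaussian point
#' spread function, peak-normalized; used as the model curve when comparing
#' measured punctum profiles to the optics.
#'
#' @param sigma_px PSF width in pixels.
#' @param half_length half-length of the profile in pixels.
#' @return list with `pos` (offsets, px) and `intensity` (peak-normalized).
#' @export
gaussian_profile <- function(sigma_px, half_length) {
  pos <- seq(-half_length, half_length, by = 1)
  list(pos = pos, intensity = exp(-pos^2 / (2 * sigma_px^2)))
}

#' Fit a Gaussian to a 1-D intensity profile
#'
#' Least-squares fit of `A * exp(-(pos - c)^2 / (2 s^2)) + b`; returns the
#' fitted parameters and the full width at half maximum `2.355 * s`.
#'
#' @param pos sample positions.
#' @param v intensities.
#' @return list with `amplitude`, `center`, `sigma`, `baseline`, `fwhm`;
#'   `NULL` when the fit fails.
#' @export
fit_gaussian_profile <- function(pos, v) {
  b0 <- min(v); a0 <- max(v) - b0
  c0 <- pos[which.max(v)]
  s0 <- max(profile_fwhm(pos, v) / 2.355, diff(range(pos)) / 20, 0.1,
            na.rm = TRUE)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(v ~ A * exp(-(pos - cc)^2 / (2 * s^2)) + b,
                 start = list(A = a0, cc = c0, s = s0, b = b0),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  list(amplitude = unname(p["A"]), center = unname(p["cc"]),
       sigma = abs(unname(p["s"])), baseline = unname(p["b"]),
       fwhm = 2 * sqrt(2 * log(2)) * abs(unname(p["s"])))
}

# Full width at half maximum of a sampled profile by linear interpolation of
# the half-maximum crossings; NA when the profile has no usable peak.
profile_fwhm <- function(pos, v) {
  base <- min(v)
  peak <- max(v)
  if (!is.finite(peak) || peak - base <= 0) return(NA_real_)
  h <- base + (peak - base) / 2
  ip <- which.max(v)
  left <- NA_real_; right <- NA_real_
  if (ip > 1) {
    for (i in seq(ip - 1, 1)) {
      if (v[i] <= h) {
        left <- pos[i] + (h - v[i]) / (v[i + 1] - v[i]) * (pos[i + 1] - pos[i])
        break
      }
    }
  }
  if (ip < length(v)) {
    for (i in seq(ip + 1, length(v))) {
      if (v[i] <= h) {
        right <- pos[i - 1] + (h - v[i - 1]) / (v[i] - v[i - 1]) * (pos[i] - pos[i - 1])
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right)) return(NA_real_)
  right - left
}
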