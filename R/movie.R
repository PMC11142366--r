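#' Time-lapse movie container
#'
#' A `Movie` is a time-ordered stack of single-plane grayscale frames with
#' physical calibration. Frames are stored as a numeric array
#' `[rows, cols, frames]` in camera counts.
#'
#' @param data numeric 3-D array (rows, cols, frames) or a list of matrices.
#' @param pixel_size pixel size in nm/pixel (> 0).
#' @param frame_interval time between frames in seconds (> 0).
#' @return an object of class `Movie`.
#' @export
Movie <- function(data, pixel_size, frame_interval) {
  if (is.list(data)) data <- simplify2array(data)
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1)
  stopifnot(length(dim(data)) == 3)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number (nm/pixel)")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive number (s)")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "Movie")
}

#' @export
print.Movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Movie: %d frame(s) of %d x %d px, %.1f nm/px, dt = %g s\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a `Movie`.
#' @export
n_frames <- function(movie) dim(movie$data)[3]

#' Extract one frame of a movie as a matrix
#' @param movie a `Movie`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(movie, i) movie$data[, , i]

#' Write a movie as a multi-page 16-bit TIFF
#'
#' Counts are clamped to \[0, 65535\] and stored as 16-bit unsigned samples,
#' one page per frame. Calibration is not stored in the TIFF; keep it in the
#' pipeline configuration.
#'
#' @param movie a `Movie`.
#' @param path output file path.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- lapply(seq_len(n_frames(movie)), function(i) {
    m <- pmin(pmax(get_frame(movie, i), 0), 65535) / 65535
    m
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a Movie
#'
#' @param path TIFF file path.
#' @param pixel_size nm/pixel calibration to attach.
#' @param frame_interval frame interval (s) to attach.
#' @export
read_movie_tiff <- function(path, pixel_size, frame_interval) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * 65535
  })
  Movie(frames, pixel_size = pixel_size, frame_interval = frame_interval)
}
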