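# Kymograph construction along an organelle axis and frame-to-frame track
# linking (nearest-neighbour with gap closing), replacing manual tracking.

#' Organelle path (stereocilium axis) in the image plane
#'
#' An ordered polyline from base to tip in 0-based pixel coordinates; the
#' axial coordinate s runs from 0 at the base and increases toward the tip
#' (tip-ward velocities are positive).
#'
#' @param points n x 2 matrix (or data.frame) of control points `(x, y)` in
#'   pixels, base first, tip last (>= 2 points).
#' @param half_width perpendicular scan half-width, pixels.
#' @param pixel_size nm per pixel.
#' @return object of class `organelle_path` with 1 px-pitch sample points,
#'   tangents, normals and arc lengths (px and nm).
#' @export
organelle_path <- function(points, half_width = 2, pixel_size) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 2)
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) <= 0) stop("path must have positive arc length")
  arc <- c(0, cumsum(seg_len))
  total <- arc[length(arc)]
  s_px <- seq(0, total, by = 1)
  if (s_px[length(s_px)] < total) s_px <- c(s_px, total)
  interp <- function(coord) stats::approx(arc, pts[, coord], xout = s_px)$y
  xs <- interp(1); ys <- interp(2)
  # tangent by forward/central differences along samples
  n <- length(s_px)
  tx <- c(diff(xs), xs[n] - xs[n - 1])
  ty <- c(diff(ys), ys[n] - ys[n - 1])
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  tx <- tx / nrm; ty <- ty / nrm
  structure(list(control_points = pts, half_width = half_width,
                 pixel_size = pixel_size, s_px = s_px,
                 s_nm = s_px * pixel_size, x = xs, y = ys,
                 tangent = cbind(tx, ty), normal = cbind(-ty, tx),
                 length_px = total, length_nm = total * pixel_size),
            class = "organelle_path")
}

#' Write / read an organelle path as JSON
#' @param path an `organelle_path`.
#' @param file JSON file path.
#' @export
write_path_json <- function(path, file) {
  jsonlite::write_json(list(control_points = path$control_points,
                            half_width = path$half_width,
                            pixel_size = path$pixel_size),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_path_json
#' @export
read_path_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  organelle_path(x$control_points, half_width = x$half_width,
                 pixel_size = x$pixel_size)
}

#' Build a kymograph along a path
#'
#' Each column is the line scan along the path at one frame; the intensity
#' at each path sample is the maximum over a perpendicular scan of
#' `half_width` pixels either side (bilinear sampling), which keeps faint
#' single molecules visible on thin organelles. Rows run base to tip,
#' columns are time.
#'
#' @param movie a [Movie()].
#' @param path an [organelle_path()].
#' @return object of class `kymograph`: list with `data` (rows = path
#'   samples, cols = frames), `nm_per_row`, `s_per_col`, `s_nm`.
#' @export
build_kymograph <- function(movie, path) {
  nf <- n_frames(movie)
  ny <- nrow(movie$data); nx <- ncol(movie$data)
  offs <- seq(-path$half_width, path$half_width, by = 1)
  np <- length(path$s_px)
  xs <- outer(path$x, rep(1, length(offs))) +
    outer(path$normal[, 1], offs)
  ys <- outer(path$y, rep(1, length(offs))) +
    outer(path$normal[, 2], offs)
  if (any(path$x < 0 | path$x > nx - 1 | path$y < 0 | path$y > ny - 1))
    stop("path extends outside the frame bounds")
  K <- matrix(0, np, nf)
  for (f in seq_len(nf)) {
    fr <- get_frame(movie, f)
    v <- bilinear_sample(fr, as.vector(xs), as.vector(ys), fill = NA_real_)
    v <- matrix(v, np, length(offs))
    K[, f] <- apply(v, 1, max, na.rm = TRUE)
  }
  structure(list(data = K, nm_per_row = path$pixel_size,
                 s_per_col = movie$frame_interval, s_nm = path$s_nm,
                 path = path),
            class = "kymograph")
}

#' Write a kymograph as TIFF and/or PNG
#'
#' The TIFF stores raw counts (16-bit); the PNG is contrast-stretched for
#' display with time running left to right and the base at the top row.
#'
#' @param kymo a `kymograph`.
#' @param tiff_path,png_path output paths (`NULL` to skip).
#' @export
write_kymograph <- function(kymo, tiff_path = NULL, png_path = NULL) {
  if (!is.null(tiff_path)) {
    m <- pmin(pmax(kymo$data, 0), 65535) / 65535
    tiff::writeTIFF(m, tiff_path, bits.per.sample = 16,
                    compression = "none")
  }
  if (!is.null(png_path)) {
    rng <- range(kymo$data)
    m <- if (diff(rng) > 0) (kymo$data - rng[1]) / diff(rng)
         else kymo$data * 0
    png::writePNG(m, png_path)
  }
  invisible(kymo)
}

# Exact minimum-cost assignment of detections to candidate tracks by
# branch-and-bound over the (small) candidate sets; unlinked detections pay
# `penalty`. Returns an integer vector: track index per detection (0 = new).
assign_exact <- function(cost, penalty) {
  m <- nrow(cost); k <- ncol(cost)
  best <- list(cost = Inf, assign = rep(0L, m))
  assign <- rep(0L, m)
  used <- rep(FALSE, k)
  rec <- function(i, acc) {
    if (acc >= best$cost) return()
    if (i > m) {
      best <<- list(cost = acc, assign = assign)
      return()
    }
    ord <- order(cost[i, ])
    for (j in ord) {
      if (!used[j] && is.finite(cost[i, j])) {
        used[j] <<- TRUE; assign[i] <<- j
        rec(i + 1, acc + cost[i, j])
        used[j] <<- FALSE; assign[i] <<- 0L
      }
    }
    rec(i + 1, acc + penalty)
  }
  rec(1L, 0)
  best$assign
}

# Greedy fallback for large frames: links in order of increasing distance.
assign_greedy <- function(cost) {
  m <- nrow(cost); k <- ncol(cost)
  assign <- rep(0L, m)
  used <- rep(FALSE, k)
  cand <- which(is.finite(cost), arr.ind = TRUE)
  if (nrow(cand) == 0) return(assign)
  cand <- cand[order(cost[cand]), , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (assign[i] == 0L && !used[j]) { assign[i] <- j; used[j] <- TRUE }
  }
  assign
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame nearest-neighbour linking with gap closing: a detection
#' may continue a track whose last detection lies at most `max_gap` frames
#' back, within a search radius of `max_jump * gap` (nm). Within a frame
#' the assignment minimizes total displacement (exact for <= `exact_n`
#' detections, greedy beyond). Unlinked detections start new tracks.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (pixels);
#'   additional columns are carried through.
#' @param pixel_size nm per pixel.
#' @param max_jump maximum frame-to-frame displacement, nm.
#' @param max_gap maximum number of missed frames bridged by gap closing.
#' @param exact_n use the exact assignment up to this many detections per
#'   frame.
#' @return the detections data.frame with a `track_id` column, ordered by
#'   track and frame; class `tracks`.
#' @export
link_tracks <- function(detections, pixel_size, max_jump = 500,
                        max_gap = 2, exact_n = 7) {
  det <- as.data.frame(detections)
  if (nrow(det) == 0) {
    det$track_id <- integer(0)
    class(det) <- c("tracks", "data.frame")
    return(det)
  }
  stopifnot(all(c("frame", "x", "y") %in% names(det)))
  det <- det[order(det$frame), , drop = FALSE]
  max_jump_px <- max_jump / pixel_size
  det$track_id <- NA_integer_
  # active track state: id, last x/y, last frame
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0)
  next_id <- 1L
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    live <- which(act_f >= f - 1 - max_gap)
    m <- length(rows); k <- length(live)
    assign <- rep(0L, m)
    if (k > 0) {
      gap <- f - act_f[live]                 # >= 1 frame steps spanned
      lim <- max_jump_px * gap
      cost <- outer(det$x[rows], act_x[live], "-")^2 +
        outer(det$y[rows], act_y[live], "-")^2
      cost <- sqrt(cost)
      cost[cost > matrix(lim, m, k, byrow = TRUE)] <- Inf
      assign <- if (m <= exact_n && k <= exact_n)
        assign_exact(cost, penalty = max_jump_px * (1 + max_gap))
      else assign_greedy(cost)
    }
    for (i in seq_len(m)) {
      r <- rows[i]
      if (assign[i] > 0L) {
        j <- live[assign[i]]
        det$track_id[r] <- act_id[j]
        act_x[j] <- det$x[r]; act_y[j] <- det$y[r]; act_f[j] <- f
      } else {
        det$track_id[r] <- next_id
        act_id <- c(act_id, next_id)
        act_x <- c(act_x, det$x[r]); act_y <- c(act_y, det$y[r])
        act_f <- c(act_f, f)
        next_id <- next_id + 1L
      }
    }
  }
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  class(det) <- c("tracks", "data.frame")
  det
}

#' Project track positions onto an organelle path
#'
#' Maps each detection to the arc length of its foot point on the path
#' polyline (axial coordinate s, nm from the base), so the axial
#' coordinate is continuous rather than quantized to path samples.
#' Detections farther from the path than the scan half-width are dropped
#' and counted.
#'
#' @param tracks data.frame from [link_tracks()] (columns `frame`, `x`,
#'   `y`, `track_id`).
#' @param path an [organelle_path()].
#' @param frame_interval frame interval in s; when given, a `t_s` time
#'   column is added.
#' @return the tracks data.frame with `s_nm`, `t_s` and `dist_px` columns;
#'   excluded detections are reported in `attr(, "n_excluded")`.
#' @export
project_to_axis <- function(tracks, path, frame_interval = NULL) {
  det <- as.data.frame(tracks)
  if (nrow(det) == 0) {
    det$s_nm <- numeric(0); det$dist_px <- numeric(0)
    attr(det, "n_excluded") <- 0L
    return(det)
  }
  pts <- path$control_points
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  arc0 <- c(0, cumsum(seg_len))
  s_nm <- numeric(nrow(det)); dist <- numeric(nrow(det))
  for (i in seq_len(nrow(det))) {
    p <- c(det$x[i], det$y[i])
    best_d2 <- Inf; best_s <- 0
    for (k in seq_len(nrow(seg))) {
      if (seg_len[k] == 0) next
      tt <- sum((p - pts[k, ]) * seg[k, ]) / seg_len[k]^2
      tt <- min(max(tt, 0), 1)
      foot <- pts[k, ] + tt * seg[k, ]
      d2 <- sum((p - foot)^2)
      if (d2 < best_d2) {
        best_d2 <- d2
        best_s <- arc0[k] + tt * seg_len[k]
      }
    }
    s_nm[i] <- best_s * path$pixel_size
    dist[i] <- sqrt(best_d2)
  }
  det$s_nm <- s_nm
  det$dist_px <- dist
  if (!is.null(frame_interval)) det$t_s <- (det$frame - 1) * frame_interval
  keep <- dist <= path$half_width
  out <- det[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- class(tracks)
  out
}

#' Write tracks as CSV
#' @param tracks a `tracks` data.frame.
#' @param path output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}
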