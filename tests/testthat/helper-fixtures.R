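# Shared fixture builders. All fixtures are generated in code; none are
# stored on disk.

# A camera frame with rendered Gaussian spots, Poisson shot noise and
# Gaussian read noise. `spots` is a matrix with columns x, y, total.
noisy_spot_frame <- function(spots, ny = 64, nx = 64, sigma_px = 1,
                             background = 10, offset = 100,
                             read_noise = 2) {
  sig <- matrix(0, ny, nx)
  if (!is.null(spots) && nrow(spots) > 0) {
    for (k in seq_len(nrow(spots)))
      sig <- kymotor:::render_gaussian_spot(sig, spots[k, 1], spots[k, 2],
                                            sigma_px, spots[k, 3])
  }
  matrix(stats::rpois(ny * nx, sig + background), ny, nx) + offset +
    matrix(stats::rnorm(ny * nx, sd = read_noise), ny, nx)
}

# Noise-free frame of spots on a constant baseline.
clean_spot_frame <- function(spots, ny = 64, nx = 64, sigma_px = 1,
                             baseline = 20) {
  sig <- matrix(baseline, ny, nx)
  for (k in seq_len(nrow(spots)))
    sig <- kymotor:::render_gaussian_spot(sig, spots[k, 1], spots[k, 2],
                                          sigma_px, spots[k, 3])
  sig
}

# Irregular static-spot scene shared by registration tests.
registration_pair <- function(seed, shift = c(0, 0), n_spots = 20,
                              total = 600, sigma_px = 1.3) {
  set.seed(seed)
  spots <- cbind(stats::runif(n_spots, 8, 56), stats::runif(n_spots, 8, 56))
  render <- function(d) {
    m <- matrix(0, 64, 64)
    for (k in seq_len(n_spots))
      m <- kymotor:::render_gaussian_spot(m, spots[k, 1] + d[1],
                                          spots[k, 2] + d[2],
                                          sigma_px, total)
    m + 20
  }
  list(a = render(c(0, 0)), b = render(shift))
}

# Long, effectively unbounded axis for trajectory-level tests.
long_axis <- function() stereocilium_geometry(c(0, 0), c(1e6, 0))

# Brute-force minimum-total-displacement matching of detections to track
# heads (independent oracle for the linker): enumerates all injective
# assignments, allowing unmatched detections at cost `penalty`.
oracle_assignment <- function(dmat, max_dist, penalty) {
  m <- nrow(dmat); k <- ncol(dmat)
  options_per_det <- lapply(seq_len(m), function(i) c(0, seq_len(k)))
  grid <- do.call(expand.grid, options_per_det)
  best <- NULL; best_cost <- Inf
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    used <- asg[asg > 0]
    if (anyDuplicated(used)) next
    cost <- 0; feasible <- TRUE
    for (i in seq_len(m)) {
      if (asg[i] == 0) cost <- cost + penalty
      else if (dmat[i, asg[i]] > max_dist) { feasible <- FALSE; break }
      else cost <- cost + dmat[i, asg[i]]
    }
    if (feasible && cost < best_cost) { best_cost <- cost; best <- asg }
  }
  best
}
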