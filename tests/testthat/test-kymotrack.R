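test_that("organelle paths validate and parameterize arc length", {
  p <- organelle_path(rbind(c(0, 10), c(30, 10), c(30, 40)),
                      half_width = 2, pixel_size = 100)
  expect_equal(p$length_px, 60)
  expect_equal(p$length_nm, 6000)
  expect_error(organelle_path(rbind(c(1, 1)), pixel_size = 100))
  expect_error(organelle_path(rbind(c(1, 1), c(1, 1)), pixel_size = 100),
               "arc length")
  tf <- tempfile(fileext = ".json")
  write_path_json(p, tf)
  p2 <- read_path_json(tf)
  expect_equal(p2$length_nm, p$length_nm)
  unlink(tf)
})

test_that("kymographs show static rows and sloped streaks", {
  px <- 162.5
  geo <- stereocilium_geometry(c(5, 16) * px, c(75, 16) * px)
  path <- organelle_path(rbind(c(5, 16), c(75, 16)), half_width = 2,
                         pixel_size = px)
  # static emitter: one bright row, constant across columns
  sig <- clean_spot_frame(cbind(40, 16, 800), ny = 32, nx = 80,
                          baseline = 10)
  movie <- Movie(replicate(12, sig), px, 1)
  k <- build_kymograph(movie, path)
  expect_equal(ncol(k$data), 12)
  rows <- apply(k$data, 2, which.max)
  expect_true(all(rows == rows[1]))
  # constant-velocity emitter: straight streak of the right slope
  v <- 200  # nm/s
  frames <- lapply(0:19, function(f)
    clean_spot_frame(cbind(10 + v * f / px, 16, 800), ny = 32, nx = 80,
                     baseline = 10))
  movie2 <- Movie(frames, px, 1)
  k2 <- build_kymograph(movie2, path)
  pos_nm <- (apply(k2$data, 2, which.max) - 1) * k2$nm_per_row
  slope <- unname(stats::coef(stats::lm(pos_nm ~ I(0:19)))[2])
  expect_lt(abs(slope - v) / v, 0.05)
  # empty movie: background statistics only
  bg <- Movie(replicate(5, matrix(10, 32, 80)), px, 1)
  k3 <- build_kymograph(bg, path)
  expect_true(all(abs(k3$data - 10) < 1e-9))
  # out-of-frame path rejected
  bad <- organelle_path(rbind(c(-5, 16), c(75, 16)), pixel_size = px)
  expect_error(build_kymograph(movie, bad), "outside")
})

test_that("kymographs export to TIFF and PNG", {
  px <- 162.5
  path <- organelle_path(rbind(c(5, 16), c(70, 16)), pixel_size = px)
  movie <- Movie(replicate(4, clean_spot_frame(cbind(40, 16, 800),
                                               ny = 32, nx = 80)), px, 1)
  k <- build_kymograph(movie, path)
  tf <- tempfile(fileext = ".tif"); pf <- tempfile(fileext = ".png")
  write_kymograph(k, tf, pf)
  expect_true(file.exists(tf) && file.exists(pf))
  back <- tiff::readTIFF(tf)
  expect_equal(dim(back), dim(k$data))
  unlink(c(tf, pf))
})

test_that("single emitters and separated emitters link into clean tracks", {
  det <- data.frame(frame = 1:10, x = 20 + 0.1 * (1:10), y = 16)
  tr <- link_tracks(det, pixel_size = 162.5)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
  det2 <- rbind(data.frame(frame = rep(1:10, each = 1), x = 10, y = 16),
                data.frame(frame = 1:10, x = 30, y = 16))
  tr2 <- link_tracks(det2, pixel_size = 162.5)
  expect_equal(length(unique(tr2$track_id)), 2)
  by_track <- split(tr2$x, tr2$track_id)
  expect_true(all(vapply(by_track, function(x) length(unique(x)) == 1,
                         logical(1))))
  # empty input
  tr0 <- link_tracks(data.frame(frame = integer(0), x = numeric(0),
                                y = numeric(0)), pixel_size = 162.5)
  expect_equal(nrow(tr0), 0)
})

test_that("linking matches the brute-force assignment on crossing tracks", {
  px <- 100
  # two trajectories crossing at frame 5, plus a bystander
  t <- 0:9
  a <- cbind(frame = t + 1, x = 10 + t, y = 20)
  b <- cbind(frame = t + 1, x = 19 - t, y = 20.4)
  c0 <- cbind(frame = t + 1, x = 30, y = 10)
  det <- as.data.frame(rbind(a, b, c0))
  tr <- link_tracks(det, pixel_size = px, max_jump = 300)
  expect_equal(length(unique(tr$track_id)), 3)
  # replay the per-frame matching against the exhaustive oracle
  max_jump_px <- 300 / px
  heads <- det[det$frame == 1, c("x", "y")]
  ids <- seq_len(nrow(heads))
  for (f in 2:10) {
    cur <- det[det$frame == f, c("x", "y")]
    dmat <- as.matrix(stats::dist(rbind(as.matrix(cur),
                                        as.matrix(heads))))
    dmat <- dmat[seq_len(nrow(cur)), nrow(cur) + seq_len(nrow(heads)),
                 drop = FALSE]
    asg <- oracle_assignment(dmat, max_jump_px,
                             penalty = max_jump_px * 3)
    # package assignment for the same frame
    got <- tr$track_id[tr$frame == f][order(tr$x[tr$frame == f])]
    want <- ids[asg][order(cur$x)]
    expect_equal(got, want)
    heads <- cur
    ids <- ids[asg]
  }
})

test_that("gap closing bridges missed frames within the scaled radius", {
  det <- data.frame(frame = c(1, 2, 4, 5), x = c(10, 10.1, 10.2, 10.3),
                    y = 16)
  tr <- link_tracks(det, pixel_size = 162.5, max_jump = 500, max_gap = 2)
  expect_equal(length(unique(tr$track_id)), 1)
  tr2 <- link_tracks(det, pixel_size = 162.5, max_jump = 500, max_gap = 0)
  expect_equal(length(unique(tr2$track_id)), 2)
})

test_that("projection maps detections to continuous arc length", {
  px <- 100
  path <- organelle_path(rbind(c(0, 10), c(50, 10)), half_width = 2,
                         pixel_size = px)
  det <- data.frame(frame = 1:3,
                    x = c(0, 20.37, 30), y = c(10, 10, 11.5),
                    track_id = 1L)
  pr <- project_to_axis(det, path, frame_interval = 0.5)
  expect_equal(pr$s_nm, c(0, 2037, 3000), tolerance = 1e-9)
  expect_equal(pr$t_s, c(0, 0.5, 1))
  # beyond the half-width the detection is excluded
  det2 <- data.frame(frame = 1, x = 20, y = 14, track_id = 1L)
  pr2 <- project_to_axis(det2, path)
  expect_equal(nrow(pr2), 0)
  expect_equal(attr(pr2, "n_excluded"), 1L)
})

test_that("end-to-end tracking recovers a processive trajectory", {
  px <- 162.5
  geo <- stereocilium_geometry(c(5, 16) * px, c(75, 16) * px)
  cfg <- sim_config(image_shape = c(32, 80), n_frames = 25, seed = 77)
  sim <- simulate_movie(cfg, geo,
                        list(emitter(motility_model("processive",
                                                    speed = 150),
                                     start = 300)))
  det <- detect_movie(sim$movie, psf_sigma_px = 152 / px)
  tr <- link_tracks(det, pixel_size = px)
  main <- names(which.max(table(tr$track_id)))
  path <- organelle_path(rbind(c(5, 16), c(75, 16)), half_width = 2,
                         pixel_size = px)
  pr <- project_to_axis(tr[tr$track_id == main, ], path,
                        frame_interval = 1)
  truth <- sim$truth$emitters[[1]]$axial_nm[pr$frame]
  expect_lt(sqrt(mean((pr$s_nm - truth)^2)), px)   # < 1 pixel RMS
  # with an unbounded search radius and no gaps, identity is exact
  tr_inf <- link_tracks(det, pixel_size = px, max_jump = 1e9, max_gap = 0)
  expect_equal(length(unique(tr_inf$track_id)), 1)
})
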