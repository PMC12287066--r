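track_from_norm <- function(xn, yn, frame_rate = 25,
                            p1 = c(0, 100), p2 = c(100, 100)) {
  # place normalized points into the pixel frame implied by p1/p2 (y down)
  scale <- sqrt(sum((p2 - p1)^2))
  e1 <- (p2 - p1) / scale
  e2 <- c(e1[2], -e1[1])
  px <- p1[1] + scale * (xn * e1[1] + yn * e2[1])
  py <- p1[2] + scale * (xn * e1[2] + yn * e2[2])
  tracking_table(seq_along(px) - 1L, px, py, frame_rate,
                 reference_points = list(p1 = p1, p2 = p2))
}

test_that("board transform maps the reference frame onto the unit square", {
  track <- tracking_table(
    frame = 0:2, x = c(50, 0, 100), y = c(50, 100, 100), frame_rate = 25,
    reference_points = list(p1 = c(0, 100), p2 = c(100, 100))
  )
  traj <- board_transform(track)
  expect_equal(c(traj$x[1], traj$y[1]), c(0.5, 0.5)) # hand-computed affine map
  expect_equal(c(traj$x[2], traj$y[2]), c(0, 0))     # P1 -> bottom-left
  expect_equal(c(traj$x[3], traj$y[3]), c(1, 0))     # P2 -> bottom-right
})

test_that("board transform is invariant to rigid motions of the camera", {
  set.seed(31)
  n <- 200
  xn <- runif(n)
  yn <- runif(n)
  base <- board_transform(track_from_norm(xn, yn))
  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p1 <- c(0, 100)
  raw <- track_from_norm(xn, yn)
  pts <- t(rot %*% rbind(raw$x - p1[1], raw$y - p1[2]))
  p2r <- as.numeric(rot %*% (c(100, 100) - p1)) + p1
  rotated <- tracking_table(
    raw$frame, pts[, 1] + p1[1], pts[, 2] + p1[2], 25,
    reference_points = list(p1 = p1, p2 = p2r)
  )
  rt <- board_transform(rotated)
  expect_equal(rt$x, base$x, tolerance = 1e-9)
  expect_equal(rt$y, base$y, tolerance = 1e-9)
})

test_that("points outside the board are clamped and flagged", {
  track <- tracking_table(0:1, c(-10, 50), c(100, 50), 25,
                          reference_points = list(p1 = c(0, 100), p2 = c(100, 100)))
  traj <- board_transform(track)
  expect_true(traj$clamped[1])
  expect_equal(traj$x[1], 0)
  expect_false(traj$clamped[2])
})

test_that("zone entry detection matches the run-length oracle", {
  fr <- 25
  n <- 200
  xn <- rep(0.9, n)
  yn <- rep(0.9, n)
  xn[51:80] <- 0.5 # 30 frames inside the central hole
  yn[51:80] <- 0.5
  traj <- board_transform(track_from_norm(xn, yn, frame_rate = fr))
  ev <- detect_zone_events(traj, zone_disc(), min_duration = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_end - ev$t_start, 30 / fr) # 1.2 s
  expect_equal(ev$t_start, 50 / fr)
  expect_equal(ev$type, "hole")
  # never entering the zone
  away <- board_transform(track_from_norm(rep(0.9, n), rep(0.9, n)))
  expect_equal(nrow(detect_zone_events(away, zone_disc())), 0)
})

test_that("a single out-of-zone frame splits two events", {
  xn <- c(rep(0.5, 10), 0.9, rep(0.5, 10))
  yn <- rep(0.5, 21)
  traj <- board_transform(track_from_norm(xn, yn))
  ev <- detect_zone_events(traj, zone_disc(), min_duration = 0)
  expect_equal(nrow(ev), 2)
  # min_duration filters short visits out
  ev2 <- detect_zone_events(traj, zone_disc(), min_duration = 1)
  expect_equal(nrow(ev2), 0)
})

test_that("edge-band zone detects board-edge exploration", {
  xn <- c(rep(0.5, 5), rep(0.02, 5), rep(0.5, 5))
  yn <- rep(0.5, 15)
  traj <- board_transform(track_from_norm(xn, yn))
  ev <- detect_zone_events(traj, zone_edge(width = 0.1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "edge")
  expect_equal(ev$t_end - ev$t_start, 5 / 25)
})

test_that("zone events compose with total_event_duration to the frame count", {
  set.seed(44)
  n <- 1000
  traj <- board_transform(track_from_norm(runif(n), runif(n)))
  zone <- zone_disc(radius = 0.3)
  ev <- detect_zone_events(traj, zone)
  inside <- sum(in_zone(traj, zone))
  expect_equal(total_event_duration(ev), inside / 25, tolerance = 1 / 25)
})

test_that("occupancy conserves tracked time, excluding gaps", {
  fr <- 25
  # stationary animal: all time in one bin
  still <- board_transform(track_from_norm(rep(0.31, 3000), rep(0.72, 3000)))
  occ <- presence_map(still, grid_n = 32)
  expect_equal(sum(occ), 120)
  expect_equal(sum(occ > 0), 1)
  expect_equal(max(occ), 120)

  set.seed(12)
  rnd <- board_transform(track_from_norm(runif(3000), runif(3000)))
  expect_equal(sum(presence_map(rnd, 32)), 3000 / fr)

  # 10% gaps reduce total occupancy accordingly
  xn <- runif(3000)
  gap_idx <- seq_len(300)
  raw <- track_from_norm(xn, runif(3000))
  raw$x[gap_idx] <- NA
  gappy <- tracking_table(raw$frame, raw$x, raw$y, fr,
                          reference_points = list(p1 = c(0, 100), p2 = c(100, 100)))
  expect_equal(sum(presence_map(board_transform(gappy), 32)), 0.9 * 120)
})

test_that("signal maps normalize by occupancy: constant z gives 1 everywhere visited", {
  set.seed(3)
  n_frames <- 500
  fr <- 25
  fs <- 100
  traj <- board_transform(track_from_norm(runif(n_frames), runif(n_frames),
                                          frame_rate = fr))
  ch <- fake_channel(rep(1, n_frames / fr * fs), fs = fs)
  maps <- signal_maps(traj, ch, grid_n = 8)
  expect_true(all(abs(maps$signal_norm[maps$visited & maps$sample_count > 0] - 1) < 1e-12))
  expect_true(all(is.na(maps$signal_norm[!maps$visited])))
})

test_that("signal mean per bin is independent of visit count; sums are not", {
  fr <- 25
  fs <- 25 # one photometry sample per frame keeps the fixture exact
  # visit bin A (0.1, 0.1) and bin B (0.9, 0.9) in alternating blocks
  block <- 50
  xn <- c(rep(0.1, block), rep(0.9, block))
  yn <- xn
  traj1 <- board_transform(track_from_norm(xn, yn, frame_rate = fr))
  z1 <- c(rep(2, block), rep(0, block))
  ch1 <- fake_channel(z1, fs = fs)
  m1 <- signal_maps(traj1, ch1, grid_n = 4)
  expect_equal(m1$signal_norm[1, 1], 2)
  expect_equal(m1$signal_norm[4, 4], 0)

  # double the dwell in bin A with identical z statistics
  xn2 <- c(rep(0.1, 2 * block), rep(0.9, block))
  traj2 <- board_transform(track_from_norm(xn2, xn2, frame_rate = fr))
  ch2 <- fake_channel(c(rep(2, 2 * block), rep(0, block)), fs = fs)
  m2 <- signal_maps(traj2, ch2, grid_n = 4)
  expect_equal(m2$signal_norm[1, 1], m1$signal_norm[1, 1]) # mean unchanged
  expect_equal(m2$signal_sum[1, 1], 2 * m1$signal_sum[1, 1]) # sum doubles
  expect_equal(m2$occupancy[1, 1], 2 * m1$occupancy[1, 1])
})

test_that("non-overlapping photometry and tracking spans are an error", {
  traj <- board_transform(track_from_norm(runif(100), runif(100)))
  ch <- fake_channel(rnorm(100), fs = 100, t0 = 500)
  expect_error(signal_maps(traj, ch, grid_n = 8), class = "fipho_validation_error")
})

test_that("tidy maps expose bins with midpoints and the visited mask", {
  traj <- board_transform(track_from_norm(runif(200), runif(200)))
  ch <- fake_channel(rnorm(800), fs = 100)
  td <- tidy(signal_maps(traj, ch, grid_n = 8))
  expect_equal(nrow(td), 64)
  expect_equal(sum(td$occupancy), 200 / 25, tolerance = 1e-9)
  expect_true(all(td$x_mid > 0 & td$x_mid < 1))
})
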