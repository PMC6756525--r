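test_that("frame averaging: constant stacks pass through, flicker shrinks by the window factor", {
  const <- replicate(10, matrix(0.4, 6, 6), simplify = FALSE)
  out <- average_frames(const, window = 6)
  expect_equal(out, const)

  # a pixel flickering 1,0,1,0,... averages to its window occupancy
  n <- 20
  flick <- lapply(seq_len(n), function(k) {
    m <- matrix(0, 5, 5); m[3, 3] <- (k %% 2); m
  })
  out <- average_frames(flick, window = 6)
  k <- 10  # interior frame, full window (frames 7..12 -> three 'on')
  expect_equal(out[[k]][3, 3], 3 / 6)
  expect_equal(out[[k]][1, 1], 0)

  expect_error(average_frames(flick, window = 0), "window")
  # the default window is the typical six frames
  expect_equal(eval(formals(average_frames)$window), 6)
})

test_that("blob detection: thresholding, area filtering, centroids", {
  expect_equal(nrow(detect_blobs(matrix(0, 40, 40))), 0)

  fr <- matrix(0, 40, 40)
  fr[10:13, 20:24] <- 1                     # 20 px blob
  d <- detect_blobs(fr, area_bounds = c(8, 60))
  expect_equal(nrow(d), 1)
  expect_equal(d$area, 20)
  expect_equal(d$x, 21, tolerance = 1e-9)   # 0-based centroid of cols 21..25
  expect_equal(d$y, 10.5, tolerance = 1e-9)

  fr[30:31, 5:6] <- 1                       # 4 px blob: too small to be a bird
  d2 <- detect_blobs(fr, area_bounds = c(8, 60))
  expect_equal(nrow(d2), 1)
  expect_equal(d2$x, d$x)
})

test_that("linking: smooth motion gives one track containing every detection", {
  n <- 50
  det <- data.frame(frame = 1:n, x_m = 0.1 * (1:n), y_m = 2 + 0.05 * (1:n))
  tr <- link_detections(det, dt = 0.04)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), n)
})

test_that("linking: crossing constant-velocity targets keep their identities", {
  n <- 60
  t <- (1:n) * 0.04
  a <- cbind(10 * t, 2 + 0 * t)        # moves right along y = 2
  b <- cbind(24 - 10 * t, 2 + 0 * t)   # moves left along y = 2, crosses a
  det <- data.frame(frame = rep(1:n, 2), x_m = c(a[, 1], b[, 1]),
                    y_m = c(a[, 2], b[, 2]))
  det <- det[order(det$frame), ]
  tr <- link_detections(det, dt = 0.04, gate = 3)
  expect_equal(length(unique(tr$track_id)), 2)
  # constant velocity throughout: no identity swap at the crossing
  for (id in unique(tr$track_id)) {
    x <- tr$x_m[tr$track_id == id]
    expect_lt(max(abs(diff(diff(x)))), 1e-6)
  }
})

test_that("linking: a one-off detection becomes a closed length-1 track", {
  det <- data.frame(frame = 3L, x_m = 1, y_m = 1)
  tr <- link_detections(det, dt = 0.04, n_frames = 40)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$frame, 3L)
})

test_that("speed filter keeps plausible tracks and drops fast/slow ones", {
  mk <- function(id, v) {
    t <- seq(0, 10, 0.5)
    data.frame(track_id = id, frame = seq_along(t), time_s = t,
               x_m = v * 0.75 * t, y_m = 0, x_px = 50, y_px = 50, area = 20)
  }
  td <- rbind(mk(1, 1.1), mk(2, 3.0), mk(3, 0.0))
  kept <- filter_speed_outliers(td, bl_m = 0.75)
  expect_equal(sort(unique(kept$track_id)), 1)
})

test_that("dive detection needs the splash signature inside the bounding box", {
  base <- function(id, endx, areas) {
    n <- length(areas)
    t <- seq(0, by = 0.04, length.out = n)
    data.frame(track_id = id, frame = seq_len(n), time_s = t,
               x_m = 10 + 0.5 * t, y_m = 10, x_px = endx, y_px = 100,
               area = areas)
  }
  splash <- c(rep(20, 100), 20 + round(14 * sin(seq(0, pi, length.out = 20))),
              rep(6, 3))
  flat <- rep(20, 123)
  td <- rbind(base(1, 300, splash),   # splash mid-frame: a dive
              base(2, 5, splash),     # same signature at the edge: left view
              base(3, 300, flat))     # just vanishes: occlusion, not a dive
  dv <- detect_dives(td, frame_size = c(640, 360))
  expect_equal(dv$track_id, 1)
  expect_equal(dv$time_s, max(td$time_s[td$track_id == 1]))
})

test_that("track_frames recovers a rendered raft end to end", {
  cam <- camera_model(elevation = 110, inclination = 15, hfov = 55,
                      width = 640, height = 360, fps = 25)
  cf <- raft_config(n_birds = 12, duration = 12, target_nnd = 9.3,
                    dive_params = dive_params(p0 = 0.05, p1 = 0.05))
  ds <- simulate_raft(cf, seed = 4)
  stk <- render_frames(ds, cam, anchor = 0.45, blob_radius_bl = 0.6)
  tk <- track_frames(stk, bl_m = 0.75, area_bounds = c(4, 80))
  ev <- evaluate_tracking(ds, tk, stk)
  expect_gt(ev$position_recall, 0.9)
  expect_gt(length(unique(tk$dataset$tracks$bird_id)), 0)
  # body-length scale estimated from blob major axes is the right order
  expect_gt(tk$bl_m, 0.2)
  expect_lt(tk$bl_m, 2)
})
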