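render_cam <- function(...)
  camera_model(elevation = 60, inclination = 20, hfov = 40, width = 320,
               height = 240, fps = 25, ...)

test_that("a stationary bird renders as exactly one blob in every frame", {
  ds <- manual_dataset(list(line_bird(1, seq(0, 2, 0.04), 0, 0)))
  stk <- render_frames(ds, render_cam())
  for (k in seq(1, length(stk$frames), by = 10)) {
    d <- detect_blobs(stk$frames[[k]], area_bounds = c(1, 1e5))
    expect_equal(nrow(d), 1)
  }
})

test_that("blob centroids back-project to the true ground position within 0.5 BL", {
  birds <- list(line_bird(1, seq(0, 2, 0.04), 0, 0, vx = 1),
                line_bird(2, seq(0, 2, 0.04), 8, 6, vx = -0.5, vy = 0.5))
  ds <- manual_dataset(birds)
  stk <- render_frames(ds, render_cam())
  k <- 26  # t = 1 s
  d <- detect_blobs(stk$frames[[k]], area_bounds = c(1, 1e5))
  expect_equal(nrow(d), 2)
  g <- pixel_to_ground(stk$camera, cbind(d$x, d$y))
  truth <- rbind(c(1, 0), c(7.5, 6.5))
  truth_m <- cbind(stk$origin[1] + stk$bl_m * truth[, 1],
                   stk$origin[2] + stk$bl_m * truth[, 2])
  err <- sapply(1:2, function(i)
    min(sqrt((g[, 1] - truth_m[i, 1])^2 + (g[, 2] - truth_m[i, 2])^2)))
  expect_lt(max(err) / stk$bl_m, 0.5)
})

test_that("a dived bird leaves no blob after the splash has vanished", {
  t <- seq(0, 10, 0.04)
  b <- line_bird(1, t, 0, 0, vx = 0.5)
  ds <- manual_dataset(list(b),
                       dives = data.frame(raft_id = 1, bird_id = 1,
                                          time_s = 10, x_bl = 5, y_bl = 0,
                                          heading_deg = 0))
  ds$meta$duration <- 15
  stk <- render_frames(ds, render_cam())
  after <- which(stk$times > 12)
  expect_true(all(vapply(stk$frames[after], max, 0) == 0))
  # splash: area swells above the pre-dive level just after the dive
  pre <- detect_blobs(stk$frames[[which.min(abs(stk$times - 9.8))]],
                      area_bounds = c(1, 1e5))$area
  swell <- detect_blobs(stk$frames[[which.min(abs(stk$times - 10.25))]],
                        area_bounds = c(1, 1e5))$area
  expect_gt(swell, pre)
})

test_that("birds outside the footprint are clipped with a warning", {
  birds <- list(line_bird(1, seq(0, 1, 0.04), 0, 0),
                line_bird(2, seq(0, 1, 0.04), 4000, 0))
  ds <- manual_dataset(birds)
  expect_warning(render_frames(ds, render_cam(),
                               origin = c(0, 100), anchor = NULL),
                 "clipped")
})

test_that("frames write to numbered PNGs and read back identically", {
  ds <- manual_dataset(list(line_bird(1, seq(0, 0.2, 0.04), 0, 0)))
  stk <- render_frames(ds, render_cam())
  dir <- withr::local_tempdir()
  paths <- write_frames(stk, dir)
  expect_true(all(file.exists(paths)))
  rd <- read_frames(dir, fps = 25)
  expect_equal(length(rd$frames), length(stk$frames))
  expect_equal(rd$frames[[3]], stk$frames[[3]], tolerance = 1 / 255)
})
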