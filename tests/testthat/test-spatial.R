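test_that("two parallel birds produce two symmetric unit cells", {
  t <- seq(0, 10, 0.04)
  ds <- manual_dataset(list(line_bird(1, t, 0, 0, vy = 1),
                            line_bird(2, t, 5, 0, vy = 1)))
  hm <- relative_neighbour_density(ds, grid_spec(extent = 10, cell = 2))
  nz <- which(hm$values > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 2)
  expect_true(all(hm$values[nz] == 1))
  # both heading +y, so the neighbour sits exactly left / right (y = 0 row)
  cy <- hm$grid$centers[nz[, 2]]
  cx <- hm$grid$centers[nz[, 1]]
  expect_equal(sort(cx), c(-5, 5))
  expect_equal(cy, c(1, 1) * cy[1])  # same band, mirrored offsets
})

test_that("focal-frame statistics are invariant to global rotation", {
  ds <- small_raft(n = 25, duration = 20, seed = 14)
  rot <- ds
  th <- pi / 2
  rot$tracks$x_bl <- -ds$tracks$y_bl
  rot$tracks$y_bl <- ds$tracks$x_bl
  rot$dives$x_bl <- -ds$dives$y_bl
  rot$dives$y_bl <- ds$dives$x_bl
  rot$dives$heading_deg <- ds$dives$heading_deg + 90
  g <- grid_spec(extent = 20, cell = 2)
  expect_equal(relative_neighbour_density(ds, g)$values,
               relative_neighbour_density(rot, g)$values)
  expect_equal(fraction_followed(ds, g)$fraction$values,
               fraction_followed(rot, g)$fraction$values)
})

test_that("circular variance closed forms: aligned 0, balanced antipodal and cardinal 1", {
  # perfectly aligned headings: zero variance
  expect_equal(heading_cell_cv(c(0, 0, 0)), 0, tolerance = 1e-9)
  # cell mixture {0, 0, 180, -180}: zero resultant, variance exactly 1
  expect_equal(heading_cell_cv(c(0, 0, 180)), 1, tolerance = 1e-9)
  # cell mixture {0, 0, 90, 180, 270, -180}: zero resultant again
  expect_equal(heading_cell_cv(c(0, 0, 90, 180, 270)), 1, tolerance = 1e-9)
})

test_that("NND and speed summaries match hand computation", {
  t <- seq(0, 0.5, 0.04)
  ds <- manual_dataset(list(line_bird(1, t, 0, 0, vx = 0.01),
                            line_bird(2, t, 5, 0, vx = 0.01),
                            line_bird(3, t, 12, 0, vx = 0.01)))
  st <- summary_stats(ds, step = 1)  # single timestep at t = 0
  expect_equal(st$nnd_mean, 17 / 3, tolerance = 1e-6)
  expect_equal(st$speed_mean, 0.01, tolerance = 1e-9)

  frozen <- manual_dataset(list(line_bird(1, t, 0, 0), line_bird(2, t, 4, 0)))
  expect_equal(summary_stats(frozen, step = 1)$speed_mean, 0)

  expect_equal(transmission_speed(70.28, 1.67), 42.0838, tolerance = 1e-4)
})

test_that("fraction followed: the followed cell is 1, a non-diving focal gives 0", {
  t <- seq(0, 6, 0.04)
  # C dives at t = 5; F (10 BL behind, heading +x) dives 1 s later
  f <- line_bird(1, c(t[t < 6], 6), 0, 0, vx = 0.1)
  c_ <- line_bird(2, c(t[t < 5], 5), 10, 0, vx = 0.1)
  dv <- data.frame(raft_id = 1, bird_id = c(2, 1),
                   time_s = c(5, 6), x_bl = c(10.5, 0.6), y_bl = c(0, 0),
                   heading_deg = c(0, 0))
  ds <- manual_dataset(list(f, c_), dives = dv)
  ff <- fraction_followed(ds, grid_spec(extent = 20, cell = 2))
  expect_equal(nrow(ff$pairs), 1)
  expect_true(ff$pairs$followed)
  expect_equal(max(ff$fraction$values, na.rm = TRUE), 1)
  expect_equal(max(ff$density$values), 1)  # normalization max is exactly 1

  # focal that never dives: all fractions zero
  dv2 <- dv[1, ]
  f2 <- line_bird(1, t, 0, 0, vx = 0.1)
  ds2 <- manual_dataset(list(f2, c_), dives = dv2)
  ff2 <- fraction_followed(ds2, grid_spec(extent = 20, cell = 2))
  expect_equal(sum(ff2$fraction$values, na.rm = TRUE), 0)
  expect_true(all(ff2$fraction$values <= 1, na.rm = TRUE))
})

test_that("dive-time randomization preserves counts and is seed-deterministic", {
  ds <- small_raft(n = 30, duration = 30, seed = 4)
  expect_gt(nrow(ds$dives), 5)
  g <- grid_spec(extent = 20, cell = 4)
  a <- randomize_dive_times(ds, g, n = 20, seed = 9)
  b <- randomize_dive_times(ds, g, n = 20, seed = 9)
  c <- randomize_dive_times(ds, g, n = 20, seed = 10)
  expect_identical(a$fraction$values, b$fraction$values)
  expect_identical(a$front_bias, b$front_bias)
  expect_false(identical(a$front_bias, c$front_bias))
  expect_equal(length(a$front_bias), 20)
  expect_true(all(a$fraction$values <= 1, na.rm = TRUE))
})

test_that("wave diagnostic emits (dt, along-offset) pairs with the right signs", {
  t <- seq(0, 2, 0.04)
  b1 <- line_bird(1, c(t[t < 1], 1), 0, 0, vx = 0.1)
  b2 <- line_bird(2, c(t[t < 2], 2), -5, 0, vx = 0.1)
  dv <- data.frame(raft_id = 1, bird_id = c(1, 2), time_s = c(1, 2),
                   x_bl = c(0.1, -4.9), y_bl = c(0, 0),
                   heading_deg = c(0, 0))
  ds <- manual_dataset(list(b1, b2), dives = dv)
  wd <- wave_diagnostic(ds, window = 30)
  # one ordered pair: the second dive, 1 s later and 5 BL behind the first
  expect_equal(nrow(wd$pairs), 1)
  expect_equal(wd$pairs$dt, 1)
  expect_equal(wd$pairs$along, -5, tolerance = 1e-9)
})

test_that("the wave generator trips the diagnostic and social data does not", {
  cfw <- raft_config(n_birds = 100, duration = 60,
                     dive_params = dive_params(p0 = 0.002, p1 = 0.002))
  wave <- simulate_wave_raft(cfw, band_prob = 0.7, seed = 3)
  expect_gt(nrow(wave$dives), 20)
  # front-before concentration: later dives sit behind earlier ones
  expect_gt(wave_diagnostic(wave)$score, 0.2)
  soc <- simulate_raft(raft_config(n_birds = 60, duration = 60), seed = 3)
  expect_lt(wave_diagnostic(soc)$score, 0.1)
})
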