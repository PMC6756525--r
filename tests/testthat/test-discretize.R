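test_that("one bird, 60 s, no dives gives 120 empty-cue records", {
  ds <- manual_dataset(list(line_bird(1, seq(0, 60, 0.5), 0, 0, vx = 1)))
  obs <- discretize_dives(ds)
  expect_equal(nrow(obs$records), 120)
  expect_true(all(obs$records$dived == 0))
  expect_equal(nrow(obs$cues), 0)
  expect_equal(obs$records$t0, seq(0, 59.5, 0.5))
})

test_that("conspecific dives cue records with their exact times", {
  t_a <- seq(0, 10.2, 0.04)
  # A swims along +x and dives at exactly t = 10.2; B is 10 BL ahead
  a <- line_bird(1, c(t_a[t_a < 10.2], 10.2), 0, 0, vx = 1)
  a$t <- c(t_a[t_a < 10.2], 10.2); a$x <- a$t; a$y <- rep(0, length(a$t))
  b <- line_bird(2, seq(0, 20, 0.04), 10, 0, vx = 1)
  dv <- data.frame(raft_id = 1, bird_id = 1, time_s = 10.2, x_bl = 10.2,
                   y_bl = 0, heading_deg = 0)
  obs <- discretize_dives(manual_dataset(list(a, b), dives = dv))
  bq <- obs$records$bird_id == 2
  # B's record for [10.5, 11.0) carries the cue with dt from the exact 10.2
  r105 <- which(bq & abs(obs$records$t0 - 10.5) < 1e-9)
  cue <- obs$cues[obs$cues$record == r105, ]
  expect_equal(nrow(cue), 1)
  expect_equal(cue$dt, 0.3, tolerance = 1e-9)
  # B at t0 = 10.5 sits at 20.5; the dive happened at 10.2, i.e. behind
  expect_equal(cue$dist, 10.3, tolerance = 1e-6)
  expect_equal(cue$bearing, 180, tolerance = 1e-6)
  # the record straddling the dive (state at 10.0 < 10.2) carries no cue
  r100 <- which(bq & abs(obs$records$t0 - 10.0) < 1e-9)
  expect_equal(nrow(obs$cues[obs$cues$record == r100, ]), 0)
  # A's final record is its dive indicator
  ra <- obs$records[obs$records$bird_id == 1, ]
  expect_equal(sum(ra$dived), 1)
  expect_equal(ra$t0[ra$dived == 1], 10.0)
})

test_that("pooled rafts contribute additively with raft ids retained", {
  d1 <- small_raft(n = 20, duration = 20, seed = 1)
  d2 <- small_raft(n = 15, duration = 20, seed = 2)
  o1 <- discretize_dives(d1)
  o2 <- discretize_dives(d2)
  op <- discretize_dives(combine_rafts(list(d1, d2)))
  expect_equal(nrow(op$records), nrow(o1$records) + nrow(o2$records))
  expect_equal(nrow(op$cues), nrow(o1$cues) + nrow(o2$cues))
  expect_setequal(unique(op$records$raft_id), c(1, 2))
})

test_that("duplicate dives for one bird are rejected", {
  ds <- small_raft(n = 10, duration = 10, seed = 3)
  ds$dives <- rbind(ds$dives, ds$dives[1, ])
  expect_error(discretize_dives(ds), "duplicate")
})

test_that("excluded birds drop out of records and (optionally) the cue pool", {
  ds <- small_raft(n = 20, duration = 20, seed = 5)
  stopifnot(nrow(ds$dives) > 2)
  drop <- data.frame(raft_id = 1, bird_id = ds$dives$bird_id[1])
  o_all <- discretize_dives(ds)
  o_ex <- discretize_dives(ds, exclude = drop)
  o_keepcue <- discretize_dives(ds, exclude = drop, exclude_cues = FALSE)
  expect_false(drop$bird_id %in% o_ex$records$bird_id)
  expect_lt(nrow(o_ex$records), nrow(o_all$records))
  expect_lt(nrow(o_ex$cues), nrow(o_keepcue$cues))
})

test_that("is_social applies the zone boundaries exactly", {
  params <- dive_params()  # lag 1.67, dist 70.28, arc 216.06
  cue <- function(dt, dist, bearing)
    manual_obs(one_record(), data.frame(record = 1L, dt = dt, dist = dist,
                                        bearing = bearing))
  # 10 BL directly ahead, 1.0 s ago: inside the zone
  expect_true(is_social(cue(1.0, 10, 0), params))
  # directly behind: 180 > arc/2 = 108.03
  expect_false(is_social(cue(1.0, 10, 180), params))
  # too long ago: 1.8 > 1.67
  expect_false(is_social(cue(1.8, 10, 0), params))
  # boundary conventions: dt <= lag inclusive, dist < D strict,
  # bearing <= arc/2 inclusive
  expect_true(is_social(cue(params$lag, 10, 0), params))
  expect_false(is_social(cue(1.0, params$dist, 0), params))
  expect_true(is_social(cue(1.0, 10, params$arc / 2), params))
})
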