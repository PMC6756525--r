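test_that("empty rafts, determinism and trajectory invariants", {
  empty <- simulate_raft(raft_config(n_birds = 0), seed = 1)
  expect_equal(nrow(empty$tracks), 0)
  expect_equal(nrow(empty$dives), 0)

  cf <- raft_config(n_birds = 25, duration = 20)
  a <- simulate_raft(cf, seed = 5)
  b <- simulate_raft(cf, seed = 5)
  c <- simulate_raft(cf, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$tracks, c$tracks))

  expect_true(all(is.finite(a$tracks$x_bl)), all(is.finite(a$tracks$y_bl)))
  # a diving bird's trajectory ends exactly at its dive instant
  for (i in seq_len(nrow(a$dives))) {
    tr <- a$tracks[a$tracks$bird_id == a$dives$bird_id[i], ]
    expect_equal(max(tr$time_s), a$dives$time_s[i])
  }
  # non-divers persist to the end of the clip
  survivors <- setdiff(unique(a$tracks$bird_id), a$dives$bird_id)
  for (s in survivors) {
    tr <- a$tracks[a$tracks$bird_id == s, ]
    expect_equal(max(tr$time_s), 20)
  }
})

test_that("constant-hazard dive counts stay in the 99% binomial envelope", {
  p <- 0.06
  cf <- raft_config(n_birds = 100, duration = 60,
                    dive_params = dive_params(p0 = p, p1 = p))
  ds <- simulate_raft(cf, seed = 21)
  # each bird dives within the clip w.p. 1 - (1-p)^60 (120 half-second
  # trials of the complementary-hazard probability compose exactly)
  p_dive <- 1 - (1 - p)^60
  env <- qbinom(c(0.005, 0.995), 100, p_dive)
  expect_gte(nrow(ds$dives), env[1])
  expect_lte(nrow(ds$dives), env[2])
})

test_that("social and intrinsic dive frequencies match their generating rates", {
  dp <- dive_params()  # the empirically inferred two-rate parameters
  ds <- simulate_raft(raft_config(n_birds = 100, duration = 60,
                                  dive_params = dp), seed = 8)
  obs <- discretize_dives(ds)
  soc <- is_social(obs, dp)
  q1 <- 1 - (1 - dp$p1)^0.5
  q0 <- 1 - (1 - dp$p0)^0.5
  d1 <- sum(obs$records$dived[soc]); n1 <- sum(soc)
  d0 <- sum(obs$records$dived[!soc]); n0 <- sum(!soc)
  # social dive frequency exceeds non-social
  expect_gt(d1 / n1, d0 / n0)
  # each within its 99% binomial envelope of the generating value
  expect_true(d1 >= qbinom(0.005, n1, q1) && d1 <= qbinom(0.995, n1, q1))
  expect_true(d0 >= qbinom(0.005, n0, q0) && d0 <= qbinom(0.995, n0, q0))
})

test_that("generator decision labels match is_social exactly", {
  dp <- dive_params()
  ds <- simulate_raft(raft_config(n_birds = 60, duration = 60,
                                  dive_params = dp), seed = 7)
  obs <- discretize_dives(ds)
  lab <- is_social(obs, dp)
  key_obs <- paste(obs$records$bird_id, round(obs$records$t0 * 2))
  key_dec <- paste(ds$decisions$bird_id, round(ds$decisions$t0 * 2))
  m <- match(key_obs, key_dec)
  expect_true(all(!is.na(m)))
  expect_identical(lab, ds$decisions$social[m])
})

test_that("empirical hazard matches p0 over 1e5 non-social bird-seconds", {
  p0 <- 0.0015
  cf <- raft_config(n_birds = 600, duration = 200, sim_step = 0.1,
                    heading_noise = 3, alignment_weight = 0.05,
                    attraction_weight = 0, follow_weight = 0,
                    dive_params = dive_params(p0 = p0, p1 = p0,
                                              lag = 0.5, dist = 1))
  ds <- simulate_raft(cf, seed = 31)
  dec <- ds$decisions
  ns <- dec[!dec$social, ]
  expect_gt(nrow(ns) * 0.5, 1e5)   # non-social bird-seconds simulated
  # attribute each dive to its decision interval
  dive_key <- paste(ds$dives$bird_id, floor(ds$dives$time_s / 0.5))
  ns_key <- paste(ns$bird_id, round(ns$t0 / 0.5))
  d <- sum(dive_key %in% ns_key)
  q_hat <- d / nrow(ns)
  p_hat <- 1 - (1 - q_hat)^2
  se_q <- sqrt(q_hat * (1 - q_hat) / nrow(ns))
  se_p <- 2 * (1 - q_hat) * se_q
  expect_lt(abs(p_hat - p0), 3 * se_p)
})

test_that("following the nearest forward neighbour yields front-back anisotropy", {
  cf <- raft_config(n_birds = 70, duration = 60, follow_weight = 0.05,
                    dive_params = dive_params(p0 = 0.003, p1 = 0.003))
  ds <- simulate_raft(cf, seed = 13)
  hm <- relative_neighbour_density(ds, grid_spec(extent = 20, cell = 2))
  q <- quadrant_means(hm)
  expect_gt(q["front_back"], q["left_right"])
})

test_that("respawn keeps the surface population topped up with fresh ids", {
  cf <- raft_config(n_birds = 30, duration = 40, respawn = TRUE,
                    respawn_rate = 0.5,
                    dive_params = dive_params(p0 = 0.05, p1 = 0.05))
  ds <- simulate_raft(cf, seed = 3)
  expect_gt(length(unique(ds$tracks$bird_id)), 30)
  # late-clip surface population is non-empty
  late <- ds$tracks[ds$tracks$time_s > 35, ]
  expect_gt(length(unique(late$bird_id)), 0)
})
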