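test_that("chains are reproducible under a fixed seed", {
  obs <- discretize_dives(small_raft(n = 25, duration = 20, seed = 2))
  a <- run_mcmc(obs, burn = 200, draws = 300, seed = 11)
  b <- run_mcmc(obs, burn = 200, draws = 300, seed = 11)
  c <- run_mcmc(obs, burn = 200, draws = 300, seed = 12)
  expect_identical(a$samples, b$samples)
  expect_identical(a$loglik, b$loglik)
  expect_false(identical(a$samples, c$samples))
  expect_equal(nrow(a$samples), 300)
  # summaries are consistent with the samples
  expect_equal(a$summary$mean[a$summary$parameter == "p0"],
               mean(a$samples[, "p0"]))
  expect_equal(a$summary$mle[a$summary$parameter == "p0"],
               unname(a$samples[which.max(a$loglik), "p0"]))
  # central 95% interval within the prior support
  expect_true(all(a$summary$ci_lo >= c(0, 0, 0.5, 0, 0)[1:5]))
})

test_that("the null-variant posterior covers the generating rate in >= 90% of repeats", {
  p0 <- 0.05
  covered <- logical(20)
  for (i in 1:20) {
    ds <- simulate_raft(raft_config(n_birds = 30, duration = 40,
                                    dive_params = dive_params(p0 = p0,
                                                              p1 = p0)),
                        seed = 500 + i)
    obs <- discretize_dives(ds)
    fit <- run_mcmc(obs, variant = "null", burn = 300, draws = 1500,
                    seed = i)
    s <- fit$summary
    covered[i] <- s$ci_lo[1] <= p0 && p0 <= s$ci_hi[1]
  }
  expect_gte(mean(covered), 0.9)
})

test_that("with zero dives the intrinsic-rate posterior concentrates near zero", {
  ds <- manual_dataset(lapply(1:5, function(i)
    line_bird(i, seq(0, 30, 0.5), 5 * i, 0, vx = 1)))
  obs <- discretize_dives(ds)
  expect_equal(sum(obs$records$dived), 0)
  fit <- run_mcmc(obs, variant = "null", burn = 500, draws = 3000, seed = 1)
  expect_lt(fit$summary$mean[1], 0.02)
  expect_lt(fit$summary$ci_hi[1], 0.05)
})

test_that("variants sample only their own parameter blocks", {
  obs <- discretize_dives(small_raft(n = 25, duration = 20, seed = 2))
  fno <- run_mcmc(obs, variant = "noangle", burn = 100, draws = 200,
                  seed = 5)
  expect_true(all(fno$samples[, "arc"] == 360))
  expect_setequal(fno$summary$parameter, c("p0", "p1", "lag", "dist"))
  fnull <- run_mcmc(obs, variant = "null", burn = 100, draws = 200,
                    seed = 5)
  expect_equal(fnull$summary$parameter, "p0")
})
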