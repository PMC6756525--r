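fake_fit <- function(samples, variant = "full") {
  structure(list(variant = variant, samples = samples,
                 loglik = rep(0, nrow(samples))),
            class = "dive_fit")
}

test_that("a point-mass posterior has p_waic = 0 and waic = -2 * loglik", {
  ds <- small_raft(n = 20, duration = 15, seed = 6)
  obs <- discretize_dives(ds)
  pp <- dive_params()
  th <- unlist(pp[c("p0", "p1", "lag", "dist", "arc")])
  sm <- matrix(th, 10, 5, byrow = TRUE,
               dimnames = list(NULL, names(th)))
  w <- waic(fake_fit(sm), obs)
  expect_equal(w$p_waic, 0, tolerance = 1e-10)
  expect_equal(w$waic, -2 * log_likelihood(obs, pp), tolerance = 1e-8)
  expect_equal(w$lppd, log_likelihood(obs, pp), tolerance = 1e-8)
})

test_that("streaming WAIC matches a direct two-loop computation", {
  ds <- small_raft(n = 12, duration = 6, seed = 8)
  obs <- discretize_dives(ds)
  obs$records <- obs$records[1:5, ]
  obs$cues <- obs$cues[obs$cues$record <= 5, ]
  set.seed(3)
  sm <- t(replicate(10, unlist(random_params()[c("p0", "p1", "lag", "dist",
                                                 "arc")])))
  # direct computation: the 5 x 10 pointwise log-likelihood matrix
  ll <- matrix(0, 5, 10)
  for (s in 1:10) {
    pp <- dive_params(p0 = sm[s, 1], p1 = sm[s, 2], lag = sm[s, 3],
                      dist = sm[s, 4], arc = sm[s, 5])
    soc <- is_social(obs, pp)
    q <- ifelse(soc, 1 - (1 - pp$p1)^0.5, 1 - (1 - pp$p0)^0.5)
    ll[, s] <- ifelse(obs$records$dived == 1, log(q), log1p(-q))
  }
  lppd <- sum(log(rowMeans(exp(ll))))
  p_waic <- sum(apply(ll, 1, var))
  w <- waic(fake_fit(sm), obs)
  expect_equal(w$lppd, lppd, tolerance = 1e-10)
  expect_equal(w$p_waic, p_waic, tolerance = 1e-10)
  expect_equal(w$waic, -2 * (lppd - p_waic), tolerance = 1e-10)
  expect_error(waic(fake_fit(sm[1, , drop = FALSE]), obs), "2 posterior")
})

test_that("Cohen's d follows its definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means exactly one pooled sd apart
  expect_equal(cohens_d_from_moments(1, 1, 0, 1), 1)
  expect_equal(cohens_d_from_moments(1, sqrt(0.5), 0, sqrt(1.5)), 1)
  expect_error(cohens_d_from_moments(1, 0, 0, 0), "pooled")
  # the two inferred dive rates, from their printed summary moments
  d <- cohens_d_from_moments(0.1484, 0.0021, 0.0634, 0.0022)
  expect_equal(d, 39.524, tolerance = 1e-3)
})
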