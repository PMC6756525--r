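#' Posterior sampling of the dive-model parameters
#'
#' Component-wise random-walk Metropolis over the variant's parameters with
#' reflecting Gaussian proposals at the uniform prior bounds. The
#' likelihood is discontinuous in the interaction-zone parameters (records
#' flip their social label at the cue boundaries), so a gradient-free
#' sampler is the appropriate choice; proposal scales are adapted toward a
#' 44% acceptance rate during burn-in only, and frozen afterwards.
#'
#' Sampling is done on per-second probabilities; the likelihood converts
#' them to per-interval probabilities by the complementary-hazard form,
#' matching the generator's convention exactly. Rate updates reuse cached
#' social/dive counts, so only interaction-zone proposals rescan the cue
#' table (the candidate-list acceleration). Some meta-stability of the
#' visual-arc component is expected: the likelihood is piecewise constant
#' between the observed cue bearings, so the chain moves across flat
#' plateaus separated by small jumps.
#'
#' @param obs A [discretize_dives()] result (non-empty).
#' @param priors A [dive_priors()].
#' @param variant `"full"` (all five parameters), `"noangle"` (arc fixed at
#'   360 degrees) or `"null"` (intrinsic rate only).
#' @param burn Burn-in iterations discarded (default 5000).
#' @param draws Posterior samples kept (default 20000).
#' @param seed Integer seed; the same seed gives an identical chain.
#' @param init Optional named list of starting values; by default drawn
#'   uniformly from the priors.
#' @return An object of class `dive_fit`: posterior `samples` (a
#'   `draws` x 5 matrix with fixed components filled in), per-iteration
#'   `loglik`, a `summary` data.frame (mean, sd, central 95% interval and
#'   the maximum-likelihood sample) for the sampled parameters, acceptance
#'   rates and settings.
#' @export
run_mcmc <- function(obs, priors = dive_priors(),
                     variant = c("full", "noangle", "null"), burn = 5000,
                     draws = 20000, seed = 1L, init = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(obs, "dive_obs"), nrow(obs$records) > 0, draws >= 1)
  set.seed(seed)

  par_names <- c("p0", "p1", "lag", "dist", "arc")
  sampled <- switch(variant, full = par_names,
                    noangle = c("p0", "p1", "lag", "dist"), null = "p0")
  lo <- vapply(priors[par_names], `[`, 0, 1)
  hi <- vapply(priors[par_names], `[`, 0, 2)

  theta <- (lo + stats::runif(5) * (hi - lo))
  names(theta) <- par_names
  if (variant == "noangle") theta["arc"] <- 360
  if (!is.null(init)) theta[names(init)] <- unlist(init)

  n_rec <- nrow(obs$records)
  n_dived <- sum(obs$records$dived)
  cue_rec <- obs$cues$record; cue_dt <- obs$cues$dt
  cue_dist <- obs$cues$dist; cue_brg <- obs$cues$bearing
  dived <- obs$records$dived
  zone_counts <- function(th) {
    if (variant == "null") return(c(0, 0))
    social_counts_cpp(n_rec, cue_rec, cue_dt, cue_dist, cue_brg, dived,
                      th["lag"], th["dist"], th["arc"] / 2)
  }
  cnt <- zone_counts(theta)
  cur_ll <- counts_ll(cnt[1], cnt[2], n_rec, n_dived, theta["p0"],
                      theta["p1"], obs$step)

  scales <- 0.1 * (hi - lo); names(scales) <- par_names
  reflect <- function(x, l, h) {
    w <- h - l
    y <- (x - l) %% (2 * w)
    if (y > w) y <- 2 * w - y
    l + y
  }

  total <- burn + draws
  samples <- matrix(NA_real_, draws, 5,
                    dimnames = list(NULL, par_names))
  loglik <- numeric(draws)
  acc <- setNames(numeric(5), par_names)
  prop <- setNames(numeric(5), par_names)
  acc_win <- setNames(numeric(5), par_names)
  prop_win <- setNames(numeric(5), par_names)
  burn_acc <- 0

  for (it in seq_len(total)) {
    for (nm in sampled) {
      cand <- theta
      cand[nm] <- reflect(theta[[nm]] + stats::rnorm(1, 0, scales[[nm]]),
                          lo[[nm]], hi[[nm]])
      if (nm %in% c("p0", "p1")) {
        new_cnt <- cnt
      } else {
        new_cnt <- zone_counts(cand)
      }
      new_ll <- counts_ll(new_cnt[1], new_cnt[2], n_rec, n_dived,
                          cand[["p0"]], cand[["p1"]], obs$step)
      prop[nm] <- prop[nm] + 1; prop_win[nm] <- prop_win[nm] + 1
      if (is.finite(new_ll) &&
          log(stats::runif(1)) < new_ll - cur_ll) {
        theta <- cand; cnt <- new_cnt; cur_ll <- new_ll
        acc[nm] <- acc[nm] + 1; acc_win[nm] <- acc_win[nm] + 1
        if (it <= burn) burn_acc <- burn_acc + 1
      }
    }
    if (it <= burn && it %% 50 == 0) {
      for (nm in sampled) {
        if (prop_win[nm] > 0) {
          rate <- acc_win[nm] / prop_win[nm]
          scales[nm] <- min(max(scales[nm] * exp(rate - 0.44),
                                1e-6 * (hi[[nm]] - lo[[nm]])),
                            hi[[nm]] - lo[[nm]])
        }
      }
      acc_win[] <- 0; prop_win[] <- 0
    }
    if (it == burn && burn > 0 && burn_acc == 0)
      stop("no proposal was accepted during burn-in; the chain has not ",
           "moved. Check that the observations contain dives, that the ",
           "priors cover plausible values, or supply 'init' values near ",
           "the data's support.")
    if (it > burn) {
      samples[it - burn, ] <- theta
      loglik[it - burn] <- cur_ll
    }
  }

  best <- which.max(loglik)
  summ <- do.call(rbind, lapply(sampled, function(nm) {
    s <- samples[, nm]
    data.frame(parameter = nm, mean = mean(s), sd = stats::sd(s),
               ci_lo = unname(stats::quantile(s, 0.025)),
               ci_hi = unname(stats::quantile(s, 0.975)),
               mle = s[best])
  }))
  rownames(summ) <- NULL
  structure(list(variant = variant, samples = samples, loglik = loglik,
                 summary = summ, sampled = sampled,
                 acceptance = ifelse(prop > 0, acc / prop, NA),
                 burn = burn, draws = draws, seed = seed, step = obs$step,
                 priors = priors,
                 n_records = n_rec, n_dived = n_dived),
            class = "dive_fit")
}

#' @export
print.dive_fit <- function(x, ...) {
  cat(sprintf("dive_fit (%s variant): %d draws after %d burn-in on %d records (%d dives)\n",
              x$variant, x$draws, x$burn, x$n_records, x$n_dived))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Widely applicable information criterion of a fitted dive model
#'
#' `lppd = sum_i log mean_s exp(ll_is)` and
#' `p_waic = sum_i var_s(ll_is)` over records i and posterior samples s,
#' with `waic = -2 (lppd - p_waic)`; lower is better. The pointwise
#' log-likelihood matrix is accumulated sample-by-sample (each sample
#' relabels the records and contributes one of four Bernoulli log-masses
#' per record), so the full matrix is never materialized.
#'
#' @param fit A [run_mcmc()] result.
#' @param obs The [discretize_dives()] observations the model was fitted to.
#' @param thin Keep every `thin`-th posterior sample (default 1 = all).
#' @return List with `waic`, `lppd`, `p_waic` and `n_samples`.
#' @export
waic <- function(fit, obs, thin = 1L) {
  stopifnot(inherits(fit, "dive_fit"), inherits(obs, "dive_obs"))
  keep <- seq(1L, nrow(fit$samples), by = as.integer(thin))
  if (length(keep) < 2) stop("WAIC needs at least 2 posterior samples")
  sm <- fit$samples[keep, , drop = FALSE]
  vcode <- match(fit$variant, c("full", "noangle", "null")) - 1L
  out <- waic_stream_cpp(obs$records$dived, obs$cues$record, obs$cues$dt,
                         obs$cues$dist, obs$cues$bearing, sm, obs$step,
                         vcode)
  out$n_samples <- length(keep)
  out
}

#' Cohen's d between two posterior sample vectors
#'
#' `(mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)`.
#'
#' @param samples_a,samples_b Non-empty numeric vectors.
#' @return Scalar effect size.
#' @export
cohens_d <- function(samples_a, samples_b) {
  stopifnot(length(samples_a) > 0, length(samples_b) > 0)
  cohens_d_from_moments(mean(samples_a), stats::sd(samples_a),
                        mean(samples_b), stats::sd(samples_b))
}

#' Cohen's d from summary moments
#'
#' @param mean_a,sd_a,mean_b,sd_b Means and standard deviations of the two
#'   distributions.
#' @return Scalar effect size; 0 when the means are equal, an error when
#'   they differ but the pooled sd is zero.
#' @export
cohens_d_from_moments <- function(mean_a, sd_a, mean_b, sd_b) {
  if (isTRUE(all.equal(mean_a, mean_b))) return(0)
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  if (pooled == 0) stop("zero pooled standard deviation")
  (mean_a - mean_b) / pooled
}
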