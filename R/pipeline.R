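#' Configuration of the synthetic recovery experiment
#'
#' The study-scale defaults mirror the field campaign the generator
#' emulates: 26 rafts of around a hundred birds each (sizes drawn
#' uniformly between 50 and 156, mean ~103), 60-second clips, dive
#' behaviour generated with the empirically inferred parameter means, and
#' the analysis discretized at 0.5 s with 5000 burn-in + 20000 kept MCMC
#' draws under the standard uniform priors.
#'
#' @param n_rafts Number of rafts.
#' @param birds_range Inclusive range raft sizes are drawn from.
#' @param duration Clip length, seconds.
#' @param dive_params Generating [dive_params()].
#' @param burn,draws MCMC settings.
#' @param priors A [dive_priors()].
#' @param base_config A [raft_config()] template for movement settings.
#' @return A list of class `recovery_config`.
#' @export
recovery_config <- function(n_rafts = 26, birds_range = c(50, 156),
                            duration = 60,
                            dive_params = raftdives::dive_params(),
                            burn = 5000, draws = 20000,
                            priors = dive_priors(),
                            base_config = raft_config()) {
  structure(list(n_rafts = n_rafts, birds_range = birds_range,
                 duration = duration, dive_params = dive_params,
                 burn = burn, draws = draws, priors = priors,
                 base_config = base_config),
            class = "recovery_config")
}

#' Simulate a set of rafts at the study scale
#'
#' @param config A [recovery_config()].
#' @param seed Integer seed; raft sizes and per-raft simulation seeds are
#'   derived from it.
#' @return A pooled [raft_dataset()].
#' @export
simulate_rafts <- function(config, seed = 1L) {
  set.seed(seed)
  sizes <- round(stats::runif(config$n_rafts, config$birds_range[1],
                              config$birds_range[2]))
  seeds <- sample.int(2^31 - 2, config$n_rafts)
  rafts <- lapply(seq_len(config$n_rafts), function(r) {
    cf <- config$base_config
    cf$n_birds <- as.integer(sizes[r])
    cf$duration <- config$duration
    cf$dive_params <- config$dive_params
    simulate_raft(cf, seed = seeds[r], raft_id = r)
  })
  combine_rafts(rafts)
}

#' Run the full synthetic recovery experiment
#'
#' Simulates rafts with known generating parameters, discretizes them,
#' fits the requested model variants by MCMC, and reports posterior
#' summaries with coverage flags against the generating truth, a WAIC
#' comparison table, the focal-frame heatmaps and the raft summary
#' statistics. Everything is reproducible from (config, seed); the
#' returned manifest records the configuration, derived seeds, stage
#' timings and any files written.
#'
#' @param config A [recovery_config()].
#' @param seed Integer master seed.
#' @param variants Model variants to fit (subset of full/noangle/null).
#' @param heatmaps Whether to compute the spatial heatmaps.
#' @param out_dir Optional directory; when given, trajectory/dive tables,
#'   posterior samples and summary JSON are written there.
#' @return A list of class `recovery_report`: `dataset`, `obs`, `fits`,
#'   `recovery` (per-parameter truth/estimate/coverage table), `waic`
#'   table, `heatmaps`, `stats`, `manifest`.
#' @export
run_recovery_experiment <- function(config = recovery_config(), seed = 1L,
                                    variants = c("full", "noangle", "null"),
                                    heatmaps = TRUE, out_dir = NULL) {
  t_all <- proc.time()[3]
  timings <- c()
  tic <- function() proc.time()[3]

  t0 <- tic()
  dataset <- simulate_rafts(config, seed)
  timings["simulate"] <- tic() - t0

  t0 <- tic()
  obs <- discretize_dives(dataset,
                          cue_max_lag = config$priors$lag[2],
                          cue_max_dist = config$priors$dist[2])
  timings["discretize"] <- tic() - t0

  fits <- list()
  for (v in variants) {
    t0 <- tic()
    fits[[v]] <- run_mcmc(obs, priors = config$priors, variant = v,
                          burn = config$burn, draws = config$draws,
                          seed = seed + match(v, c("full", "noangle",
                                                   "null")))
    timings[paste0("mcmc_", v)] <- tic() - t0
  }

  recovery <- NULL
  if ("full" %in% names(fits)) {
    truth <- unlist(config$dive_params[c("p0", "p1", "lag", "dist", "arc")])
    s <- fits$full$summary
    recovery <- data.frame(
      parameter = s$parameter, truth = truth[s$parameter],
      mean = s$mean, sd = s$sd, ci_lo = s$ci_lo, ci_hi = s$ci_hi,
      mle = s$mle,
      covered = truth[s$parameter] >= s$ci_lo & truth[s$parameter] <= s$ci_hi,
      rel_err = abs(s$mean - truth[s$parameter]) / truth[s$parameter])
    rownames(recovery) <- NULL
  }

  waic_tab <- NULL
  if (length(fits) > 0) {
    t0 <- tic()
    ws <- lapply(fits, waic, obs = obs)
    waic_tab <- data.frame(
      variant = names(ws),
      waic = vapply(ws, `[[`, 0, "waic"),
      lppd = vapply(ws, `[[`, 0, "lppd"),
      p_waic = vapply(ws, `[[`, 0, "p_waic"))
    if ("full" %in% waic_tab$variant)
      waic_tab$delta_vs_full <- waic_tab$waic[waic_tab$variant == "full"] -
        waic_tab$waic
    rownames(waic_tab) <- NULL
    timings["waic"] <- tic() - t0
  }

  hm <- NULL
  if (heatmaps) {
    t0 <- tic()
    hm <- list(density = relative_neighbour_density(dataset),
               headings = relative_heading_field(dataset),
               following = fraction_followed(dataset))
    timings["heatmaps"] <- tic() - t0
  }
  stats <- summary_stats(dataset, params = config$dive_params)

  outputs <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    outputs <- c(outputs, write_raft_tables(dataset, out_dir))
    for (v in names(fits))
      outputs <- c(outputs, write_posterior(
        fits[[v]], file.path(out_dir, paste0("posterior_", v, ".tsv"))))
    if (!is.null(recovery)) {
      p <- file.path(out_dir, "recovery.tsv")
      utils::write.table(recovery, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      outputs <- c(outputs, p)
    }
    if (!is.null(waic_tab)) {
      p <- file.path(out_dir, "waic.tsv")
      utils::write.table(waic_tab, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      outputs <- c(outputs, p)
    }
    if (!is.null(hm)) {
      for (nm in c("density")) {
        p <- file.path(out_dir, paste0("heatmap_", nm, ".tsv"))
        write_heatmap(hm[[nm]], p)
        outputs <- c(outputs, p)
      }
      p <- file.path(out_dir, "heatmap_fraction_followed.tsv")
      write_heatmap(hm$following$fraction, p)
      outputs <- c(outputs, p)
    }
  }

  manifest <- list(
    seed = seed,
    config = list(n_rafts = config$n_rafts,
                  birds_range = config$birds_range,
                  duration = config$duration,
                  dive_params = unclass(config$dive_params),
                  burn = config$burn, draws = config$draws,
                  priors = lapply(unclass(config$priors), identity)),
    variants = variants,
    n_records = nrow(obs$records), n_cues = nrow(obs$cues),
    n_dives = nrow(dataset$dives),
    timings = as.list(round(timings, 2)),
    total_s = round(proc.time()[3] - t_all, 2),
    outputs = outputs)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  structure(list(dataset = dataset, obs = obs, fits = fits,
                 recovery = recovery, waic = waic_tab, heatmaps = hm,
                 stats = stats, manifest = manifest),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: %d rafts, %d dives, %d records (seed %d)\n",
              x$manifest$config$n_rafts, x$manifest$n_dives,
              x$manifest$n_records, x$manifest$seed))
  if (!is.null(x$recovery)) {
    cat("\nParameter recovery (full model):\n")
    print(x$recovery, digits = 4)
  }
  if (!is.null(x$waic)) {
    cat("\nModel comparison:\n")
    print(x$waic, digits = 6)
  }
  cat(sprintf("\nRaft structure: NND %.2f +- %.2f BL, speed %.2f +- %.2f BL/s\n",
              x$stats$nnd_mean, x$stats$nnd_sd, x$stats$speed_mean,
              x$stats$speed_sd))
  invisible(x)
}
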