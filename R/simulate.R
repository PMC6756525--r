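#' Construct a raft dataset
#'
#' The common container for observed or simulated rafts: surface
#' trajectories, dive events with exact (continuous) times, and metadata.
#' All positions are in body lengths (BL) on the ground plane; headings are
#' in degrees (0 = +x, counter-clockwise).
#'
#' @param tracks data.frame with columns `raft_id`, `bird_id`, `time_s`,
#'   `x_bl`, `y_bl`; times strictly increasing within each bird. A bird's
#'   trajectory ends at its dive time if it dives.
#' @param dives data.frame with columns `raft_id`, `bird_id`, `time_s`,
#'   `x_bl`, `y_bl`, `heading_deg`.
#' @param meta named list of metadata (duration, frame rate, body-length
#'   scale in metres, ...).
#' @param decisions optional bookkeeping from the simulator: one row per
#'   (bird, decision interval) with the social label the generator used.
#' @return An object of class `raft_dataset`.
#' @export
raft_dataset <- function(tracks, dives, meta = list(), decisions = NULL) {
  need_t <- c("raft_id", "bird_id", "time_s", "x_bl", "y_bl")
  need_d <- c(need_t, "heading_deg")
  stopifnot(all(need_t %in% names(tracks)), all(need_d %in% names(dives)))
  if (nrow(tracks)) {
    stopifnot(all(is.finite(tracks$x_bl)), all(is.finite(tracks$y_bl)))
    key <- paste(tracks$raft_id, tracks$bird_id)
    bad <- tapply(tracks$time_s, key, function(t) any(diff(t) <= 0))
    if (any(unlist(bad)))
      stop("trajectory times must be strictly increasing within each bird")
  }
  structure(list(tracks = tracks, dives = dives, meta = meta,
                 decisions = decisions),
            class = "raft_dataset")
}

#' @export
print.raft_dataset <- function(x, ...) {
  nr <- length(unique(x$tracks$raft_id))
  nb <- nrow(unique(x$tracks[c("raft_id", "bird_id")]))
  cat(sprintf("raft_dataset: %d raft(s), %d bird(s), %d trajectory fixes, %d dives\n",
              nr, nb, nrow(x$tracks), nrow(x$dives)))
  invisible(x)
}

#' Pool several rafts into one dataset
#'
#' Raft ids are reassigned 1..n in order.
#'
#' @param datasets list of `raft_dataset` objects.
#' @return A pooled `raft_dataset`.
#' @export
combine_rafts <- function(datasets) {
  stopifnot(length(datasets) > 0,
            all(vapply(datasets, inherits, TRUE, "raft_dataset")))
  renum <- function(df, i) { if (nrow(df)) df$raft_id <- i; df }
  tracks <- do.call(rbind, Map(function(d, i) renum(d$tracks, i),
                               datasets, seq_along(datasets)))
  dives <- do.call(rbind, Map(function(d, i) renum(d$dives, i),
                              datasets, seq_along(datasets)))
  dec <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]$decisions
    if (is.null(d) || !nrow(d)) return(NULL)
    d$raft_id <- i
    d
  })
  dec <- if (all(vapply(dec, is.null, TRUE))) NULL else do.call(rbind, dec)
  rownames(tracks) <- rownames(dives) <- NULL
  raft_dataset(tracks, dives,
               meta = list(duration = max(vapply(datasets,
                 function(d) d$meta$duration %||% max(c(0, d$tracks$time_s)),
                 0)),
                 sim_step = datasets[[1]]$meta$sim_step,
                 n_rafts = length(datasets)),
               decisions = dec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_raft_dataset <- function(config, raft_id) {
  cols <- function(nms) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(nms)), nms))
    df
  }
  raft_dataset(cols(c("raft_id", "bird_id", "time_s", "x_bl", "y_bl")),
               cols(c("raft_id", "bird_id", "time_s", "x_bl", "y_bl",
                      "heading_deg")),
               meta = list(raft_id = raft_id, duration = config$duration,
                           sim_step = config$sim_step,
                           decision_step = config$decision_step),
               decisions = data.frame(raft_id = numeric(0),
                                      bird_id = numeric(0), t0 = numeric(0),
                                      social = logical(0)))
}

#' Simulate a foraging raft under the two-rate social dive process
#'
#' Agents move by a correlated, loosely aligned walk (a shared travel
#' direction, weak attraction to the raft centroid, and a tendency to steer
#' toward the nearest neighbour ahead). Dive trials happen on the 0.5 s
#' decision grid of the inference model: at each interval start, every
#' surfaced bird's social state is evaluated from the exact times and
#' locations of earlier conspecific dives (within the lag window, closer
#' than the detection distance, inside the visual arc), the bird dives
#' within the interval with the complementary-hazard probability
#' `1 - (1 - p)^decision_step`, and the exact dive instant is drawn
#' uniformly within the interval. A diving bird's trajectory ends at that
#' instant and the bird stops influencing its neighbours.
#'
#' The same (config, seed) always produces an identical dataset.
#'
#' @param config A [raft_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param raft_id Raft identifier stored in the output tables.
#' @return A [raft_dataset()]; `$decisions` holds the simulator's internal
#'   per-interval social labels, against which [is_social()] can be checked.
#' @export
simulate_raft <- function(config, seed = config$seed, raft_id = 1L) {
  sim_engine(config, seed, raft_id, dive_mode = "social")
}

#' Simulate a raft with dives triggered by a moving front
#'
#' A diagnostic generator for the wave hypothesis: a trigger front sweeps
#' backward through the raft (from the leading to the trailing edge, at
#' `wave_speed` body lengths per second relative to the raft), and birds
#' dive with high probability while the front passes over them, with a
#' small background rate elsewhere and no social response at all. Birds
#' ahead of a focal bird therefore dive systematically earlier — the
#' front-before concentration that [wave_diagnostic()] is designed to
#' detect, and that socially triggered diving does not produce.
#'
#' @param config A [raft_config()]; its `dive_params$p0` is used as the
#'   background rate.
#' @param wave_speed Backward sweep speed of the front relative to the
#'   raft, BL/s.
#' @param band_width Width of the trigger band along the travel direction,
#'   BL.
#' @param band_prob Per-second dive probability while under the band.
#' @param band_offset Start of the band centre ahead of the raft's leading
#'   bird, BL.
#' @param seed Integer seed.
#' @param raft_id Raft identifier.
#' @return A [raft_dataset()].
#' @export
simulate_wave_raft <- function(config, wave_speed = 5, band_width = 10,
                               band_prob = 0.5, band_offset = 5,
                               seed = config$seed, raft_id = 1L) {
  sim_engine(config, seed, raft_id, dive_mode = "wave",
             wave = list(speed = wave_speed, width = band_width,
                         prob = band_prob, offset = band_offset))
}

# The movement + dive engine shared by the social and wave generators.
sim_engine <- function(config, seed, raft_id, dive_mode, wave = NULL) {
  stopifnot(inherits(config, "raft_config"))
  set.seed(seed)
  n0 <- config$n_birds
  if (n0 == 0) return(empty_raft_dataset(config, raft_id))

  dp <- config$dive_params
  h_step <- config$sim_step
  n_steps <- round(config$duration / h_step)
  times <- (0:n_steps) * h_step
  n_dec <- floor(config$duration / config$decision_step + 1e-9)
  dec_times <- (seq_len(n_dec) - 1) * config$decision_step
  trv <- config$travel_direction * pi / 180

  cap <- if (config$respawn) 5L * n0 else n0
  px <- py <- vxs <- vys <- spd <- hd <- rep(NA_real_, cap)
  L <- 2 * config$target_nnd * sqrt(n0)
  px[1:n0] <- stats::runif(n0, 0, L)
  py[1:n0] <- stats::runif(n0, 0, L)
  hd[1:n0] <- config$travel_direction + stats::rnorm(n0, 0, 20)
  spd[1:n0] <- pmin(2.4, pmax(0.25, stats::rnorm(n0, config$mean_speed,
                                                 config$speed_sd)))
  alive <- c(rep(TRUE, n0), rep(FALSE, cap - n0))
  scheduled <- rep(NA_real_, cap)
  n_born <- n0

  X <- matrix(NA_real_, n_steps + 1L, cap)
  Y <- matrix(NA_real_, n_steps + 1L, cap)
  X[1L, 1:n0] <- px[1:n0]; Y[1L, 1:n0] <- py[1:n0]

  d_bird <- d_time <- d_x <- d_y <- d_hd <- numeric(0)
  fin_t <- fin_x <- fin_y <- rep(NA_real_, cap)
  dc_bird <- dc_t0 <- dc_soc <- vector("list", n_dec)
  respawn_at <- numeric(0)

  if (identical(dive_mode, "wave")) {
    along0 <- px[1:n0] * cos(trv) + py[1:n0] * sin(trv)
    # the band starts ahead of the leading edge and sweeps backward
    # through the raft in the raft's co-moving frame
    band_ref <- mean(along0)
    band_rel0 <- max(along0) - mean(along0) + wave$offset
  }

  dec_ptr <- 1L
  for (k in seq_len(n_steps)) {
    t_a <- times[k]; t_b <- times[k + 1L]
    idx <- which(alive)
    m <- length(idx)
    if (m == 0L && dec_ptr > n_dec && !length(respawn_at)) break
    if (m > 0L) {
      h <- hd[idx] * pi / 180
      ux <- cos(h); uy <- sin(h)
      sx <- rep(config$alignment_weight * cos(trv), m)
      sy <- rep(config$alignment_weight * sin(trv), m)
      if (m > 1L && config$attraction_weight > 0) {
        dxc <- mean(px[idx]) - px[idx]; dyc <- mean(py[idx]) - py[idx]
        nrm <- sqrt(dxc^2 + dyc^2); ok <- nrm > 1e-9
        sx[ok] <- sx[ok] + config$attraction_weight * dxc[ok] / nrm[ok]
        sy[ok] <- sy[ok] + config$attraction_weight * dyc[ok] / nrm[ok]
      }
      if (m > 1L && config$follow_weight > 0) {
        DX <- matrix(px[idx], m, m, byrow = TRUE) - px[idx]
        DY <- matrix(py[idx], m, m, byrow = TRUE) - py[idx]
        D2 <- DX^2 + DY^2
        D2[DX * ux + DY * uy <= 0] <- Inf   # only neighbours ahead
        diag(D2) <- Inf
        jm <- max.col(-D2, ties.method = "first")
        sel <- cbind(seq_len(m), jm)
        dmin <- sqrt(D2[sel])
        ok <- is.finite(dmin) & dmin > 1e-9
        sx[ok] <- sx[ok] + config$follow_weight * DX[sel][ok] / dmin[ok]
        sy[ok] <- sy[ok] + config$follow_weight * DY[sel][ok] / dmin[ok]
      }
      nh <- atan2(uy + sy, ux + sx) * 180 / pi +
        stats::rnorm(m, 0, config$heading_noise)
      hd[idx] <- nh
      vxs[idx] <- spd[idx] * cos(nh * pi / 180)
      vys[idx] <- spd[idx] * sin(nh * pi / 180)
    }

    # chronological events within [t_a, t_b): dive finalizations + decision
    repeat {
      cand <- which(alive & !is.na(scheduled))
      nd_t <- Inf; nd_i <- NA_integer_
      if (length(cand)) {
        j <- cand[which.min(scheduled[cand])]
        if (scheduled[j] < t_b - 1e-12) { nd_i <- j; nd_t <- scheduled[j] }
      }
      t0 <- if (dec_ptr <= n_dec && dec_times[dec_ptr] < t_b - 1e-12)
        dec_times[dec_ptr] else Inf
      if (!is.finite(min(nd_t, t0))) break

      if (nd_t <= t0) {
        td <- nd_t
        xd <- px[nd_i] + vxs[nd_i] * (td - t_a)
        yd <- py[nd_i] + vys[nd_i] * (td - t_a)
        d_bird <- c(d_bird, nd_i); d_time <- c(d_time, td)
        d_x <- c(d_x, xd); d_y <- c(d_y, yd)
        d_hd <- c(d_hd, atan2(vys[nd_i], vxs[nd_i]) * 180 / pi)
        fin_t[nd_i] <- td; fin_x[nd_i] <- xd; fin_y[nd_i] <- yd
        alive[nd_i] <- FALSE; scheduled[nd_i] <- NA_real_
        if (config$respawn && n_born < cap)
          respawn_at <- c(respawn_at, td + stats::rexp(1, config$respawn_rate))
      } else {
        a <- which(alive & is.na(scheduled))
        ma <- length(a)
        if (ma > 0L) {
          x0 <- px[a] + vxs[a] * (t0 - t_a)
          y0 <- py[a] + vys[a] * (t0 - t_a)
          h0 <- atan2(vys[a], vxs[a]) * 180 / pi
          if (identical(dive_mode, "social")) {
            soc <- rep(FALSE, ma)
            if (length(d_time)) {
              win <- which(d_time < t0 & d_time >= t0 - dp$lag - 1e-9)
              if (length(win)) {
                dtv <- t0 - d_time[win]
                keep <- dtv > 0 & dtv <= dp$lag
                win <- win[keep]
                if (length(win)) {
                  DXd <- outer(x0, d_x[win], function(a_, b_) b_ - a_)
                  DYd <- outer(y0, d_y[win], function(a_, b_) b_ - a_)
                  DIST <- sqrt(DXd^2 + DYd^2)
                  BRG <- abs(wrap_angle(atan2(DYd, DXd) * 180 / pi - h0))
                  soc <- rowSums(DIST < dp$dist & BRG <= dp$arc / 2) > 0
                }
              }
            }
            q <- step_prob(ifelse(soc, dp$p1, dp$p0), config$decision_step)
          } else {
            along <- x0 * cos(trv) + y0 * sin(trv)
            centre <- band_ref + config$mean_speed * t0 +
              band_rel0 - wave$speed * t0
            onband <- abs(along - centre) <= wave$width / 2
            soc <- onband
            q <- step_prob(ifelse(onband, wave$prob, dp$p0),
                           config$decision_step)
          }
          u <- stats::runif(ma)
          divers <- which(u < q)
          if (length(divers))
            scheduled[a[divers]] <- t0 +
              stats::runif(length(divers)) * config$decision_step
          dc_bird[[dec_ptr]] <- a; dc_t0[[dec_ptr]] <- rep(t0, ma)
          dc_soc[[dec_ptr]] <- soc
        }
        dec_ptr <- dec_ptr + 1L
      }
    }

    # respawns due before the end of this step appear at the next frame
    if (config$respawn && length(respawn_at)) {
      due <- respawn_at < t_b
      for (i in seq_len(sum(due))) {
        if (n_born >= cap) break
        n_born <- n_born + 1L
        srv <- which(alive)
        if (length(srv) >= 2L) {
          px[n_born] <- stats::runif(1, min(px[srv]), max(px[srv]))
          py[n_born] <- stats::runif(1, min(py[srv]), max(py[srv]))
        } else {
          px[n_born] <- stats::runif(1, 0, L); py[n_born] <- stats::runif(1, 0, L)
        }
        hd[n_born] <- config$travel_direction + stats::rnorm(1, 0, 20)
        spd[n_born] <- pmin(2.4, pmax(0.25, stats::rnorm(1, config$mean_speed,
                                                         config$speed_sd)))
        vxs[n_born] <- spd[n_born] * cos(hd[n_born] * pi / 180)
        vys[n_born] <- spd[n_born] * sin(hd[n_born] * pi / 180)
        alive[n_born] <- TRUE
      }
      respawn_at <- respawn_at[!due]
    }

    srv <- which(alive)
    if (length(srv)) {
      px[srv] <- px[srv] + vxs[srv] * h_step
      py[srv] <- py[srv] + vys[srv] * h_step
      X[k + 1L, srv] <- px[srv]
      Y[k + 1L, srv] <- py[srv]
    }
  }

  # assemble trajectory table (per-bird frame fixes + exact dive endpoint)
  born <- seq_len(n_born)
  tr_list <- vector("list", n_born)
  for (i in born) {
    ks <- which(!is.na(X[, i]))
    if (!length(ks)) next
    ts <- times[ks]; xs <- X[ks, i]; ys <- Y[ks, i]
    if (!is.na(fin_t[i])) {
      keep <- ts < fin_t[i] - 1e-12
      ts <- c(ts[keep], fin_t[i]); xs <- c(xs[keep], fin_x[i])
      ys <- c(ys[keep], fin_y[i])
    }
    tr_list[[i]] <- list(bird = rep(i, length(ts)), t = ts, x = xs, y = ys)
  }
  tr_list <- tr_list[!vapply(tr_list, is.null, TRUE)]
  tracks <- data.frame(
    raft_id = raft_id,
    bird_id = unlist(lapply(tr_list, `[[`, "bird")),
    time_s = unlist(lapply(tr_list, `[[`, "t")),
    x_bl = unlist(lapply(tr_list, `[[`, "x")),
    y_bl = unlist(lapply(tr_list, `[[`, "y")))
  dives <- data.frame(raft_id = rep(raft_id, length(d_bird)),
                      bird_id = d_bird, time_s = d_time, x_bl = d_x,
                      y_bl = d_y, heading_deg = wrap_angle(d_hd))
  decisions <- data.frame(
    raft_id = rep(raft_id, length(unlist(dc_bird))),
    bird_id = unlist(dc_bird),
    t0 = unlist(dc_t0),
    social = unlist(dc_soc))
  raft_dataset(tracks, dives,
               meta = list(raft_id = raft_id, duration = config$duration,
                           sim_step = config$sim_step,
                           decision_step = config$decision_step,
                           dive_mode = dive_mode, seed = seed,
                           params = dp),
               decisions = decisions)
}
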