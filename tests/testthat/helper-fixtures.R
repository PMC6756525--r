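# Shared fixtures and independent oracles.

wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# A small social raft for unit tests.
small_raft <- function(n = 40, duration = 30, seed = 1, ...) {
  simulate_raft(raft_config(n_birds = n, duration = duration, ...),
                seed = seed)
}

# Hand-built raft dataset from per-bird position matrices.
# birds: list of list(id, t, x, y); dives: data.frame or NULL.
manual_dataset <- function(birds, dives = NULL, raft_id = 1) {
  tracks <- do.call(rbind, lapply(birds, function(b)
    data.frame(raft_id = raft_id, bird_id = b$id, time_s = b$t,
               x_bl = b$x, y_bl = b$y)))
  if (is.null(dives))
    dives <- data.frame(raft_id = numeric(0), bird_id = numeric(0),
                        time_s = numeric(0), x_bl = numeric(0),
                        y_bl = numeric(0), heading_deg = numeric(0))
  raft_dataset(tracks, dives, meta = list(duration = max(tracks$time_s)))
}

# A straight-line bird.
line_bird <- function(id, t, x0, y0, vx = 0, vy = 0)
  list(id = id, t = t, x = x0 + vx * t, y = y0 + vy * t)

# Hand-built discretized observations (records + cues), bypassing
# discretize_dives(), for boundary tests of is_social()/log_likelihood().
manual_obs <- function(records, cues = NULL, step = 0.5) {
  if (is.null(cues))
    cues <- data.frame(record = integer(0), dt = numeric(0),
                       dist = numeric(0), bearing = numeric(0))
  structure(list(records = records, cues = cues, step = step,
                 cue_max_lag = 2, cue_max_dist = 100),
            class = "dive_obs")
}

one_record <- function(dived = 0L) {
  data.frame(raft_id = 1, bird_id = 1, interval = 0L, t0 = 0,
             x_bl = 0, y_bl = 0, heading_deg = 0, dived = dived)
}

# Brute-force two-rate log-likelihood: scans the full record x dive grid
# (no candidate-list pruning). Fully independent of the C++ kernel.
brute_loglik <- function(dataset, obs, params, variant = "full") {
  rec <- obs$records
  step <- obs$step
  soc <- rep(FALSE, nrow(rec))
  if (variant != "null") {
    arc <- if (variant == "noangle") 360 else params$arc
    for (rid in unique(rec$raft_id)) {
      rr <- which(rec$raft_id == rid)
      dv <- dataset$dives[dataset$dives$raft_id == rid, ]
      if (!nrow(dv)) next
      dt <- outer(rec$t0[rr], dv$time_s, `-`)
      dx <- -outer(rec$x_bl[rr], dv$x_bl, `-`)
      dy <- -outer(rec$y_bl[rr], dv$y_bl, `-`)
      dst <- sqrt(dx^2 + dy^2)
      brg <- abs(wrap180(atan2(dy, dx) * 180 / pi - rec$heading_deg[rr]))
      ok <- dt > 0 & dt <= params$lag & dst < params$dist &
        brg <= arc / 2 & outer(rec$bird_id[rr], dv$bird_id, `!=`)
      soc[rr] <- rowSums(ok) > 0
    }
  }
  q <- ifelse(soc, 1 - (1 - params$p1)^step, 1 - (1 - params$p0)^step)
  sum(ifelse(rec$dived == 1, log(q), log1p(-q)))
}

# Exhaustive minimum-cost assignment for small square matrices.
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf; best_p <- NULL
  for (p in perms(seq_len(n))) {
    tc <- sum(cost[cbind(seq_len(n), p)])
    if (tc < best) { best <- tc; best_p <- p }
  }
  list(cost = best, perm = best_p)
}

# Uniform draw of dive-model parameters from the priors.
random_params <- function(priors = dive_priors()) {
  dive_params(p0 = runif(1, priors$p0[1], priors$p0[2]),
              p1 = runif(1, priors$p1[1], priors$p1[2]),
              lag = runif(1, priors$lag[1], priors$lag[2]),
              dist = runif(1, max(priors$dist[1], 1e-3), priors$dist[2]),
              arc = runif(1, priors$arc[1], priors$arc[2]))
}

# Circular variance of one focal-frame cell, via relative_heading_field on
# a constructed scene: focal A at the origin heading +x, neighbours ~3 BL
# ahead with the given headings. Because every ordered pair is binned, a
# 180-degree neighbour's own view of A lands in the same cell (with
# relative heading -180); the heading sets below are chosen so the
# inspected cell contains exactly the intended circular mixture.
heading_cell_cv <- function(headings) {
  t <- seq(0, 0.5, 0.04)
  birds <- c(list(line_bird(99, t, 0, 0, vx = 0.1)),
             lapply(seq_along(headings), function(i)
               line_bird(i, t, 3, -0.05 * i,
                         vx = 0.1 * cos(headings[i] * pi / 180),
                         vy = 0.1 * sin(headings[i] * pi / 180))))
  g <- grid_spec(extent = 8, cell = 2)
  f <- relative_heading_field(manual_dataset(birds), g, step = 0.5)
  f$circular_variance$values[5, 6]   # the cell holding A's neighbours
}

# Quadrant means of a focal-frame heatmap (front/back vs left/right).
quadrant_means <- function(hm) {
  cx <- matrix(hm$grid$centers, hm$grid$n, hm$grid$n)
  cy <- matrix(hm$grid$centers, hm$grid$n, hm$grid$n, byrow = TRUE)
  v <- hm$values
  fb <- abs(cy) > abs(cx)
  lr <- abs(cx) > abs(cy)
  c(front_back = mean(v[fb], na.rm = TRUE),
    left_right = mean(v[lr], na.rm = TRUE))
}
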