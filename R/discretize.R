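#' Discretize trajectories and dives into model observations
#'
#' Converts a [raft_dataset()] into the observation table of the two-rate
#' Bernoulli dive model: one record per surfaced bird per `step`-second
#' interval, with a dive indicator (1 in the interval containing the bird's
#' dive, which is always its last record), plus a precomputed candidate-cue
#' list. A candidate cue is any other bird's dive (same raft) whose exact
#' time precedes the interval start by at most `cue_max_lag` seconds and
#' whose location lies within `cue_max_dist` body lengths of the focal's
#' position at the interval start. Candidate bounds default to the upper
#' bounds of the lag and distance priors, so the likelihood of any
#' admissible parameter proposal can be evaluated from the stored cues
#' alone. Conspecific dives keep their exact (continuous) times; only the
#' focal's dive indicator is discretized.
#'
#' Each cue carries `dt` (interval start minus dive time), `dist` and the
#' absolute `bearing` (degrees in \[0, 180\]) of the dive location from the
#' focal's heading at the interval start. Headings are taken as the
#' direction of displacement of the trajectory segment containing the
#' interval start. Multiple rafts are pooled with their raft id retained.
#' Birds with fewer than two trajectory fixes carry no defined heading and
#' are dropped.
#'
#' @param dataset A [raft_dataset()].
#' @param step Interval length in seconds (default 0.5).
#' @param cue_max_lag,cue_max_dist Candidate-cue bounds (s, BL); keep at
#'   the prior upper bounds unless the priors are changed accordingly.
#' @param exclude Optional data.frame with columns `raft_id`, `bird_id`:
#'   birds (e.g. on a fast-moving leading edge) removed from the analysis —
#'   both their records and, when `exclude_cues` is `TRUE` (default), their
#'   dives as cues for others.
#' @param exclude_cues Whether excluded birds' dives are also removed from
#'   the cue pool.
#' @return An object of class `dive_obs`: list with `records` (data.frame:
#'   `raft_id`, `bird_id`, `interval`, `t0`, `x_bl`, `y_bl`, `heading_deg`,
#'   `dived`), `cues` (data.frame: `record`, `dt`, `dist`, `bearing`), and
#'   the discretization settings.
#' @export
discretize_dives <- function(dataset, step = 0.5, cue_max_lag = 2,
                             cue_max_dist = 100, exclude = NULL,
                             exclude_cues = TRUE) {
  stopifnot(inherits(dataset, "raft_dataset"), step > 0)
  tracks <- dataset$tracks
  dives <- dataset$dives
  if (!is.null(exclude) && nrow(exclude)) {
    drop_key <- paste(exclude$raft_id, exclude$bird_id)
    tracks <- tracks[!(paste(tracks$raft_id, tracks$bird_id) %in% drop_key), ]
    if (exclude_cues)
      dives <- dives[!(paste(dives$raft_id, dives$bird_id) %in% drop_key), ]
  }

  rec_parts <- list(); cue_parts <- list(); rec_offset <- 0L
  for (rid in sort(unique(tracks$raft_id))) {
    tr <- tracks[tracks$raft_id == rid, ]
    dv <- dives[dives$raft_id == rid, ]
    if (anyDuplicated(paste(dv$bird_id, dv$time_s)) ||
        any(duplicated(dv$bird_id)))
      stop("duplicate dives for a bird id within raft ", rid)
    birds <- split(tr, tr$bird_id)
    parts <- lapply(birds, function(b) {
      if (nrow(b) < 2L) return(NULL)
      ts <- b$time_s
      j_lo <- ceiling(ts[1] / step - 1e-9)
      j_hi <- ceiling(ts[length(ts)] / step - 1e-9) - 1
      if (j_hi < j_lo) return(NULL)
      jj <- j_lo:j_hi
      t0 <- jj * step
      x0 <- stats::approx(ts, b$x_bl, xout = t0)$y
      y0 <- stats::approx(ts, b$y_bl, xout = t0)$y
      seg <- pmin(pmax(findInterval(t0, ts), 1L), nrow(b) - 1L)
      hdg <- atan2(b$y_bl[seg + 1L] - b$y_bl[seg],
                   b$x_bl[seg + 1L] - b$x_bl[seg]) * 180 / pi
      bid <- b$bird_id[1]
      dived <- integer(length(jj))
      if (bid %in% dv$bird_id) dived[length(dived)] <- 1L
      data.frame(raft_id = rid, bird_id = bid, interval = jj, t0 = t0,
                 x_bl = x0, y_bl = y0, heading_deg = hdg, dived = dived)
    })
    rec <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
    if (is.null(rec) || !nrow(rec)) next
    rownames(rec) <- NULL

    if (nrow(dv)) {
      nr <- nrow(rec); ndv <- nrow(dv)
      ri <- rep(seq_len(nr), times = ndv)
      di <- rep(seq_len(ndv), each = nr)
      dt <- rec$t0[ri] - dv$time_s[di]
      keep <- dt > 0 & dt <= cue_max_lag & rec$bird_id[ri] != dv$bird_id[di]
      ri <- ri[keep]; di <- di[keep]; dt <- dt[keep]
      dx <- dv$x_bl[di] - rec$x_bl[ri]
      dy <- dv$y_bl[di] - rec$y_bl[ri]
      dist <- sqrt(dx^2 + dy^2)
      keep2 <- dist <= cue_max_dist
      ri <- ri[keep2]; di <- di[keep2]; dt <- dt[keep2]; dist <- dist[keep2]
      bearing <- abs(wrap_angle(atan2(dy[keep2], dx[keep2]) * 180 / pi -
                                  rec$heading_deg[ri]))
      if (length(ri))
        cue_parts[[length(cue_parts) + 1L]] <-
          data.frame(record = ri + rec_offset, dt = dt, dist = dist,
                     bearing = bearing)
    }
    rec_parts[[length(rec_parts) + 1L]] <- rec
    rec_offset <- rec_offset + nrow(rec)
  }

  records <- if (length(rec_parts)) do.call(rbind, rec_parts) else
    data.frame(raft_id = numeric(0), bird_id = numeric(0),
               interval = integer(0), t0 = numeric(0), x_bl = numeric(0),
               y_bl = numeric(0), heading_deg = numeric(0),
               dived = integer(0))
  cues <- if (length(cue_parts)) do.call(rbind, cue_parts) else
    data.frame(record = integer(0), dt = numeric(0), dist = numeric(0),
               bearing = numeric(0))
  rownames(records) <- rownames(cues) <- NULL
  structure(list(records = records, cues = cues, step = step,
                 cue_max_lag = cue_max_lag, cue_max_dist = cue_max_dist),
            class = "dive_obs")
}

#' @export
print.dive_obs <- function(x, ...) {
  cat(sprintf(
    "dive_obs: %d records (%d dives) in %.2g s intervals, %d candidate cues\n",
    nrow(x$records), sum(x$records$dived), x$step, nrow(x$cues)))
  invisible(x)
}

#' Social state of each observation record
#'
#' A record is social under `params` iff at least one candidate cue
#' satisfies `dt <= lag`, `dist < dist` (strictly) and
#' `bearing <= arc / 2`.
#'
#' @param obs A [discretize_dives()] result.
#' @param params A [dive_params()] (only `lag`, `dist`, `arc` are used).
#' @return Logical vector, one element per record.
#' @export
is_social <- function(obs, params) {
  stopifnot(inherits(obs, "dive_obs"))
  social_labels_cpp(nrow(obs$records), obs$cues$record, obs$cues$dt,
                    obs$cues$dist, obs$cues$bearing,
                    params$lag, params$dist, params$arc / 2)
}

# k * log(q) with the 0 * log(0) = 0 convention.
ll_term <- function(k, logq) if (k == 0) 0 else k * logq

# Bernoulli log-likelihood from the sufficient counts.
counts_ll <- function(n1, n1d, n_rec, n_dived, p0, p1, step) {
  q0 <- step_prob(p0, step); q1 <- step_prob(p1, step)
  n0 <- n_rec - n1; n0d <- n_dived - n1d
  ll_term(n1d, log(q1)) + ll_term(n1 - n1d, log1p(-q1)) +
    ll_term(n0d, log(q0)) + ll_term(n0 - n0d, log1p(-q0))
}

#' Log-likelihood of the two-rate dive model
#'
#' Sum over records of the Bernoulli log mass with per-interval probability
#' `1 - (1 - p)^step`, where `p` is `p1` for social records and `p0`
#' otherwise. The `noangle` variant evaluates the social state with the arc
#' fixed at 360 degrees; the `null` variant uses `p0` for every record.
#'
#' @param obs A [discretize_dives()] result.
#' @param params A [dive_params()].
#' @param variant `"full"`, `"noangle"` or `"null"`.
#' @return Scalar log-likelihood (may be `-Inf` at degenerate rates).
#' @export
log_likelihood <- function(obs, params, variant = c("full", "noangle",
                                                    "null")) {
  variant <- match.arg(variant)
  stopifnot(inherits(obs, "dive_obs"))
  n_rec <- nrow(obs$records)
  n_dived <- sum(obs$records$dived)
  if (variant == "null")
    return(counts_ll(0, 0, n_rec, n_dived, params$p0, params$p1, obs$step))
  half_arc <- if (variant == "noangle") 180 else params$arc / 2
  cnt <- social_counts_cpp(n_rec, obs$cues$record, obs$cues$dt,
                           obs$cues$dist, obs$cues$bearing,
                           obs$records$dived, params$lag, params$dist,
                           half_arc)
  counts_ll(cnt[1], cnt[2], n_rec, n_dived, params$p0, params$p1, obs$step)
}
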