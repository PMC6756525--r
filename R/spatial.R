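#' Focal-frame grid specification
#'
#' A square grid centred on the focal bird, rotated so the focal's heading
#' points to "front" (+y). `extent` is the half-width; offsets with
#' `|x|` or `|y| >= extent` fall outside the grid.
#'
#' @param extent Half-width in body lengths.
#' @param cell Cell size in body lengths; must divide `extent`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(extent = 40, cell = 2) {
  stopifnot(cell > 0, extent > 0)
  if (abs(extent / cell - round(extent / cell)) > 1e-9)
    stop("extent must be a whole number of cells")
  n <- as.integer(2 * round(extent / cell))
  structure(list(extent = extent, cell = cell, n = n,
                 centers = -extent + (seq_len(n) - 0.5) * cell),
            class = "grid_spec")
}

new_heatmap <- function(values, kind, grid, norm_max = NA_real_) {
  structure(list(values = values, kind = kind, grid = grid,
                 norm_max = norm_max),
            class = "raft_heatmap")
}

#' @export
print.raft_heatmap <- function(x, ...) {
  cat(sprintf("raft_heatmap (%s): %dx%d cells of %g BL, extent %g BL",
              x$kind, x$grid$n, x$grid$n, x$grid$cell, x$grid$extent))
  if (!is.na(x$norm_max)) cat(sprintf(", max count %g", x$norm_max))
  cat("\n")
  invisible(x)
}

# Rotate offsets into the focal frame: heading maps to +y ("front").
rotate_to_focal <- function(dx, dy, heading_deg) {
  th <- (90 - heading_deg) * pi / 180
  list(x = dx * cos(th) - dy * sin(th),
       y = dx * sin(th) + dy * cos(th))
}

# Flat cell index (or NA outside the grid) for focal-frame offsets.
grid_index <- function(grid, x, y) {
  ix <- floor((x + grid$extent) / grid$cell) + 1
  iy <- floor((y + grid$extent) / grid$cell) + 1
  ok <- ix >= 1 & ix <= grid$n & iy >= 1 & iy <= grid$n
  ifelse(ok, (iy - 1) * grid$n + ix, NA_integer_)
}

# Interpolated per-bird states of one raft on a time grid: positions and
# segment headings; NA while the bird is off the surface.
states_on_grid <- function(tracks_raft, times) {
  birds <- split(tracks_raft, tracks_raft$bird_id)
  nb <- length(birds)
  nt <- length(times)
  PX <- PY <- PH <- matrix(NA_real_, nt, nb)
  for (i in seq_len(nb)) {
    b <- birds[[i]]
    if (nrow(b) < 2) next
    inside <- times >= b$time_s[1] & times <= b$time_s[nrow(b)]
    if (!any(inside)) next
    ts <- times[inside]
    PX[inside, i] <- stats::approx(b$time_s, b$x_bl, xout = ts)$y
    PY[inside, i] <- stats::approx(b$time_s, b$y_bl, xout = ts)$y
    seg <- pmin(pmax(findInterval(ts, b$time_s), 1L), nrow(b) - 1L)
    PH[inside, i] <- atan2(b$y_bl[seg + 1L] - b$y_bl[seg],
                           b$x_bl[seg + 1L] - b$x_bl[seg]) * 180 / pi
  }
  list(x = PX, y = PY, h = PH,
       bird_id = as.numeric(names(birds)))
}

#' Relative neighbour density around the focal bird
#'
#' Every (focal, neighbour, timestep) offset is rotated into the focal
#' frame (heading = front = +y), binned on the grid, and the counts
#' normalized so the highest density is 1.
#'
#' @param dataset A [raft_dataset()].
#' @param grid A [grid_spec()].
#' @param step Sampling interval along the trajectories, seconds.
#' @return A `raft_heatmap` of kind `"normalized-density"`; `norm_max`
#'   holds the raw maximum count.
#' @export
relative_neighbour_density <- function(dataset, grid = grid_spec(),
                                       step = 0.5) {
  counts <- numeric(grid$n^2)
  for (rid in unique(dataset$tracks$raft_id)) {
    tr <- dataset$tracks[dataset$tracks$raft_id == rid, ]
    duration <- max(tr$time_s)
    st <- states_on_grid(tr, seq(0, duration, by = step))
    for (k in seq_len(nrow(st$x))) {
      a <- which(!is.na(st$x[k, ]))
      m <- length(a)
      if (m < 2) next
      dx <- matrix(st$x[k, a], m, m, byrow = TRUE) - st$x[k, a]
      dy <- matrix(st$y[k, a], m, m, byrow = TRUE) - st$y[k, a]
      off <- rotate_to_focal(dx, dy, st$h[k, a])
      keep <- row(dx) != col(dx)
      idx <- grid_index(grid, off$x[keep], off$y[keep])
      idx <- idx[!is.na(idx)]
      if (length(idx)) counts <- counts + tabulate(idx, grid$n^2)
    }
  }
  mx <- max(counts)
  vals <- matrix(if (mx > 0) counts / mx else counts, grid$n, grid$n)
  new_heatmap(vals, "normalized-density", grid, norm_max = mx)
}

#' Relative heading field around the focal bird
#'
#' Per focal-frame cell, the circular mean and the circular variance
#' (1 minus the mean resultant length) of the neighbour-minus-focal
#' heading differences. Cells with no observations are `NA`.
#'
#' @inheritParams relative_neighbour_density
#' @return List of two `raft_heatmap`s: `mean_heading` (degrees) and
#'   `circular_variance` (0 = perfectly aligned, 1 = no mean direction).
#' @export
relative_heading_field <- function(dataset, grid = grid_spec(),
                                   step = 0.5) {
  n2 <- grid$n^2
  sc <- ss <- cnt <- numeric(n2)
  for (rid in unique(dataset$tracks$raft_id)) {
    tr <- dataset$tracks[dataset$tracks$raft_id == rid, ]
    st <- states_on_grid(tr, seq(0, max(tr$time_s), by = step))
    for (k in seq_len(nrow(st$x))) {
      a <- which(!is.na(st$x[k, ]))
      m <- length(a)
      if (m < 2) next
      dx <- matrix(st$x[k, a], m, m, byrow = TRUE) - st$x[k, a]
      dy <- matrix(st$y[k, a], m, m, byrow = TRUE) - st$y[k, a]
      relh <- (matrix(st$h[k, a], m, m, byrow = TRUE) - st$h[k, a]) *
        pi / 180
      off <- rotate_to_focal(dx, dy, st$h[k, a])
      keep <- which(row(dx) != col(dx))
      idx <- grid_index(grid, off$x[keep], off$y[keep])
      ok <- !is.na(idx)
      if (!any(ok)) next
      idx <- idx[ok]; rh <- relh[keep][ok]
      sc <- sc + tabulate_sum(cos(rh), idx, n2)
      ss <- ss + tabulate_sum(sin(rh), idx, n2)
      cnt <- cnt + tabulate(idx, n2)
    }
  }
  mean_h <- ifelse(cnt > 0, atan2(ss, sc) * 180 / pi, NA_real_)
  rbar <- ifelse(cnt > 0, sqrt(sc^2 + ss^2) / cnt, NA_real_)
  list(mean_heading = new_heatmap(matrix(mean_h, grid$n, grid$n),
                                  "mean-heading", grid),
       circular_variance = new_heatmap(matrix(1 - rbar, grid$n, grid$n),
                                       "circular-variance", grid))
}

# Sum of w by integer group over a fixed number of bins.
tabulate_sum <- function(w, idx, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# (focal, conspecific-dive) pair table used by the dive-following
# statistics: one row per dive per focal bird surfaced at that moment.
follow_pairs <- function(dataset, window = 2) {
  parts <- list()
  for (rid in unique(dataset$tracks$raft_id)) {
    tr <- dataset$tracks[dataset$tracks$raft_id == rid, ]
    dv <- dataset$dives[dataset$dives$raft_id == rid, ]
    if (!nrow(dv)) next
    st <- states_on_grid(tr, dv$time_s)
    dive_times <- split(dv$time_s, dv$bird_id)
    for (i in seq_along(st$bird_id)) {
      bid <- st$bird_id[i]
      ok <- which(!is.na(st$x[, i]) & dv$bird_id != bid)
      if (!length(ok)) next
      dx <- dv$x_bl[ok] - st$x[ok, i]
      dy <- dv$y_bl[ok] - st$y[ok, i]
      off <- rotate_to_focal(dx, dy, st$h[ok, i])
      own <- dive_times[[as.character(bid)]]
      followed <- if (is.null(own)) rep(FALSE, length(ok)) else
        vapply(dv$time_s[ok], function(td)
          any(own > td & own <= td + window), TRUE)
      parts[[length(parts) + 1L]] <- data.frame(
        raft_id = rid, focal_id = bid, dive_time = dv$time_s[ok],
        x = off$x, y = off$y, followed = followed)
    }
  }
  if (!length(parts))
    return(data.frame(raft_id = numeric(0), focal_id = numeric(0),
                      dive_time = numeric(0), x = numeric(0),
                      y = numeric(0), followed = logical(0)))
  do.call(rbind, parts)
}

#' Dive density and fraction of dives followed, in the focal frame
#'
#' For every conspecific dive and every focal bird surfaced at that
#' moment, the dive's offset is rotated into the focal's frame and binned.
#' The density map is the normalized count of such dives; the fraction map
#' is, per cell, the share of those dives after which the focal itself
#' dived within `window` seconds.
#'
#' @param dataset A [raft_dataset()].
#' @param grid A [grid_spec()].
#' @param window Following window in seconds (default 2).
#' @return List: `density` (`raft_heatmap`, normalized counts), `fraction`
#'   (`raft_heatmap`, `NA` in empty cells), and the underlying `pairs`
#'   table.
#' @export
fraction_followed <- function(dataset, grid = grid_spec(), window = 2) {
  pairs <- follow_pairs(dataset, window)
  n2 <- grid$n^2
  idx <- grid_index(grid, pairs$x, pairs$y)
  ok <- !is.na(idx)
  cnt <- tabulate(idx[ok], n2)
  fol <- tabulate_sum(as.numeric(pairs$followed[ok]), idx[ok], n2)
  mx <- max(cnt)
  dens <- new_heatmap(matrix(if (mx > 0) cnt / mx else cnt, grid$n, grid$n),
                      "normalized-density", grid, norm_max = mx)
  frac <- new_heatmap(matrix(ifelse(cnt > 0, fol / cnt, NA_real_),
                             grid$n, grid$n), "fraction", grid)
  list(density = dens, fraction = frac, pairs = pairs)
}

#' Front-vs-back bias of dive following
#'
#' Share of front-offset conspecific dives that were followed minus the
#' share of back-offset ones, among dives within `max_dist` body lengths
#' of the focal (by default the heatmap extent, so the statistic
#' summarizes the same region the fraction map shows; distant dives
#' carry no cue information and only dilute it).
#'
#' @param pairs The `pairs` table of [fraction_followed()] (or a
#'   `fraction_followed` result).
#' @param max_dist Offset radius in BL over which the bias is computed.
#' @return Scalar bias (positive = dives ahead are followed more often).
#' @export
follow_front_bias <- function(pairs, max_dist = 40) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pairs$pairs
  sel <- pairs$x^2 + pairs$y^2 <= max_dist^2
  front <- pairs$y > 0
  mean(pairs$followed[sel & front]) - mean(pairs$followed[sel & !front])
}

#' Randomization null for the dive-following statistics
#'
#' Dive times are randomly reassigned to members of the flock (within each
#' raft, each dive time goes to a random bird surfaced at that moment)
#' while every bird's position and orientation are preserved, and the
#' dive-following statistics are recomputed; repeated `n` times. The
#' returned maps pool the (focal, dive) pairs of all permutations. Because
#' every quantity that does not depend on the dive-to-bird assignment
#' (pair structure, focal states, following windows) is precomputed once,
#' each permutation costs only a few vectorized passes.
#'
#' @param dataset A [raft_dataset()].
#' @param grid A [grid_spec()].
#' @param n Number of permutations (default 1000).
#' @param window Following window in seconds.
#' @param seed Integer seed; the same seed gives an identical null.
#' @param bias_max_dist Offset radius for the per-permutation front bias
#'   (see [follow_front_bias()]).
#' @return List: `fraction` (pooled null fraction `raft_heatmap`),
#'   `density` (pooled normalized dive density), `front_bias` (numeric
#'   vector, one front-bias statistic per permutation), `n`.
#' @export
randomize_dive_times <- function(dataset, grid = grid_spec(), n = 1000,
                                 window = 2, seed = 1L,
                                 bias_max_dist = grid$extent) {
  stopifnot(nrow(dataset$dives) >= 2)
  set.seed(seed)
  rafts <- unique(dataset$tracks$raft_id)
  pre <- list()
  for (rid in rafts) {
    tr <- dataset$tracks[dataset$tracks$raft_id == rid, ]
    dv <- dataset$dives[dataset$dives$raft_id == rid, ]
    if (!nrow(dv)) next
    st <- states_on_grid(tr, dv$time_s)
    alive <- !is.na(st$x)                       # nd x nb
    pr <- which(alive, arr.ind = TRUE)          # (dive, focal column)
    pd <- pr[, 1]; pi_ <- pr[, 2]
    # dives inside each dive's following window (fixed across permutations)
    wlist <- lapply(dv$time_s, function(td)
      which(dv$time_s > td & dv$time_s <= td + window))
    wlen <- lengths(wlist)[pd]
    trip_pair <- rep(seq_along(pd), wlen)
    trip_e <- unlist(wlist[pd], use.names = FALSE)
    pre[[length(pre) + 1L]] <- list(
      st = st, nd = nrow(dv), npair = length(pd), pd = pd, pi = pi_,
      fx = st$x[pr], fy = st$y[pr], fh = st$h[pr],
      cand = apply(alive, 1, which, simplify = FALSE),
      trip_pair = trip_pair, trip_e = trip_e,
      trip_focal = pi_[trip_pair])
  }
  n2 <- grid$n^2
  cnt <- fol_acc <- numeric(n2)
  bias <- numeric(n)
  b2 <- bias_max_dist^2
  for (p in seq_len(n)) {
    fr_fol <- fr_cnt <- bk_fol <- bk_cnt <- 0
    for (r in pre) {
      owner <- vapply(r$cand, function(v)
        if (length(v) == 1L) v else sample(v, 1L), 0L)
      keep <- owner[r$pd] != r$pi
      dx <- r$st$x[cbind(r$pd, owner[r$pd])] - r$fx
      dy <- r$st$y[cbind(r$pd, owner[r$pd])] - r$fy
      followed <- tabulate(r$trip_pair[owner[r$trip_e] == r$trip_focal],
                           r$npair) > 0
      off <- rotate_to_focal(dx[keep], dy[keep], r$fh[keep])
      fl <- followed[keep]
      idx <- grid_index(grid, off$x, off$y)
      ok <- !is.na(idx)
      if (any(ok)) {
        cnt <- cnt + tabulate(idx[ok], n2)
        fol_acc <- fol_acc + tabulate_sum(as.numeric(fl[ok]), idx[ok], n2)
      }
      near <- off$x^2 + off$y^2 <= b2
      fr <- near & off$y > 0
      bk <- near & off$y < 0
      fr_fol <- fr_fol + sum(fl[fr]); fr_cnt <- fr_cnt + sum(fr)
      bk_fol <- bk_fol + sum(fl[bk]); bk_cnt <- bk_cnt + sum(bk)
    }
    bias[p] <- (if (fr_cnt) fr_fol / fr_cnt else NA) -
      (if (bk_cnt) bk_fol / bk_cnt else NA)
  }
  mx <- max(cnt)
  list(fraction = new_heatmap(matrix(ifelse(cnt > 0, fol_acc / cnt,
                                            NA_real_),
                                     grid$n, grid$n), "fraction", grid),
       density = new_heatmap(matrix(if (mx > 0) cnt / mx else cnt,
                                    grid$n, grid$n),
                             "normalized-density", grid, norm_max = mx),
       front_bias = bias, n = n)
}

#' Wave diagnostic: timing of dives against along-heading distance
#'
#' For each ordered pair of dives in a raft (focal first, the other within
#' `window` seconds after it), emits the time difference and the signed
#' along-heading offset of the other dive in the focal's frame. If dive
#' waves were sweeping through the raft as it passed over prey, later
#' dives would concentrate behind focal dives (equivalently: dives ahead
#' of a focal happen earlier). Socially triggered diving produces no such
#' concentration beyond the short cue lag, so the score is computed from
#' pairs separated by more than `lag_exclude` seconds.
#'
#' @param dataset A [raft_dataset()].
#' @param window Maximum time difference, seconds.
#' @param lag_exclude Pairs closer in time than this are excluded from the
#'   score (they carry the social-following signal).
#' @return List: `pairs` (data.frame `dt`, `along`), `quadrants` (counts
#'   front/behind for near/far pairs), and `score` = (behind - front) /
#'   (behind + front) among far pairs — near 0 without waves, strongly
#'   positive with them.
#' @export
wave_diagnostic <- function(dataset, window = 30, lag_exclude = 2) {
  stopifnot(nrow(dataset$dives) >= 2)
  parts <- list()
  for (rid in unique(dataset$dives$raft_id)) {
    dv <- dataset$dives[dataset$dives$raft_id == rid, ]
    nd <- nrow(dv)
    if (nd < 2) next
    fi <- rep(seq_len(nd), times = nd)
    oi <- rep(seq_len(nd), each = nd)
    dt <- dv$time_s[oi] - dv$time_s[fi]
    keep <- dt > 0 & dt <= window
    fi <- fi[keep]; oi <- oi[keep]; dt <- dt[keep]
    if (!length(fi)) next
    hf <- dv$heading_deg[fi] * pi / 180
    along <- (dv$x_bl[oi] - dv$x_bl[fi]) * cos(hf) +
      (dv$y_bl[oi] - dv$y_bl[fi]) * sin(hf)
    parts[[length(parts) + 1L]] <- data.frame(dt = dt, along = along)
  }
  pairs <- if (length(parts)) do.call(rbind, parts) else
    data.frame(dt = numeric(0), along = numeric(0))
  far <- pairs$dt > lag_exclude
  quad <- c(front_near = sum(!far & pairs$along > 0),
            behind_near = sum(!far & pairs$along < 0),
            front_far = sum(far & pairs$along > 0),
            behind_far = sum(far & pairs$along < 0))
  tot <- quad["front_far"] + quad["behind_far"]
  score <- if (tot > 0)
    unname((quad["behind_far"] - quad["front_far"]) / tot) else NA_real_
  list(pairs = pairs, quadrants = quad, score = score)
}

#' Summary statistics of a raft dataset
#'
#' Pooled nearest-neighbour distances (per bird per timestep), pooled
#' per-step speeds, inter-dive intervals and relative-heading spread, plus
#' the implied social transmission speed when dive-model parameters are
#' supplied.
#'
#' @param dataset A [raft_dataset()].
#' @param step Sampling interval for the NND series, seconds.
#' @param params Optional [dive_params()] (or fitted summary values) for
#'   the transmission speed `dist / lag`.
#' @return List with `nnd_mean`, `nnd_sd`, `speed_mean`, `speed_sd`,
#'   `dive_intervals`, `rel_headings` (pooled pairwise heading differences
#'   at the sampled timesteps, degrees), `n_dives`, and
#'   `transmission_speed` (BL/s, `NA` without `params`).
#' @export
summary_stats <- function(dataset, step = 0.5, params = NULL) {
  stopifnot(nrow(dataset$tracks) > 0)
  nnd <- list(); relh <- list(); speeds <- list()
  for (rid in unique(dataset$tracks$raft_id)) {
    tr <- dataset$tracks[dataset$tracks$raft_id == rid, ]
    st <- states_on_grid(tr, seq(0, max(tr$time_s), by = step))
    for (k in seq_len(nrow(st$x))) {
      a <- which(!is.na(st$x[k, ]))
      m <- length(a)
      if (m >= 2) {
        d2 <- outer(st$x[k, a], st$x[k, a], `-`)^2 +
          outer(st$y[k, a], st$y[k, a], `-`)^2
        diag(d2) <- Inf
        nnd[[length(nnd) + 1L]] <- sqrt(apply(d2, 1, min))
        dh <- abs(wrap_angle(outer(st$h[k, a], st$h[k, a], `-`)))
        relh[[length(relh) + 1L]] <- dh[upper.tri(dh)]
      }
    }
    for (b in split(tr, tr$bird_id)) {
      if (nrow(b) < 2) next
      speeds[[length(speeds) + 1L]] <-
        sqrt(diff(b$x_bl)^2 + diff(b$y_bl)^2) / diff(b$time_s)
    }
  }
  nnd <- unlist(nnd); speeds <- unlist(speeds)
  iv <- unlist(lapply(split(dataset$dives$time_s, dataset$dives$raft_id),
                      function(t) diff(sort(t))), use.names = FALSE)
  list(nnd_mean = mean(nnd), nnd_sd = stats::sd(nnd),
       speed_mean = mean(speeds), speed_sd = stats::sd(speeds),
       dive_intervals = iv %||% numeric(0),
       rel_headings = unlist(relh) %||% numeric(0),
       n_dives = nrow(dataset$dives),
       transmission_speed = if (is.null(params)) NA_real_ else
         transmission_speed(params$dist, params$lag))
}

#' Social transmission speed implied by the interaction zone
#'
#' The ratio of the detection distance to the lag window: how fast a dive
#' cue can propagate across the raft.
#'
#' @param dist Detection distance, BL.
#' @param lag Lag window, s.
#' @return BL per second.
#' @export
transmission_speed <- function(dist, lag) dist / lag

#' Write a heatmap as a delimited matrix with a JSON sidecar
#'
#' @param hm A `raft_heatmap`.
#' @param file Output path for the matrix (tab-separated); the sidecar is
#'   written next to it as `<file>.json`.
#' @return Invisibly, `file`.
#' @export
write_heatmap <- function(hm, file) {
  utils::write.table(hm$values, file, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(kind = hm$kind, extent = hm$grid$extent, cell = hm$grid$cell,
         n = hm$grid$n, norm_max = hm$norm_max,
         orientation = "columns = front axis (+y last column)"),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
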