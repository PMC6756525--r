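#' Temporal frame averaging
#'
#' Pixel-wise mean over a centred window of preceding and successive
#' frames, truncated at the ends of the stack. Averaging suppresses water
#' flicker (specks lasting a frame or two) while leaving the slowly moving
#' birds nearly untouched.
#'
#' @param frames A `frame_stack` or plain list of matrices.
#' @param window Window length in frames (default 6; typical useful range
#'   4–9). A window of `w` covers `floor(w/2)` preceding and
#'   `ceiling(w/2) - 1` successive frames around each frame.
#' @return The same type as the input, with averaged frames.
#' @export
average_frames <- function(frames, window = 6) {
  stack <- NULL
  if (inherits(frames, "frame_stack")) { stack <- frames; frames <- frames$frames }
  if (window < 1) stop("window must be at least 1")
  n <- length(frames)
  lo <- pmax(1, seq_len(n) - floor(window / 2))
  hi <- pmin(n, seq_len(n) + ceiling(window / 2) - 1)
  out <- vector("list", n)
  cur <- Reduce(`+`, frames[lo[1]:hi[1]])
  out[[1]] <- cur / (hi[1] - lo[1] + 1)
  for (k in seq_len(n - 1) + 1) {
    if (hi[k] > hi[k - 1])
      for (j in (hi[k - 1] + 1):hi[k]) cur <- cur + frames[[j]]
    if (lo[k] > lo[k - 1])
      for (j in lo[k - 1]:(lo[k] - 1)) cur <- cur - frames[[j]]
    out[[k]] <- cur / (hi[k] - lo[k] + 1)
  }
  if (!is.null(stack)) { stack$frames <- out; stack } else out
}

#' Detect bird-sized blobs in a grayscale frame
#'
#' Thresholds the frame, labels connected components and keeps those whose
#' pixel area lies within `area_bounds` (shapes too small or too large to
#' be birds are discarded). Centroids are intensity-free (binary) moments
#' in 0-based pixel coordinates; the major-axis length (ellipse-equivalent
#' diameter, `4 * sqrt(largest second moment)`) is retained for estimating
#' the body-length scale.
#'
#' @param frame Numeric matrix in \[0, 1\].
#' @param threshold Intensity threshold.
#' @param area_bounds Length-2 inclusive pixel-area bounds.
#' @return data.frame with columns `x`, `y` (0-based pixels), `area`,
#'   `major_px`; zero rows when nothing qualifies.
#' @export
detect_blobs <- function(frame, threshold = 0.5, area_bounds = c(8, 60)) {
  empty <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      major_px = numeric(0))
  bw <- frame > threshold
  if (!any(bw)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  idx <- which(lab > 0)
  l <- lab[idx]
  H <- nrow(frame)
  rows <- ((idx - 1) %% H)           # 0-based pixel y
  cols <- ((idx - 1) %/% H)          # 0-based pixel x
  area <- tabulate(l)
  sums <- rowsum(cbind(cols, rows, cols^2, rows^2, cols * rows), l)
  cx <- sums[, 1] / area; cy <- sums[, 2] / area
  vxx <- sums[, 3] / area - cx^2
  vyy <- sums[, 4] / area - cy^2
  vxy <- sums[, 5] / area - cx * cy
  tr2 <- (vxx + vyy) / 2
  det_off <- sqrt(pmax(0, ((vxx - vyy) / 2)^2 + vxy^2))
  major <- 4 * sqrt(pmax(tr2 + det_off, 0.05))
  keep <- area >= area_bounds[1] & area <= area_bounds[2]
  data.frame(x = cx[keep], y = cy[keep], area = area[keep],
             major_px = major[keep])
}

#' Correct detections for perspective distortion
#'
#' Back-projects pixel centroids onto the sea-surface plane, removing the
#' perspective distortion of the oblique view.
#'
#' @param detections data.frame with pixel columns `x`, `y` (0-based).
#' @param camera A [camera_model()].
#' @return The input with ground columns `x_m`, `y_m` (metres) appended.
#' @export
correct_coordinates <- function(detections, camera) {
  if (!nrow(detections)) {
    detections$x_m <- numeric(0); detections$y_m <- numeric(0)
    return(detections)
  }
  g <- pixel_to_ground(camera, cbind(detections$x, detections$y))
  detections$x_m <- g[, 1]
  detections$y_m <- g[, 2]
  detections
}

#' Estimate the body-length scale from detections
#'
#' Median over detections of the projected major-axis ground length. With
#' the renderer's default blob size (about one body length across) this
#' estimates the body length in metres; override it in the tracking config
#' whenever the true scale is known.
#'
#' @param detections data.frame with `x`, `y`, `major_px` columns.
#' @param camera A [camera_model()].
#' @return Scalar metres.
#' @export
estimate_body_length <- function(detections, camera) {
  stopifnot(nrow(detections) > 0)
  p1 <- pixel_to_ground(camera, cbind(detections$x - detections$major_px / 2,
                                      detections$y))
  p2 <- pixel_to_ground(camera, cbind(detections$x + detections$major_px / 2,
                                      detections$y))
  stats::median(sqrt(rowSums((p2 - p1)^2)))
}

# One Kalman (linear quadratic estimation) constant-velocity track.
kf_matrices <- function(dt, process_noise, obs_noise) {
  F <- diag(4); F[1, 3] <- dt; F[2, 4] <- dt
  G <- c(dt^2 / 2, dt)
  Qa <- process_noise^2 * outer(G, G)
  Q <- matrix(0, 4, 4)
  Q[c(1, 3), c(1, 3)] <- Qa; Q[c(2, 4), c(2, 4)] <- Qa
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  R <- diag(obs_noise^2, 2)
  list(F = F, Q = Q, H = H, R = R)
}

#' Link per-frame detections into trajectories
#'
#' Each open track carries a position+velocity state estimator (linear
#' quadratic estimation, i.e. a constant-velocity Kalman filter) in ground
#' coordinates. At every frame the predicted positions are matched to the
#' observed detections by the auction assignment minimizing total
#' prediction–observation distance, with pairings beyond `gate` forbidden.
#' Unmatched detections seed new tracks; a track unmatched for longer than
#' `gap_tolerance` seconds is closed (it keeps coasting on its prediction
#' in between, but only matched observations enter the trajectory).
#'
#' @param detections data.frame with columns `frame` (1-based), `x_m`,
#'   `y_m` and optionally `x`, `y` (pixels) and `area`, sorted by frame.
#' @param dt Frame interval in seconds.
#' @param gate Maximum prediction–observation distance (metres).
#' @param gap_tolerance Seconds a track may go unmatched before closing.
#' @param process_noise Kalman white-acceleration noise (m/s^2).
#' @param obs_noise Kalman observation noise (m).
#' @param n_frames Total frame count (defaults to the last detection's).
#' @return data.frame of track points: `track_id`, `frame`, `time_s`,
#'   `x_m`, `y_m`, `x_px`, `y_px`, `area`.
#' @export
link_detections <- function(detections, dt, gate = 2, gap_tolerance = 0.5,
                            process_noise = 0.5, obs_noise = 0.1,
                            n_frames = NULL) {
  km <- kf_matrices(dt, process_noise, obs_noise)
  max_miss <- max(0L, floor(gap_tolerance / dt))
  if (is.null(n_frames))
    n_frames <- if (nrow(detections)) max(detections$frame) else 0L
  if (!("x" %in% names(detections))) detections$x <- NA_real_
  if (!("y" %in% names(detections))) detections$y <- NA_real_
  if (!("area" %in% names(detections))) detections$area <- NA_real_

  tracks <- list()    # open tracks
  closed <- list()
  next_id <- 1L
  by_frame <- split(seq_len(nrow(detections)), detections$frame)

  for (k in seq_len(n_frames)) {
    # predict
    for (i in seq_along(tracks)) {
      tr <- tracks[[i]]
      tr$state <- as.numeric(km$F %*% tr$state)
      tr$P <- km$F %*% tr$P %*% t(km$F) + km$Q
      tracks[[i]] <- tr
    }
    di <- by_frame[[as.character(k)]]
    nt <- length(tracks); nd <- length(di)
    matched_t <- integer(0); matched_d <- integer(0)
    if (nt > 0 && nd > 0) {
      pred <- t(vapply(tracks, function(tr) tr$state[1:2], numeric(2)))
      obs <- cbind(detections$x_m[di], detections$y_m[di])
      C <- sqrt(outer(pred[, 1], obs[, 1], `-`)^2 +
                  outer(pred[, 2], obs[, 2], `-`)^2)
      C[C > gate] <- Inf
      n <- nt + nd
      A <- matrix(Inf, n, n)
      A[seq_len(nt), seq_len(nd)] <- C
      A[seq_len(nt), nd + seq_len(nt)] <- gate          # track goes unmatched
      A[nt + seq_len(nd), seq_len(nd)] <- gate          # detection unmatched
      A[nt + seq_len(nd), nd + seq_len(nt)] <- 0
      asg <- auction_assignment(A)
      for (i in seq_len(nt)) {
        j <- asg[i]
        if (j <= nd && is.finite(C[i, j])) {
          matched_t <- c(matched_t, i); matched_d <- c(matched_d, j)
        }
      }
    } else if (nt > 0 && nd == 0) {
      # nothing to match
    }
    # update matched tracks
    for (m in seq_along(matched_t)) {
      i <- matched_t[m]; j <- matched_d[m]; row <- di[j]
      tr <- tracks[[i]]
      z <- c(detections$x_m[row], detections$y_m[row])
      S <- km$H %*% tr$P %*% t(km$H) + km$R
      K <- tr$P %*% t(km$H) %*% solve(S)
      tr$state <- as.numeric(tr$state + K %*% (z - km$H %*% tr$state))
      tr$P <- (diag(4) - K %*% km$H) %*% tr$P
      tr$missed <- 0L
      tr$frame <- c(tr$frame, k)
      tr$x_m <- c(tr$x_m, z[1]); tr$y_m <- c(tr$y_m, z[2])
      tr$x_px <- c(tr$x_px, detections$x[row])
      tr$y_px <- c(tr$y_px, detections$y[row])
      tr$area <- c(tr$area, detections$area[row])
      tracks[[i]] <- tr
    }
    # close stale tracks
    if (nt > 0) {
      un <- setdiff(seq_len(nt), matched_t)
      for (i in un) tracks[[i]]$missed <- tracks[[i]]$missed + 1L
      stale <- vapply(tracks, function(tr) tr$missed > max_miss, TRUE)
      closed <- c(closed, tracks[stale])
      tracks <- tracks[!stale]
    }
    # new tracks from unmatched detections
    new_d <- setdiff(seq_len(nd), matched_d)
    for (j in new_d) {
      row <- di[j]
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id,
        state = c(detections$x_m[row], detections$y_m[row], 0, 0),
        P = diag(c(obs_noise^2, obs_noise^2, 1, 1)),
        missed = 0L, frame = k,
        x_m = detections$x_m[row], y_m = detections$y_m[row],
        x_px = detections$x[row], y_px = detections$y[row],
        area = detections$area[row])
      next_id <- next_id + 1L
    }
  }
  closed <- c(closed, tracks)
  if (!length(closed))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      time_s = numeric(0), x_m = numeric(0),
                      y_m = numeric(0), x_px = numeric(0),
                      y_px = numeric(0), area = numeric(0)))
  out <- do.call(rbind, lapply(closed, function(tr) {
    data.frame(track_id = tr$id, frame = tr$frame,
               time_s = (tr$frame - 1) * dt, x_m = tr$x_m, y_m = tr$y_m,
               x_px = tr$x_px, y_px = tr$y_px, area = tr$area)
  }))
  out[order(out$track_id, out$frame), ]
}

# mean path speed of one track (length units per second); single-fix
# tracks have zero speed by convention.
track_mean_speed <- function(t, x, y) {
  if (length(t) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2)) / (t[length(t)] - t[1])
}

#' Remove trajectories with implausible speeds
#'
#' Tracks whose mean speed falls outside `[vmin, vmax]` body lengths per
#' second are discarded (birds do not swim that slowly or that fast; such
#' tracks are flotsam, glints or linking errors).
#'
#' @param track_df A [link_detections()] result.
#' @param bl_m Body length in metres.
#' @param vmin,vmax Speed bounds, BL/s.
#' @return The filtered track data.frame.
#' @export
filter_speed_outliers <- function(track_df, bl_m, vmin = 0.2, vmax = 2.5) {
  if (!nrow(track_df)) return(track_df)
  sp <- vapply(split(track_df, track_df$track_id), function(tr)
    track_mean_speed(tr$time_s, tr$x_m, tr$y_m), 0) / bl_m
  keep_ids <- as.numeric(names(sp)[sp >= vmin & sp <= vmax])
  track_df[track_df$track_id %in% keep_ids, ]
}

#' Detect dives from track endings
#'
#' A track ending inside the frame's bounding box (shrunk by `margin`
#' pixels — tracks ending at the edge simply left the view) is labelled a
#' dive iff its final `window` seconds of blob area show the splash
#' signature: a rise of at least `rise_frac` over the pre-window baseline
#' followed by a rapid decrease — either the observed area falls by at
#' least `fall_frac` from the peak, or the blob vanishes (the track ends)
#' within `vanish_gap` seconds of the peak, since a shrinking splash drops
#' below the detection floor before its full decline can be observed. Optionally a
#' sudden heading/velocity change in the final window can also qualify
#' (`use_kinematics`); that secondary criterion is off by default. The dive
#' time is the trajectory end and the dive heading the last displacement
#' direction.
#'
#' @param track_df A [link_detections()] result with pixel positions and
#'   areas.
#' @param frame_size `c(width, height)` in pixels.
#' @param margin Bounding-box margin in pixels.
#' @param window Seconds of area history inspected before the track end.
#' @param rise_frac,fall_frac Relative area rise/fall thresholds.
#' @param vanish_gap Seconds after the area peak within which a track end
#'   counts as the rapid decrease.
#' @param use_kinematics Enable the heading/velocity-change criterion.
#' @param turn_thresh Degrees of per-step heading change that counts as
#'   sudden (with `use_kinematics`).
#' @return data.frame of dives: `track_id`, `time_s`, `x_m`, `y_m`,
#'   `heading_deg`.
#' @export
detect_dives <- function(track_df, frame_size, margin = 10, window = 2,
                         rise_frac = 0.30, fall_frac = 0.60,
                         vanish_gap = 0.6, use_kinematics = FALSE,
                         turn_thresh = 120) {
  out <- list()
  for (tr in split(track_df, track_df$track_id)) {
    n <- nrow(tr)
    if (n < 3) next
    endx <- tr$x_px[n]; endy <- tr$y_px[n]
    if (is.na(endx) ||
        endx < margin || endx > frame_size[1] - 1 - margin ||
        endy < margin || endy > frame_size[2] - 1 - margin) next
    t_end <- tr$time_s[n]
    in_win <- tr$time_s > t_end - window
    pre <- tr$area[!in_win]
    a <- tr$area[in_win]
    baseline <- if (length(pre)) stats::median(utils::tail(pre, 25)) else
      stats::median(a[seq_len(max(1, floor(length(a) / 2)))])
    pk <- which.max(a)
    t_win <- tr$time_s[in_win]
    fell <- (length(a) > pk &&
               min(a[(pk + 1):length(a)]) <= (1 - fall_frac) * a[pk]) ||
      (t_end - t_win[pk]) <= vanish_gap
    splash <- a[pk] >= (1 + rise_frac) * baseline && fell
    kin <- FALSE
    if (use_kinematics && sum(in_win) >= 3) {
      xw <- tr$x_m[in_win]; yw <- tr$y_m[in_win]
      hw <- atan2(diff(yw), diff(xw)) * 180 / pi
      kin <- any(abs(wrap_angle(diff(hw))) > turn_thresh)
    }
    if (isTRUE(splash) || kin) {
      hd <- atan2(tr$y_m[n] - tr$y_m[n - 1], tr$x_m[n] - tr$x_m[n - 1]) *
        180 / pi
      out[[length(out) + 1L]] <- data.frame(
        track_id = tr$track_id[1], time_s = t_end, x_m = tr$x_m[n],
        y_m = tr$y_m[n], heading_deg = hd)
    }
  }
  if (!length(out))
    return(data.frame(track_id = integer(0), time_s = numeric(0),
                      x_m = numeric(0), y_m = numeric(0),
                      heading_deg = numeric(0)))
  do.call(rbind, out)
}

#' Track a rendered frame stack end to end
#'
#' Frame averaging, blob detection, perspective correction, Kalman/auction
#' linking, speed filtering and dive detection in one call.
#'
#' @param stack A `frame_stack` (with its camera), or a list of matrices
#'   plus an explicit `camera`.
#' @param camera A [camera_model()]; defaults to the stack's.
#' @param window,threshold,area_bounds,gate,gap_tolerance,margin Stage
#'   parameters (see the stage functions).
#' @param bl_m Body length in metres; `NULL` estimates it from the blob
#'   major axes via [estimate_body_length()].
#' @param vmin,vmax Speed filter bounds, BL/s.
#' @param ... Passed to [detect_dives()].
#' @return List: `dataset` (a [raft_dataset()] in BL units relative to the
#'   camera foot point), `tracks` (the raw track table in metres),
#'   `dives`, `bl_m`, and per-stage `counts`.
#' @export
track_frames <- function(stack, camera = NULL, window = 6, threshold = 0.5,
                         area_bounds = c(8, 60), gate = 2,
                         gap_tolerance = 0.5, margin = 10, bl_m = NULL,
                         vmin = 0.2, vmax = 2.5, ...) {
  if (inherits(stack, "frame_stack")) {
    camera <- camera %||% stack$camera
    frames <- stack$frames
  } else frames <- stack
  stopifnot(inherits(camera, "camera_model"))
  dt <- 1 / camera$fps
  # streaming frame averaging + detection (one averaged frame in memory)
  n <- length(frames)
  lo <- pmax(1, seq_len(n) - floor(window / 2))
  hi <- pmin(n, seq_len(n) + ceiling(window / 2) - 1)
  cur <- Reduce(`+`, frames[lo[1]:hi[1]])
  det_parts <- vector("list", n)
  for (k in seq_len(n)) {
    if (k > 1) {
      if (hi[k] > hi[k - 1])
        for (j in (hi[k - 1] + 1):hi[k]) cur <- cur + frames[[j]]
      if (lo[k] > lo[k - 1])
        for (j in lo[k - 1]:(lo[k] - 1)) cur <- cur - frames[[j]]
    }
    d <- detect_blobs(cur / (hi[k] - lo[k] + 1), threshold, area_bounds)
    if (nrow(d)) { d$frame <- k; det_parts[[k]] <- d }
  }
  det <- do.call(rbind, det_parts)
  if (is.null(det) || !nrow(det))
    stop("no detections above threshold; nothing to track")
  det <- correct_coordinates(det, camera)
  if (is.null(bl_m)) bl_m <- estimate_body_length(det, camera)
  tracks <- link_detections(det, dt = dt, gate = gate,
                            gap_tolerance = gap_tolerance,
                            n_frames = n)
  n_raw <- length(unique(tracks$track_id))
  tracks <- filter_speed_outliers(tracks, bl_m, vmin, vmax)
  dives <- detect_dives(tracks, frame_size = c(camera$width, camera$height),
                        margin = margin, ...)
  tr_bl <- data.frame(raft_id = 1, bird_id = tracks$track_id,
                      time_s = tracks$time_s, x_bl = tracks$x_m / bl_m,
                      y_bl = tracks$y_m / bl_m)
  dv_bl <- data.frame(raft_id = rep(1, nrow(dives)),
                      bird_id = dives$track_id, time_s = dives$time_s,
                      x_bl = dives$x_m / bl_m, y_bl = dives$y_m / bl_m,
                      heading_deg = dives$heading_deg)
  ds <- raft_dataset(tr_bl, dv_bl,
                     meta = list(duration = (n - 1) * dt,
                                 sim_step = dt, bl_m = bl_m,
                                 source = "tracking"))
  list(dataset = ds, tracks = tracks, dives = dives, bl_m = bl_m,
       counts = c(frames = n, detections = nrow(det),
                  tracks = n_raw,
                  tracks_kept = length(unique(tracks$track_id)),
                  dives = nrow(dives)))
}

#' Compare tracker output against simulated ground truth
#'
#' @param truth The simulated [raft_dataset()] that was rendered.
#' @param tracked A [track_frames()] result.
#' @param stack The rendered `frame_stack` (for the origin and scale).
#' @param pos_tol Position tolerance in BL for counting a true position as
#'   recovered.
#' @param dive_time_tol,dive_pos_tol Matching windows for dive events
#'   (seconds; BL). Detected dive times lag the true instant by the splash
#'   duration, so the window must cover it.
#' @return List: `position_recall` (fraction of true bird-frames with a
#'   tracked position within `pos_tol`), `dive_recall`, `dive_precision`,
#'   `n_true_positions`, `n_true_dives`, `n_detected_dives`.
#' @export
evaluate_tracking <- function(truth, tracked, stack, pos_tol = 1,
                              dive_time_tol = 2, dive_pos_tol = 3) {
  bl_m <- stack$bl_m; origin <- stack$origin
  tol_m <- pos_tol * bl_m
  times <- stack$times
  dt <- times[2] - times[1]
  tt <- tracked$tracks
  hits <- 0L; total <- 0L
  for (b in split(truth$tracks, truth$tracks$bird_id)) {
    if (nrow(b) < 2) next
    inside <- times >= b$time_s[1] & times <= b$time_s[nrow(b)]
    ts <- times[inside]
    gx <- origin[1] + bl_m * stats::approx(b$time_s, b$x_bl, xout = ts)$y
    gy <- origin[2] + bl_m * stats::approx(b$time_s, b$y_bl, xout = ts)$y
    fr <- round(ts / dt) + 1L
    for (i in seq_along(ts)) {
      cand <- tt[tt$frame == fr[i], ]
      total <- total + 1L
      if (nrow(cand) &&
          min((cand$x_m - gx[i])^2 + (cand$y_m - gy[i])^2) <= tol_m^2)
        hits <- hits + 1L
    }
  }
  tdv <- truth$dives
  ddv <- tracked$dives
  used <- rep(FALSE, nrow(ddv))
  matched <- 0L
  if (nrow(tdv) && nrow(ddv)) {
    gx <- origin[1] + bl_m * tdv$x_bl; gy <- origin[2] + bl_m * tdv$y_bl
    for (i in seq_len(nrow(tdv))) {
      ok <- !used & ddv$time_s >= tdv$time_s[i] - 0.2 &
        ddv$time_s <= tdv$time_s[i] + dive_time_tol &
        (ddv$x_m - gx[i])^2 + (ddv$y_m - gy[i])^2 <=
          (dive_pos_tol * bl_m)^2
      if (any(ok)) {
        used[which(ok)[1]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  list(position_recall = if (total) hits / total else NA_real_,
       dive_recall = if (nrow(tdv)) matched / nrow(tdv) else NA_real_,
       dive_precision = if (nrow(ddv)) matched / nrow(ddv) else NA_real_,
       n_true_positions = total, n_true_dives = nrow(tdv),
       n_detected_dives = nrow(ddv))
}
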