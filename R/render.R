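#' Render a raft dataset as a grayscale frame stack
#'
#' Each surfaced bird appears as one bright elliptical blob at its
#' perspective-projected pixel position, with the blob's pixel axes set by
#' the local lateral and range pixel scales (so blobs are foreshortened
#' exactly as the ground is). A dive is rendered as the slight splash a
#' dive produces: the blob swells briefly, then shrinks to nothing within
#' `splash$vanish` seconds of the dive instant, after which the bird never
#' reappears. Optional noise adds water flicker (bright specks) and
#' Gaussian pixel noise.
#'
#' @param dataset A [raft_dataset()] for a single raft.
#' @param camera A [camera_model()].
#' @param bl_m Body length in metres (ground scale of the dataset's BL
#'   units).
#' @param origin Length-2 ground offset (metres) mapping dataset
#'   coordinates to the world: `ground_m = origin + bl_m * (x_bl, y_bl)`.
#'   By default the dataset's bounding-box centre is anchored at pixel
#'   `(width/2, anchor * height)`.
#' @param anchor Vertical frame anchor (0 = top) used for the default
#'   origin; the default places the raft in the lower, better-resolved part
#'   of the view.
#' @param blob_radius_bl Blob semi-major axis on the ground, in BL; the
#'   default renders a blob about one body length across.
#' @param splash List: `swell` (peak area scale factor on the linear blob
#'   axes), `rise` (s to peak) and `vanish` (s from dive to disappearance,
#'   at most 2).
#' @param noise List: `flicker_density` (expected fraction of pixels
#'   flickering per frame), `flicker_amp` (speck brightness), `gaussian_sd`.
#' @param seed Seed for the noise draws.
#' @return An object of class `frame_stack`: list with `frames` (list of
#'   height x width matrices in \[0, 1\]), `times`, `camera`, `origin`,
#'   `bl_m`. Birds outside the frame are clipped with a warning.
#' @export
render_frames <- function(dataset, camera, bl_m = 0.75, origin = NULL,
                          anchor = 0.7, blob_radius_bl = 0.5,
                          splash = list(swell = 1.6, rise = 0.3,
                                        vanish = 0.8),
                          noise = list(flicker_density = 0,
                                       flicker_amp = 0, gaussian_sd = 0),
                          seed = 1L) {
  stopifnot(inherits(dataset, "raft_dataset"),
            inherits(camera, "camera_model"),
            length(unique(dataset$tracks$raft_id)) <= 1,
            splash$vanish <= 2, splash$rise < splash$vanish)
  set.seed(seed)
  W <- camera$width; H <- camera$height
  duration <- dataset$meta$duration %||% max(dataset$tracks$time_s)
  times <- seq(0, duration, by = 1 / camera$fps)

  if (is.null(origin)) {
    ctr <- c(mean(range(dataset$tracks$x_bl)),
             mean(range(dataset$tracks$y_bl)))
    gctr <- pixel_to_ground(camera, c((W - 1) / 2, anchor * (H - 1)))
    origin <- as.numeric(gctr) - bl_m * ctr
  }

  # per-bird interpolated positions at frame times (NA while off-surface)
  birds <- split(dataset$tracks, dataset$tracks$bird_id)
  ids <- names(birds)
  nb <- length(birds)
  PX <- PY <- matrix(NA_real_, length(times), nb)
  for (i in seq_len(nb)) {
    b <- birds[[i]]
    if (nrow(b) < 2) {
      k <- which.min(abs(times - b$time_s[1]))
      PX[k, i] <- b$x_bl; PY[k, i] <- b$y_bl
      next
    }
    inside <- times >= b$time_s[1] & times <= b$time_s[nrow(b)]
    PX[inside, i] <- stats::approx(b$time_s, b$x_bl, xout = times[inside])$y
    PY[inside, i] <- stats::approx(b$time_s, b$y_bl, xout = times[inside])$y
  }
  dv <- dataset$dives
  dive_time <- setNames(rep(NA_real_, nb), ids)
  dive_x <- dive_y <- dive_time
  if (nrow(dv)) {
    m <- match(as.character(dv$bird_id), ids)
    dive_time[m] <- dv$time_s; dive_x[m] <- dv$x_bl; dive_y[m] <- dv$y_bl
  }

  n_clipped <- 0L
  frames <- vector("list", length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    fr <- matrix(0, H, W)
    x <- PX[k, ]; y <- PY[k, ]
    scale <- rep(1, nb)
    splashing <- !is.na(dive_time) & t > dive_time &
      t <= dive_time + splash$vanish
    if (any(splashing)) {
      dt <- t - dive_time[splashing]
      s <- ifelse(dt <= splash$rise,
                  1 + (splash$swell - 1) * dt / splash$rise,
                  splash$swell *
                    (1 - (dt - splash$rise) / (splash$vanish - splash$rise)))
      scale[splashing] <- s
      x[splashing] <- dive_x[splashing]; y[splashing] <- dive_y[splashing]
    }
    act <- which(!is.na(x) & scale > 0.05)
    if (length(act)) {
      g <- cbind(origin[1] + bl_m * x[act], origin[2] + bl_m * y[act])
      uv <- ground_to_pixel(camera, g)
      d <- 0.05
      uvx <- ground_to_pixel(camera, cbind(g[, 1] + d, g[, 2]))
      uvy <- ground_to_pixel(camera, cbind(g[, 1], g[, 2] + d))
      ppm_x <- sqrt(rowSums((uvx - uv)^2)) / d   # lateral pixels per metre
      ppm_y <- sqrt(rowSums((uvy - uv)^2)) / d   # range pixels per metre
      rx <- pmax(1, blob_radius_bl * bl_m * ppm_x) * scale[act]
      ry <- pmax(1, blob_radius_bl * bl_m * ppm_y) * scale[act]
      for (a in seq_along(act)) {
        u <- uv[a, 1]; v <- uv[a, 2]
        if (is.na(u) || u < -rx[a] || u > W - 1 + rx[a] ||
            v < -ry[a] || v > H - 1 + ry[a]) {
          n_clipped <- n_clipped + 1L
          next
        }
        cl <- max(1, floor(u - rx[a])):min(W, ceiling(u + rx[a] + 2))
        rw <- max(1, floor(v - ry[a])):min(H, ceiling(v + ry[a] + 2))
        dd <- sqrt(outer(((rw - 1) - v)^2 / ry[a]^2,
                         ((cl - 1) - u)^2 / rx[a]^2, `+`))
        val <- pmin(1, pmax(0, (1 - dd) / 0.35))
        fr[rw, cl] <- pmax(fr[rw, cl], val)
      }
    }
    if (noise$flicker_density > 0 && noise$flicker_amp > 0) {
      ns <- stats::rbinom(1, W * H, noise$flicker_density)
      if (ns > 0) {
        at <- sample.int(W * H, ns)
        fr[at] <- pmax(fr[at], noise$flicker_amp * stats::runif(ns, 0.5, 1))
      }
    }
    if (noise$gaussian_sd > 0)
      fr <- pmin(1, pmax(0, fr + stats::rnorm(W * H, 0, noise$gaussian_sd)))
    frames[[k]] <- fr
  }
  if (n_clipped > 0)
    warning(n_clipped, " bird-frame(s) fell outside the camera footprint ",
            "and were clipped")
  structure(list(frames = frames, times = times, camera = camera,
                 origin = origin, bl_m = bl_m),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frames of %dx%d px, %.3g s at %g fps\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              max(x$times), x$camera$fps))
  invisible(x)
}

#' Write a frame stack as numbered PNG images
#'
#' @param stack A [render_frames()] result (or plain list of matrices).
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; frames are written as
#'   `<prefix>00001.png`, ...
#' @return Invisibly, the written paths.
#' @export
write_frames <- function(stack, dir, prefix = "frame_") {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s%05d.png", prefix, seq_along(frames)))
  for (i in seq_along(frames)) png::writePNG(frames[[i]], paths[i])
  invisible(paths)
}

#' Read numbered grayscale frames from a directory
#'
#' @param dir Directory of PNG frames.
#' @param pattern Filename regular expression.
#' @param fps Frame rate used to reconstruct frame times.
#' @return A `frame_stack` without camera metadata (attach via
#'   [track_frames()]'s `camera` argument).
#' @export
read_frames <- function(dir, pattern = "\\.png$", fps = 25) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no frames matching '", pattern, "' in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  structure(list(frames = frames, times = (seq_along(frames) - 1) / fps,
                 camera = NULL, origin = c(0, 0), bl_m = NA_real_),
            class = "frame_stack")
}
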