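#' Oblique overhead camera model
#'
#' A pinhole camera at height `elevation` above the sea surface, looking
#' along ground +y. `inclination` is the angle from the vertical to the
#' bottom edge of the field of view (the paper's convention for a tripod
#' camera on a cliff: the bottom edge is the closest visible water).
#' The optical-axis inclination is `inclination + vfov / 2`, and the
#' vertical field of view follows from the horizontal one and the aspect
#' ratio. Pixels are 0-based with the origin at the top-left; ground y
#' increases away from the camera, and `heading` rotates the ground frame
#' about the camera foot point.
#'
#' @param elevation Camera height above the water, metres.
#' @param inclination Degrees from vertical to the bottom edge of the view.
#' @param heading Camera heading, degrees (rotation of the ground frame).
#' @param fps Frame rate, Hz.
#' @param width,height Sensor resolution in pixels.
#' @param hfov Horizontal field of view, degrees. The default (a long-lens
#'   view) keeps the whole frame below the horizon at the default
#'   inclination.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(elevation = 31.6, inclination = 79.46, heading = 0,
                         fps = 25, width = 1920, height = 1080, hfov = 16) {
  stopifnot(elevation > 0, inclination > -90, inclination < 90,
            width > 0, height > 0, hfov > 0, hfov < 180, fps > 0)
  vfov <- 2 * atan(tan(hfov / 2 * pi / 180) * height / width) * 180 / pi
  if (inclination + vfov > 90)
    stop("the top edge of the view reaches the horizon (inclination + ",
         "vfov = ", round(inclination + vfov, 2),
         " deg); reduce inclination or hfov")
  structure(list(elevation = elevation, inclination = inclination,
                 heading = heading, fps = fps, width = as.integer(width),
                 height = as.integer(height), hfov = hfov, vfov = vfov,
                 axis = inclination + vfov / 2),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "camera_model: %dx%d px @ %g fps, %.4g m elevation, bottom-edge inclination %.4g deg, hfov %.4g deg (axis %.4g deg)\n",
    x$width, x$height, x$fps, x$elevation, x$inclination, x$hfov, x$axis))
  invisible(x)
}

# Orthonormal camera basis in world coordinates (x lateral, y away, z up):
# a = optical axis (down-forward), r = image right, u = image up.
camera_basis <- function(camera) {
  ax <- camera$axis * pi / 180
  list(a = c(0, sin(ax), -cos(ax)),
       r = c(1, 0, 0),
       u = c(0, cos(ax), sin(ax)))
}

rotate2 <- function(xy, deg) {
  th <- deg * pi / 180
  cbind(xy[, 1] * cos(th) - xy[, 2] * sin(th),
        xy[, 1] * sin(th) + xy[, 2] * cos(th))
}

#' Project ground points to pixel coordinates
#'
#' @param camera A [camera_model()].
#' @param xy Two-column matrix (or length-2 vector) of ground positions in
#'   metres, y away from the camera.
#' @return Two-column matrix of 0-based pixel coordinates (x right, y
#'   down); points behind the camera plane are `NA`.
#' @export
ground_to_pixel <- function(camera, xy) {
  xy <- rbind2mat(xy)
  if (camera$heading != 0) xy <- rotate2(xy, -camera$heading)
  b <- camera_basis(camera)
  p <- cbind(xy[, 1], xy[, 2], -camera$elevation)  # relative to the camera
  zc <- p %*% b$a
  xc <- p %*% b$r
  yc <- p %*% b$u
  bad <- zc <= 0
  xn <- xc / zc; yn <- yc / zc
  w2 <- tan(camera$hfov / 2 * pi / 180)
  h2 <- tan(camera$vfov / 2 * pi / 180)
  u <- (camera$width - 1) / 2 + xn / w2 * camera$width / 2
  v <- (camera$height - 1) / 2 - yn / h2 * camera$height / 2
  u[bad] <- NA_real_; v[bad] <- NA_real_
  cbind(x = as.numeric(u), y = as.numeric(v))
}

#' Back-project pixel coordinates onto the sea surface
#'
#' Inverse pinhole projection: the ray through the pixel is intersected
#' with the z = 0 ground plane.
#'
#' @param camera A [camera_model()].
#' @param uv Two-column matrix (or length-2 vector) of 0-based pixel
#'   coordinates.
#' @return Two-column matrix of ground positions in metres. Rays parallel
#'   to or above the horizon raise an error.
#' @export
pixel_to_ground <- function(camera, uv) {
  uv <- rbind2mat(uv)
  b <- camera_basis(camera)
  w2 <- tan(camera$hfov / 2 * pi / 180)
  h2 <- tan(camera$vfov / 2 * pi / 180)
  xn <- (uv[, 1] - (camera$width - 1) / 2) * (2 * w2 / camera$width)
  yn <- -(uv[, 2] - (camera$height - 1) / 2) * (2 * h2 / camera$height)
  dx <- xn * b$r[1] + yn * b$u[1] + b$a[1]
  dy <- xn * b$r[2] + yn * b$u[2] + b$a[2]
  dz <- xn * b$r[3] + yn * b$u[3] + b$a[3]
  if (any(dz >= -1e-12))
    stop("pixel ray parallel to or above the horizon")
  t <- camera$elevation / (-dz)
  out <- cbind(t * dx, t * dy)
  if (camera$heading != 0) out <- rotate2(out, camera$heading)
  colnames(out) <- c("x", "y")
  out
}

#' Ground footprint of the camera view
#'
#' Back-projects the four frame corners (pixel centres of the corner
#' pixels).
#'
#' @param camera A [camera_model()].
#' @return 4 x 2 matrix of ground corner positions in metres (top-left,
#'   top-right, bottom-right, bottom-left).
#' @export
camera_footprint <- function(camera) {
  w <- camera$width - 1; h <- camera$height - 1
  pixel_to_ground(camera, rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)))
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 2) else as.matrix(x)
}
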