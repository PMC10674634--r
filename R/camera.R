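#' Pinhole stereo camera model
#'
#' Constructs the single source of geometric truth used throughout the
#' package: an in-air pinhole model of a rectified stereo rig. Disparity is
#' assumed purely horizontal (the pair is rectified upstream, e.g. by the
#' camera firmware), and refraction is ignored by construction: the model
#' targets housings whose ports are orthogonal to the optical axes, so rays
#' cross the air/water interface at normal incidence.
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner,
#' x growing rightward and y downward; pixel centers sit at integer
#' coordinates.
#'
#' @param focal_px Focal length in pixels. A single value (square pixels) or
#'   a length-2 vector `c(horizontal, vertical)`.
#' @param baseline_m Stereo baseline in meters (distance between the two
#'   optical centers). The reference rig uses 0.095 m.
#' @param image_size Integer `c(width, height)` in pixels.
#' @param principal_point Optional `c(cx, cy)` in pixel coordinates; defaults
#'   to the image center `((width-1)/2, (height-1)/2)`.
#' @param vertical_fov_deg Optional vertical field of view in degrees; when
#'   omitted it is derived as `2 * atan(height / (2 * focal_v))`.
#'
#' @return An object of class `camera_model` with fields `focal_px`
#'   (named `h`/`v`), `principal_point` (named `cx`/`cy`), `baseline_m`,
#'   `image_size` (named `width`/`height`) and `vertical_fov_deg`.
#' @examples
#' cam <- camera_model(focal_px = 600, baseline_m = 0.095,
#'                     image_size = c(1280, 720))
#' triangulate(cam, disparity_px = 30)   # 1.9 m
#' @export
camera_model <- function(focal_px, baseline_m, image_size,
                         principal_point = NULL, vertical_fov_deg = NULL) {
  if (length(focal_px) == 1L) focal_px <- c(focal_px, focal_px)
  stopifnot(length(focal_px) == 2L, all(is.finite(focal_px)),
            length(image_size) == 2L)
  if (any(focal_px <= 0)) stop("focal_px must be positive")
  if (!is.finite(baseline_m) || baseline_m <= 0) {
    stop("baseline_m must be positive")
  }
  image_size <- as.integer(round(image_size))
  if (any(image_size < 1L)) stop("image_size components must be >= 1")
  if (is.null(principal_point)) {
    principal_point <- (image_size - 1) / 2
  }
  stopifnot(length(principal_point) == 2L)
  if (is.null(vertical_fov_deg)) {
    vertical_fov_deg <- 2 * atan(image_size[2] / (2 * focal_px[2])) * 180 / pi
  }
  structure(list(
    focal_px = c(h = focal_px[1], v = focal_px[2]),
    principal_point = c(cx = principal_point[1], cy = principal_point[2]),
    baseline_m = baseline_m,
    image_size = c(width = image_size[1], height = image_size[2]),
    vertical_fov_deg = vertical_fov_deg
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> %dx%d px, f = (%.1f, %.1f) px, baseline = %.3f m, vFOV = %.1f deg\n",
    x$image_size["width"], x$image_size["height"],
    x$focal_px["h"], x$focal_px["v"], x$baseline_m, x$vertical_fov_deg))
  invisible(x)
}

#' Default synthetic-rig camera
#'
#' A 640 x 480 px rig with a 380 px focal length and a 0.095 m baseline.
#' This mirrors the geometry of the compact consumer stereo camera the
#' method targets, scaled to half resolution: the vertical field of view is
#' about 65 degrees and the focal length is half the image width, so
#' disparity magnitudes and range resolution behave like the field rig's.
#'
#' @return A [camera_model()].
#' @export
default_camera <- function() {
  camera_model(focal_px = 380, baseline_m = 0.095, image_size = c(640, 480))
}

#' Triangulate depth from disparity
#'
#' Converts a horizontal stereo disparity into metric depth via the rectified
#' pinhole relation `Z = b * f / d`, with baseline `b` in meters, focal
#' length `f` in pixels and disparity `d` in pixels.
#'
#' @param camera A [camera_model()].
#' @param disparity_px Positive disparity in pixels (vectorized).
#' @return Depth in meters, same length as `disparity_px`.
#' @examples
#' cam <- camera_model(600, 0.095, c(1280, 720))
#' triangulate(cam, 30)    # 1.9
#' triangulate(cam, 28.5)  # 2.0
#' @export
triangulate <- function(camera, disparity_px) {
  stopifnot(inherits(camera, "camera_model"))
  if (length(disparity_px) == 0L || any(!is.finite(disparity_px)) ||
      any(disparity_px <= 0)) {
    stop("disparity must be positive and finite (unmatchable/invalid pixel)")
  }
  camera$baseline_m * unname(camera$focal_px["h"]) / disparity_px
}

#' Disparity expected at a given depth
#'
#' Inverse of [triangulate()]: `d = b * f / Z`.
#'
#' @inheritParams triangulate
#' @param depth_m Positive depth in meters (vectorized).
#' @return Disparity in pixels.
#' @export
disparity_at_depth <- function(camera, depth_m) {
  stopifnot(inherits(camera, "camera_model"))
  if (any(!is.finite(depth_m)) || any(depth_m <= 0)) {
    stop("depth must be positive and finite")
  }
  camera$baseline_m * unname(camera$focal_px["h"]) / depth_m
}

#' Metric footprint of one pixel at a given depth
#'
#' Width and height, in meters, of the patch of a fronto-parallel surface at
#' depth `Z` that one pixel observes: `(Z / f_h, Z / f_v)`. The footprint
#' area `Z^2 / (f_h * f_v)` is the scale factor that converts a segmented
#' pixel count into a surface area in m^2.
#'
#' @inheritParams triangulate
#' @param depth_m Positive depth in meters.
#' @return Named numeric `c(width_m, height_m)`.
#' @export
pixel_footprint <- function(camera, depth_m) {
  stopifnot(inherits(camera, "camera_model"), length(depth_m) == 1L)
  if (!is.finite(depth_m) || depth_m <= 0) stop("depth must be positive")
  c(width_m = depth_m / unname(camera$focal_px["h"]),
    height_m = depth_m / unname(camera$focal_px["v"]))
}

#' Area of one pixel's footprint at a given depth
#'
#' @inheritParams pixel_footprint
#' @return Footprint area in m^2; scales as `depth_m^2`.
#' @export
pixel_footprint_area <- function(camera, depth_m) {
  fp <- pixel_footprint(camera, depth_m)
  unname(fp["width_m"] * fp["height_m"])
}

#' Nearest distance at which a centered object fits the frame
#'
#' For a fronto-parallel object of vertical extent `e` centered in a frame
#' with vertical field of view `fov`, the closest viewing distance at which
#' the whole object is in frame is `e / (2 * tan(fov / 2))`. Used to plan
#' acquisition distances for plants that must be fully framed (top to
#' bottom) for their size to be measurable.
#'
#' @param vertical_fov_deg Field of view in degrees, strictly between 0
#'   and 180.
#' @param object_extent_m Object extent in meters (>= 0).
#' @return Minimum viewing distance in meters.
#' @examples
#' min_viewing_distance(90, 2)  # 1.0
#' @export
min_viewing_distance <- function(vertical_fov_deg, object_extent_m) {
  if (!is.finite(vertical_fov_deg) || vertical_fov_deg <= 0 ||
      vertical_fov_deg >= 180) {
    stop("vertical_fov_deg must lie strictly between 0 and 180")
  }
  if (any(object_extent_m < 0)) stop("object_extent_m must be >= 0")
  object_extent_m / (2 * tan(vertical_fov_deg * pi / 360))
}

#' Build a camera model from a manifest camera block
#'
#' @param block Named list with keys `focal_px_h`, `focal_px_v`, `cx`, `cy`,
#'   `baseline_m`, `width`, `height`. `focal_px_v`, `cx` and `cy` may be
#'   omitted (square pixels / centered principal point).
#' @return A [camera_model()].
#' @export
camera_from_manifest <- function(block) {
  req <- c("focal_px_h", "baseline_m", "width", "height")
  missing <- setdiff(req, names(block))
  if (length(missing)) {
    stop("camera block is missing keys: ", paste(missing, collapse = ", "))
  }
  fv <- if (!is.null(block$focal_px_v)) block$focal_px_v else block$focal_px_h
  pp <- if (!is.null(block$cx) && !is.null(block$cy)) c(block$cx, block$cy)
  camera_model(
    focal_px = c(block$focal_px_h, fv),
    baseline_m = block$baseline_m,
    image_size = c(block$width, block$height),
    principal_point = pp
  )
}

#' Serialize a camera model to a manifest camera block
#'
#' @param camera A [camera_model()].
#' @return A named list suitable for JSON serialization.
#' @export
camera_to_manifest <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  list(
    focal_px_h = unname(camera$focal_px["h"]),
    focal_px_v = unname(camera$focal_px["v"]),
    cx = unname(camera$principal_point["cx"]),
    cy = unname(camera$principal_point["cy"]),
    baseline_m = camera$baseline_m,
    width = unname(camera$image_size["width"]),
    height = unname(camera$image_size["height"])
  )
}
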