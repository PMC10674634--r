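#' Specify a flat hanging seaweed sheet
#'
#' Sugar kelp grown on suspended rope lines forms dense ribbon-like bundles
#' that hang vertically and are well approximated by flat 2-D sheets. A
#' sheet is anchored at its top-left corner in the left-camera frame
#' (x rightward, y downward, z along the optical axis) and extends
#' `width_m` rightward and `length_m` downward. Sheets are fronto-parallel
#' (constant depth) in this generator.
#'
#' @param top_anchor Numeric `c(x, y, z)` in meters, camera frame; `z > 0`.
#' @param width_m,length_m Sheet extent in meters; both positive.
#' @param texture_seed Integer seed for the procedural blade texture.
#' @param reflectance_gray Base monochrome reflectance intensity (0-255) seen
#'   by the stereo pair.
#' @param reflectance_rgb Base RGB reflectance `c(r, g, b)` (0-255); the
#'   default olive-brown mimics Saccharina blades.
#' @param texture_strength Multiplier on the texture modulation amplitude;
#'   0 gives a featureless sheet (a stereo-matching failure mode worth
#'   testing), 1 the default band-limited blade texture.
#' @return An object of class `sheet_spec`.
#' @export
sheet_spec <- function(top_anchor, width_m, length_m, texture_seed = 1L,
                       reflectance_gray = 150,
                       reflectance_rgb = c(110, 130, 55),
                       texture_strength = 1) {
  stopifnot(length(top_anchor) == 3L, length(reflectance_rgb) == 3L)
  if (!is.finite(top_anchor[3]) || top_anchor[3] <= 0) {
    stop("sheet anchor depth z must be positive (sheet in front of camera)")
  }
  if (width_m <= 0 || length_m <= 0) stop("sheet extent must be positive")
  if (texture_strength < 0) stop("texture_strength must be >= 0")
  structure(list(
    top_anchor = c(x = top_anchor[1], y = top_anchor[2], z = top_anchor[3]),
    width_m = width_m, length_m = length_m,
    texture_seed = as.integer(texture_seed),
    reflectance_gray = reflectance_gray,
    reflectance_rgb = reflectance_rgb,
    texture_strength = texture_strength
  ), class = "sheet_spec")
}

#' Specify a synthetic underwater stereo scene
#'
#' Bundles sheets, water optics and sensor noise into a renderable scene.
#' Haze follows the standard single-scattering attenuation model: observed
#' intensity is the surface radiance attenuated by `exp(-beta * Z)` plus an
#' airlight (veiling light) term that dominates with distance, emulating the
#' turbid estuarine water the method targets. Open-water background pixels
#' are pure airlight plus sensor noise and carry no valid disparity.
#'
#' @param sheets List of [sheet_spec()] objects. May be empty.
#' @param camera A [camera_model()]; defaults to [default_camera()].
#' @param water_attenuation_beta Attenuation coefficient in 1/m; `>= 0`.
#' @param airlight_level Monochrome airlight intensity (0-255) for the
#'   stereo pair.
#' @param airlight_rgb RGB airlight `c(r, g, b)`; the default is a hazy
#'   blue-green open-water veil.
#' @param noise_sigma Additive Gaussian sensor noise standard deviation in
#'   intensity units; `>= 0`.
#' @param rng_seed Integer master seed; all per-stage randomness (left,
#'   right and RGB sensor noise) is derived deterministically from it.
#' @param truth_max_depth Sheets anchored beyond this depth are rendered but
#'   excluded from the ground-truth mask and area, mirroring the labeling
#'   policy that only the nearest rope line's seaweed counts as foreground.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(sheets, camera = default_camera(),
                       water_attenuation_beta = 0.2,
                       airlight_level = 120,
                       airlight_rgb = c(30, 70, 110),
                       noise_sigma = 3,
                       rng_seed = 1L,
                       truth_max_depth = Inf) {
  stopifnot(is.list(sheets), inherits(camera, "camera_model"))
  if (length(sheets) && !all(vapply(sheets, inherits, TRUE, "sheet_spec"))) {
    stop("sheets must be a list of sheet_spec objects")
  }
  if (water_attenuation_beta < 0) stop("water_attenuation_beta must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(
    sheets = sheets, camera = camera,
    water_attenuation_beta = water_attenuation_beta,
    airlight_level = airlight_level,
    airlight_rgb = airlight_rgb,
    noise_sigma = noise_sigma,
    rng_seed = as.integer(rng_seed),
    truth_max_depth = truth_max_depth
  ), class = "scene_spec")
}

# Band-limited procedural blade texture, evaluated at world coordinates so
# the left and right views sample the same physical pattern (sub-pixel
# consistent). Smooth blotches plus high-frequency vertical ribbon streaks
# give the block matcher features to lock onto; wavelengths are in meters
# and sized like real blade structure (3-50 cm).
sheet_texture <- function(X, Y, seed, strength = 1) {
  ph <- local_seed(seed, stats::runif(6, 0, 2 * pi))
  a <- strength * c(0.25, 0.20, 0.15)
  1 +
    a[1] * sin(2 * pi * X / 0.10 + ph[1]) * cos(2 * pi * Y / 0.18 + ph[2]) +
    a[2] * sin(2 * pi * X / 0.035 + ph[3]) +
    a[3] * cos(2 * pi * (X / 0.15 + Y / 0.45) + ph[4] +
                 0.8 * sin(2 * pi * Y / 0.9 + ph[5]))
}

# Half-open pixel-center coverage of the interval [u0, u1): integer pixel
# coordinates j with u0 <= j < u1, clipped to [0, n - 1]. Returns c(lo, hi)
# or NULL when empty.
center_span <- function(u0, u1, n) {
  lo <- max(ceiling(u0), 0)
  hi <- min(ceiling(u1) - 1, n - 1)
  if (hi < lo) NULL else c(lo, hi)
}

# Render one grayscale or RGB view. `offset_x` is the camera's x position
# (0 for the left/RGB camera, +baseline for the right camera).
# Returns clean float radiance, per-pixel depth (Inf = open water) and
# per-pixel sheet index (0 = background).
render_view <- function(scene, offset_x, rgb = FALSE) {
  cam <- scene$camera
  W <- unname(cam$image_size["width"]); H <- unname(cam$image_size["height"])
  fh <- unname(cam$focal_px["h"]); fv <- unname(cam$focal_px["v"])
  cx <- unname(cam$principal_point["cx"])
  cy <- unname(cam$principal_point["cy"])

  depth <- matrix(Inf, H, W)
  sheet_id <- matrix(0L, H, W)
  nchan <- if (rgb) 3L else 1L
  radiance <- array(0, dim = c(H, W, nchan))

  ord <- order(vapply(scene$sheets, function(s) s$top_anchor["z"], 0),
               decreasing = TRUE)  # far to near; nearer sheets overwrite
  for (k in ord) {
    s <- scene$sheets[[k]]
    z <- unname(s$top_anchor["z"])
    x0 <- unname(s$top_anchor["x"]); y0 <- unname(s$top_anchor["y"])
    us <- center_span(fh * (x0 - offset_x) / z + cx,
                      fh * (x0 + s$width_m - offset_x) / z + cx, W)
    vs <- center_span(fv * y0 / z + cy,
                      fv * (y0 + s$length_m) / z + cy, H)
    if (is.null(us) || is.null(vs)) {
      if (offset_x == 0) {
        stop(sprintf("sheet %d projects to zero area in the left view", k))
      }
      next
    }
    cols <- us[1]:us[2]; rows <- vs[1]:vs[2]
    Xw <- (cols - cx) * z / fh + offset_x
    Yw <- (rows - cy) * z / fv
    Xm <- matrix(Xw, nrow = length(rows), ncol = length(cols), byrow = TRUE)
    Ym <- matrix(Yw, nrow = length(rows), ncol = length(cols))
    Tm <- sheet_texture(Xm, Ym, s$texture_seed, s$texture_strength)
    Tm <- pmax(Tm, 0)
    depth[rows + 1, cols + 1] <- z
    sheet_id[rows + 1, cols + 1] <- k
    if (rgb) {
      for (ch in 1:3) {
        radiance[rows + 1, cols + 1, ch] <- s$reflectance_rgb[ch] * Tm
      }
    } else {
      radiance[rows + 1, cols + 1, 1] <- s$reflectance_gray * Tm
    }
  }
  list(radiance = radiance, depth = depth, sheet_id = sheet_id)
}

#' Apply a single-scattering haze model
#'
#' Attenuates scene radiance toward a veiling airlight with optical depth
#' `beta * Z`: `I = J * exp(-beta * Z) + airlight * (1 - exp(-beta * Z))`.
#' Pixels with `NA` or infinite depth (open water) become pure airlight.
#'
#' @param image Numeric matrix (grayscale) or H x W x 3 array (RGB).
#' @param depth_map Per-pixel depth in meters, same H x W as `image`.
#' @param beta Attenuation coefficient in 1/m; `>= 0`.
#' @param airlight Airlight intensity; scalar, or length 3 for RGB input.
#' @return Hazed image, same shape and intensity bounds as the input.
#' @export
apply_haze <- function(image, depth_map, beta, airlight) {
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0 and finite")
  if (beta == 0) return(image)
  depth_map[is.na(depth_map)] <- Inf
  t <- exp(-beta * depth_map)
  if (length(dim(image)) == 3L) {
    if (length(airlight) == 1L) airlight <- rep(airlight, 3)
    out <- image
    for (ch in 1:3) {
      out[, , ch] <- image[, , ch] * t + airlight[ch] * (1 - t)
    }
    out
  } else {
    image * t + airlight[1] * (1 - t)
  }
}

#' Add clipped Gaussian sensor noise
#'
#' Adds zero-mean Gaussian noise, rounds to integer intensity and clips to
#' the 8-bit range. Reproducible under `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param image Numeric matrix or array with values in 0-255.
#' @param sigma Noise standard deviation in intensity units; `>= 0`.
#' @param seed Integer seed.
#' @return Integer raster of the same shape, values in 0-255.
#' @export
add_sensor_noise <- function(image, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  out <- if (sigma == 0) image else {
    image + local_seed(seed, stats::rnorm(length(image), 0, sigma))
  }
  array(as.integer(round(clip255(out))), dim = dim(image))
}

#' Render a ground-truthed synthetic stereo frame set
#'
#' Produces the per-frame acquisition unit the field protocol records: one
#' RGB image plus a rectified grayscale stereo pair, together with ground
#' truth no field campaign can provide (per-pixel mask and depth, exact
#' sheet surface area). The RGB camera is co-located with the left stereo
#' camera, so the truth mask is valid for both. A sheet at depth `Z`
#' appears in the right image shifted by `baseline * focal / Z` pixels;
#' textures are sampled in world coordinates so the shift is sub-pixel
#' consistent.
#'
#' @param scene A [scene_spec()].
#' @param frame_id Identifier stored with the frame set.
#' @return An object of class `image_set` with fields `rgb_image`,
#'   `left_gray`, `right_gray` (8-bit integer rasters), `truth_mask`
#'   ([segmentation_mask()]), `truth_depth` (meters, `NA` on open water),
#'   `truth_area_m2`, `frame_id` and `camera`.
#' @export
render_stereo_set <- function(scene, frame_id = "frame_0001") {
  stopifnot(inherits(scene, "scene_spec"))
  cam <- scene$camera
  beta <- scene$water_attenuation_beta

  left <- render_view(scene, offset_x = 0, rgb = FALSE)
  right <- render_view(scene, offset_x = cam$baseline_m, rgb = FALSE)
  rgbv <- render_view(scene, offset_x = 0, rgb = TRUE)

  # open water is the veiling light of the water column at any turbidity
  hz <- function(view, airlight) {
    r <- view$radiance
    bg <- view$sheet_id == 0L
    if (dim(r)[3] == 1L) {
      img <- r[, , 1]
      img[bg] <- airlight
      apply_haze(img, view$depth, beta, airlight)
    } else {
      if (length(airlight) == 1L) airlight <- rep(airlight, 3)
      for (ch in 1:3) {
        plane <- r[, , ch]
        plane[bg] <- airlight[ch]
        r[, , ch] <- plane
      }
      apply_haze(r, view$depth, beta, airlight)
    }
  }
  seed <- scene$rng_seed
  left_img <- add_sensor_noise(round(clip255(hz(left, scene$airlight_level))),
                               scene$noise_sigma, derive_seed(seed, 1))
  right_img <- add_sensor_noise(round(clip255(hz(right, scene$airlight_level))),
                                scene$noise_sigma, derive_seed(seed, 2))
  rgb_img <- add_sensor_noise(round(clip255(hz(rgbv, scene$airlight_rgb))),
                              scene$noise_sigma, derive_seed(seed, 3))

  fg <- which(vapply(scene$sheets, function(s)
    unname(s$top_anchor["z"]) <= scene$truth_max_depth, TRUE))
  mask <- matrix(left$sheet_id %in% fg, nrow(left$sheet_id))
  truth_depth <- left$depth
  truth_depth[!is.finite(truth_depth)] <- NA_real_

  truth_area <- 0
  fh <- unname(cam$focal_px["h"]); fv <- unname(cam$focal_px["v"])
  cx <- unname(cam$principal_point["cx"])
  cy <- unname(cam$principal_point["cy"])
  W <- unname(cam$image_size["width"]); H <- unname(cam$image_size["height"])
  for (k in fg) {
    s <- scene$sheets[[k]]
    z <- unname(s$top_anchor["z"])
    # exact in-frame clip of the sheet rectangle in world units
    xb <- c(-0.5 - cx, W - 0.5 - cx) * z / fh
    yb <- c(-0.5 - cy, H - 0.5 - cy) * z / fv
    wv <- max(0, min(s$top_anchor["x"] + s$width_m, xb[2]) -
                   max(s$top_anchor["x"], xb[1]))
    lv <- max(0, min(s$top_anchor["y"] + s$length_m, yb[2]) -
                   max(s$top_anchor["y"], yb[1]))
    area_k <- wv * lv
    # subtract pixels occluded by nearer sheets (discretized; exact when
    # sheets do not overlap in the image)
    us <- center_span(fh * s$top_anchor["x"] / z + cx,
                      fh * (s$top_anchor["x"] + s$width_m) / z + cx, W)
    vs <- center_span(fv * s$top_anchor["y"] / z + cy,
                      fv * (s$top_anchor["y"] + s$length_m) / z + cy, H)
    if (!is.null(us) && !is.null(vs)) {
      sub <- left$sheet_id[vs[1]:vs[2] + 1, us[1]:us[2] + 1, drop = FALSE]
      occluded <- sum(sub != k)
      area_k <- max(0, area_k - occluded * z^2 / (fh * fv))
    }
    truth_area <- truth_area + area_k
  }

  structure(list(
    rgb_image = rgb_img,
    left_gray = left_img,
    right_gray = right_img,
    truth_mask = segmentation_mask(mask, frame_id, source = "annotation"),
    truth_depth = truth_depth,
    truth_area_m2 = unname(truth_area),
    frame_id = frame_id,
    camera = cam
  ), class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf(
    "<image_set> %s: %dx%d px, truth area %.3f m2, %d mask px\n",
    x$frame_id, ncol(x$left_gray), nrow(x$left_gray),
    x$truth_area_m2, sum(x$truth_mask$values)))
  invisible(x)
}

#' Draw a random single-sheet scene from the study conditions
#'
#' Samples one hanging sheet with surface area 0.5-6 m^2 at a range of
#' 1.5-3.5 m (the working envelope of the acquisition protocol: near enough
#' to resolve blade texture through the haze, far enough to frame the
#' plant), fully in frame, with turbidity `beta` up to 0.3 /m and sensor
#' noise up to sigma 5. The range lower bound is raised when needed so the
#' sampled sheet fits the frame with a 2% margin.
#'
#' @param seed Integer seed; fully determines the scene.
#' @param camera A [camera_model()].
#' @param area_range,z_range,beta_range,sigma_range Numeric `c(lo, hi)`
#'   sampling intervals for sheet area (m^2), sheet range (m), attenuation
#'   (1/m) and noise sigma.
#' @return A [scene_spec()] containing a single sheet.
#' @export
random_scene <- function(seed, camera = default_camera(),
                         area_range = c(0.5, 6), z_range = c(1.5, 3.5),
                         beta_range = c(0, 0.3), sigma_range = c(0, 5)) {
  local_seed(seed, {
    area <- stats::runif(1, area_range[1], area_range[2])
    aspect <- stats::runif(1, 1.2, 2.5)  # length/width: hanging ribbons
    w <- sqrt(area / aspect); l <- w * aspect
    W <- unname(camera$image_size["width"])
    H <- unname(camera$image_size["height"])
    fh <- unname(camera$focal_px["h"]); fv <- unname(camera$focal_px["v"])
    z_fit <- max(w * fh / (0.98 * W), l * fv / (0.98 * H))
    zlo <- max(z_range[1], z_fit)
    z <- stats::runif(1, zlo, max(zlo, z_range[2]))
    # the acquisition protocol aims the camera at the plant, so the sheet
    # sits near the frame center: jitter uses a quarter of the free slack
    slack_x <- 0.25 * (0.98 * W * z / fh - w) / 2
    slack_y <- 0.25 * (0.98 * H * z / fv - l) / 2
    x0 <- -w / 2 + stats::runif(1, -slack_x, slack_x)
    y0 <- -l / 2 + stats::runif(1, -slack_y, slack_y)
    sheet <- sheet_spec(c(x0, y0, z), w, l,
                        texture_seed = derive_seed(seed, 11))
    scene_spec(
      sheets = list(sheet), camera = camera,
      water_attenuation_beta = stats::runif(1, beta_range[1], beta_range[2]),
      noise_sigma = stats::runif(1, sigma_range[1], sigma_range[2]),
      rng_seed = derive_seed(seed, 12)
    )
  })
}

#' Read an 8-bit grayscale PNG as an integer matrix
#'
#' Multi-channel files are reduced to their first channel (the stereo pair
#' is stored single-channel by [write_image_set()]).
#'
#' @param path PNG file path.
#' @return Integer matrix, values 0-255.
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  from_unit(x)
}

#' Read an 8-bit RGB PNG as an integer array
#'
#' @param path PNG file path.
#' @return Integer H x W x 3 array, values 0-255.
#' @export
read_rgb_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
  from_unit(x[, , 1:3])
}

#' Write a rendered frame set to disk
#'
#' Emits `<frame_id>_rgb.png`, `<frame_id>_L.png`, `<frame_id>_R.png`,
#' `<frame_id>_mask.png` (0/255) and `<frame_id>_truth.json` (truth area,
#' sheet geometry and seeds) into `dir`.
#'
#' @param iset An [render_stereo_set()] result.
#' @param dir Output directory (created if absent).
#' @param scene Optional [scene_spec()] echoed into the truth sidecar.
#' @return Invisibly, a manifest frame entry (named list of relative paths).
#' @export
write_image_set <- function(iset, dir, scene = NULL) {
  stopifnot(inherits(iset, "image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fid <- iset$frame_id
  paths <- list(
    frame_id = fid,
    rgb = paste0(fid, "_rgb.png"),
    left = paste0(fid, "_L.png"),
    right = paste0(fid, "_R.png"),
    mask = paste0(fid, "_mask.png")
  )
  png::writePNG(to_unit(iset$rgb_image), file.path(dir, paths$rgb))
  png::writePNG(to_unit(iset$left_gray), file.path(dir, paths$left))
  png::writePNG(to_unit(iset$right_gray), file.path(dir, paths$right))
  png::writePNG(to_unit(iset$truth_mask$values * 255),
                file.path(dir, paths$mask))
  truth <- list(
    frame_id = fid,
    truth_area_m2 = iset$truth_area_m2,
    mask_px = sum(iset$truth_mask$values),
    sheet_depths_m = if (!is.null(scene)) {
      vapply(scene$sheets, function(s) unname(s$top_anchor["z"]), 0)
    },
    rng_seed = if (!is.null(scene)) scene$rng_seed,
    water_attenuation_beta = if (!is.null(scene)) scene$water_attenuation_beta,
    noise_sigma = if (!is.null(scene)) scene$noise_sigma
  )
  jsonlite::write_json(truth, file.path(dir, paste0(fid, "_truth.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Simulate a multi-frame dataset with a manifest
#'
#' Renders `n_frames` independent [random_scene()] draws, writes the frame
#' sets and a `manifest.json` (camera block plus frame entries) that
#' [run_pipeline()] consumes.
#'
#' @param n_frames Number of frames.
#' @param dir Output directory.
#' @param seed Master seed; frame `i` uses a seed derived from it.
#' @param camera A [camera_model()].
#' @param ... Passed to [random_scene()].
#' @return Invisibly, the manifest path.
#' @export
simulate_dataset <- function(n_frames, dir, seed = 1L,
                             camera = default_camera(), ...) {
  stopifnot(n_frames >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- vector("list", n_frames)
  truth_area <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    scn <- random_scene(derive_seed(seed, 100 + i), camera = camera, ...)
    fid <- sprintf("frame_%04d", i)
    iset <- render_stereo_set(scn, frame_id = fid)
    frames[[i]] <- write_image_set(iset, dir, scene = scn)
    truth_area[i] <- iset$truth_area_m2
  }
  manifest <- list(camera = camera_to_manifest(camera), frames = frames)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
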