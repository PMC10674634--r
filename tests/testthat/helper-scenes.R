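# Shared fixture builders. Everything is generated in code at test time.

# reduced-resolution rig for cheap renders where metric precision is not
# under test; the focal length keeps the 3.5 cm blade-streak texture above
# Nyquist out to ~2.5 m, so stereo matching stays meaningful
small_camera <- function() {
  camera_model(focal_px = 160, baseline_m = 0.095, image_size = c(160, 120))
}

# study-condition band where the small rig resolves the blade texture
small_z_range <- c(1.6, 2.4)

small_scene <- function(seed = 1L, noise_sigma = 3, beta = 0.2,
                        z = 2.2, w = 0.8, l = 1.1) {
  scene_spec(list(sheet_spec(c(-w / 2, -l / 2, z), w, l,
                             texture_seed = seed + 500L)),
             camera = small_camera(),
             water_attenuation_beta = beta, noise_sigma = noise_sigma,
             rng_seed = seed)
}

small_sgm <- function(...) {
  # disparity at z = 2.2 m with the small rig is ~5.2 px
  sgm_params(block_size = 7L, disparity_range = c(0L, 15L), ...)
}

random_gray <- function(H, W, seed) {
  matrix(local_seed_test(seed, sample.int(256L, H * W, replace = TRUE) - 1L),
         H, W)
}

local_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# right image for a uniform integer shift d: R(y, x) = L(y, x + d),
# padded on the right with the left image's border column
shift_pair <- function(left, d) {
  W <- ncol(left)
  right <- left[, c((1 + d):W, rep(W, d)), drop = FALSE]
  right
}
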