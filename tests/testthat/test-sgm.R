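test_that("block matching cost is zero at the true shift and matches the oracle", {
  p <- sgm_params(block_size = 3L, disparity_range = c(0L, 4L),
                  texture_threshold = 0)
  L <- random_gray(10, 14, seed = 1)
  cv0 <- matching_cost(L, L, p)
  # identical images: zero cost at d = 0 everywhere
  expect_true(all(cv0$costs[, , 1] == 0L))

  R <- shift_pair(L, 4L)
  cv <- matching_cost(L, R, p)
  interior <- cv$costs[3:8, 6:9, , drop = FALSE]
  expect_true(all(apply(interior, c(1, 2), which.min) == 5L))
  expect_true(all(interior[, , 5] == 0L))

  # brute-force oracle equality on a random pair
  A <- random_gray(8, 8, seed = 2); B <- random_gray(8, 8, seed = 3)
  cvr <- matching_cost(A, B, p)
  expect_identical(array(as.integer(cvr$costs), dim = dim(cvr$costs)),
                   array(as.integer(oracle_cost_volume(A, B, 0, 4, 3)),
                         dim = dim(cvr$costs)))
  expect_error(matching_cost(A, random_gray(7, 8, seed = 4), p), "mismatch")
})

test_that("infeasible candidates carry the sentinel cost", {
  p <- sgm_params(block_size = 3L, disparity_range = c(0L, 5L),
                  texture_threshold = 0)
  cv <- matching_cost(random_gray(6, 8, seed = 5), random_gray(6, 8, seed = 6), p)
  sent <- 3^2 * 255 + 1
  for (di in 1:6) {
    d <- di - 1
    if (d > 0) expect_true(all(cv$costs[, seq_len(d), di] == sent))
    if (d < 7) expect_true(all(cv$costs[, (d + 1):8, di] < sent))
  }
})

test_that("path aggregation equals the dynamic-programming oracle", {
  p <- sgm_params(block_size = 3L, disparity_range = c(0L, 4L),
                  penalty_small = 20L, penalty_large = 90L,
                  texture_threshold = 0)
  L <- random_gray(9, 11, seed = 7); R <- random_gray(9, 11, seed = 8)
  cv <- matching_cost(L, R, p)
  for (np in c(4L, 8L)) {
    pp <- p; pp$n_paths <- np
    agg <- aggregate_paths(cv, pp)
    ref <- oracle_aggregate(array(as.numeric(cv$costs), dim = dim(cv$costs)),
                            20, 90, np)
    expect_equal(array(as.numeric(agg$costs), dim = dim(ref)), ref)
    expect_true(all(agg$costs >= 0))
  }
})

test_that("a single row aggregated along one scan equals exhaustive Viterbi", {
  # 6-pixel, 4-disparity instance: enumerate all 4^6 disparity sequences
  # with transition penalties 0 / P1 / P2 and compare against the path
  # recurrence (which normalizes by a per-pixel constant, so compare
  # shapes at the final pixel)
  C <- array(local_seed_test(9, sample(0:60, 24, replace = TRUE)),
             dim = c(1, 6, 4))
  P1 <- 7; P2 <- 25
  L <- oracle_path(C, P1, P2, 0, 1)
  vit <- oracle_enumerate_row(matrix(C[1, , ], 6, 4), P1, P2)
  final <- L[1, 6, ]
  expect_equal(final - min(final), vit - min(vit))
})

test_that("winner selection refines sub-pixel by parabolic interpolation", {
  # hand-built aggregated volume: one pixel of interest at x = 5 with
  # costs (4, 2, 3) at d = 1, 2, 3 -> disparity 2 + 1/6
  A <- array(1000L, dim = c(1, 8, 5))
  A[1, 6, ] <- c(900L, 4L, 2L, 3L, 900L)
  vol <- structure(list(costs = A, disparity_range = c(0L, 4L),
                        block_size = 1L, sentinel = 256L, texture = NULL),
                   class = "cost_volume")
  p <- sgm_params(block_size = 1L, disparity_range = c(0L, 4L),
                  uniqueness_ratio = 0L, texture_threshold = 0)
  dm <- select_disparity(vol, p)
  expect_equal(dm$values[1, 6], 2 + 1 / 6)
  # symmetric costs around the minimum: zero offset
  A[1, 6, ] <- c(900L, 4L, 2L, 4L, 900L)
  vol$costs <- A
  dm <- select_disparity(vol, p)
  expect_equal(dm$values[1, 6], 2)
  # unique strict minima yield the argmin map when subpixel is off
  p$subpixel <- FALSE
  dm <- select_disparity(vol, p)
  expect_equal(dm$values[1, 6], 2)
})

test_that("uniform shifts are recovered within a quarter pixel", {
  L <- random_gray(32, 32, seed = 10)
  R <- shift_pair(L, 4L)
  p <- sgm_params(block_size = 5L, disparity_range = c(0L, 7L),
                  texture_threshold = 0)
  dm <- compute_disparity(L, R, p)
  interior <- dm$values[4:29, 12:26]
  expect_true(all(!is.na(interior)))
  expect_true(all(abs(interior - 4) <= 0.25))
})

test_that("textureless frames yield mostly invalid pixels", {
  flat <- matrix(120L, 40, 50)
  dm <- compute_disparity(flat, flat,
                          sgm_params(block_size = 5L,
                                     disparity_range = c(0L, 7L)))
  expect_gt(mean(!dm$valid), 0.5)
  # equal raw costs also fail the uniqueness ratio on their own (before
  # aggregation, whose border effects can break exact ties)
  p0 <- sgm_params(block_size = 5L, disparity_range = c(0L, 7L),
                   texture_threshold = 0)
  dm2 <- select_disparity(matching_cost(flat, flat, p0), p0)
  expect_gt(mean(!dm2$valid), 0.5)
})

test_that("full pipeline equals the plain-R reference on random pairs", {
  for (case in 1:6) {
    H <- 6 + case; W <- 8 + case
    p <- sgm_params(block_size = c(1L, 2L, 3L, 4L, 5L, 3L)[case],
                    disparity_range = c(0L, c(3L, 4L, 5L, 6L, 7L, 4L)[case]),
                    do_left_right_check = case %% 2 == 0,
                    texture_threshold = if (case == 5) 4 else 0)
    L <- random_gray(H, W, seed = 100 + case)
    R <- random_gray(H, W, seed = 200 + case)
    dm <- compute_disparity(L, R, p)
    ref <- oracle_sgm(L, R, p)
    expect_identical(dm$valid, ref$valid)
    expect_identical(dm$values, ref$values)
  }
})

test_that("synthetic renders recover the geometric disparity", {
  cam500 <- camera_model(500, 0.095, c(640, 480))
  scn <- scene_spec(list(sheet_spec(c(-0.5, -1, 2.5), 1, 2)),
                    camera = cam500, water_attenuation_beta = 0,
                    noise_sigma = 0, rng_seed = 31L)
  iset <- render_stereo_set(scn)
  dm <- compute_disparity(iset$left_gray, iset$right_gray,
                          sgm_params(disparity_range = c(0L, 31L)))
  # median valid disparity near b*f/Z = 19 px
  med <- suppressWarnings(
    median_scene_distance(dm, cam500, crop_size = c(600, 400)))
  expect_lt(abs(med$median_disparity_px - 19), 0.5)
  # noise-free disparity consistency: >= 95% of interior sheet pixels
  # within half a pixel of truth
  m <- iset$truth_mask$values
  interior <- EBImage::erode(EBImage::Image(t(m) * 1),
                             EBImage::makeBrush(25, "box"))
  idx <- which(t(interior) > 0 & !is.na(dm$values))
  expect_gt(length(idx), 1000)
  expect_gte(mean(abs(dm$values[idx] - 19) <= 0.5), 0.95)
})

test_that("interior disparities are equivariant to a common translation", {
  L <- random_gray(36, 40, seed = 55)
  R <- shift_pair(L, 3L)
  p <- sgm_params(block_size = 5L, disparity_range = c(0L, 7L),
                  texture_threshold = 0)
  base <- compute_disparity(L, R, p)$values
  # translate both images down-right by (2, 5)
  Lt <- L[c(rep(1, 2), 1:34), c(rep(1, 5), 1:35)]
  Rt <- R[c(rep(1, 2), 1:34), c(rep(1, 5), 1:35)]
  shifted <- compute_disparity(Lt, Rt, p)$values
  expect_equal(shifted[11:30, 16:33], base[9:28, 11:28])
})

test_that("the central-crop median range ignores invalid and outlying pixels", {
  cam500 <- camera_model(500, 0.095, c(640, 480))
  mk <- function(values, valid) {
    structure(list(values = values, valid = valid,
                   disparity_range = c(0L, 47L), block_size = 16L),
              class = "disparity_map")
  }
  vals <- matrix(19, 480, 640); ok <- matrix(TRUE, 480, 640)
  expect_equal(median_scene_distance(mk(vals, ok), cam500)$range_m, 2.5)

  # 40% invalid pixels leave the median unchanged; matches a sort oracle
  inval <- matrix(local_seed_test(6, stats::runif(480 * 640) < 0.4), 480, 640)
  vals2 <- vals; vals2[inval] <- NA
  r <- median_scene_distance(mk(vals2, !inval), cam500)
  expect_equal(r$range_m, 2.5)
  x0 <- (640 - 600) / 2; y0 <- (480 - 400) / 2
  crop_vals <- vals2[(y0 + 1):(y0 + 400), (x0 + 1):(x0 + 600)]
  crop_ok <- !inval[(y0 + 1):(y0 + 400), (x0 + 1):(x0 + 600)]
  sorted <- sort(crop_vals[crop_ok])
  n <- length(sorted)
  sort_median <- if (n %% 2 == 1) sorted[(n + 1) / 2] else
    (sorted[n / 2] + sorted[n / 2 + 1]) / 2
  expect_equal(r$median_disparity_px, sort_median)

  # all invalid: explicit unavailability
  none <- median_scene_distance(mk(vals, matrix(FALSE, 480, 640)), cam500)
  expect_true(is.na(none$range_m))
  expect_true("range-unavailable" %in% none$flags)

  # crop larger than the frame is clipped with a warning and flag
  small <- mk(matrix(19, 100, 120), matrix(TRUE, 100, 120))
  expect_warning(rs <- median_scene_distance(small, cam500), "clipped")
  expect_true("clipped-crop" %in% rs$flags)
  expect_equal(rs$range_m, 2.5)
})

test_that("median range resists up to 49% corrupted disparities", {
  cam500 <- camera_model(500, 0.095, c(640, 480))
  vals <- matrix(19, 480, 640)
  corrupt <- matrix(local_seed_test(8, stats::runif(480 * 640) < 0.49),
                    480, 640)
  vals[corrupt] <- local_seed_test(9, sample(c(1, 45), sum(corrupt),
                                             replace = TRUE))
  dm <- structure(list(values = vals, valid = matrix(TRUE, 480, 640),
                       disparity_range = c(0L, 47L), block_size = 16L),
                  class = "disparity_map")
  r <- median_scene_distance(dm, cam500)
  quantum <- 2.5 - triangulate(cam500, 20)  # depth of one disparity step
  expect_lt(abs(r$range_m - 2.5), quantum)
})

test_that("disparity maps persist as fixed-point rasters with sidecar", {
  dir <- withr::local_tempdir()
  L <- random_gray(24, 30, seed = 77)
  dm <- compute_disparity(L, shift_pair(L, 3L),
                          sgm_params(block_size = 5L,
                                     disparity_range = c(0L, 7L),
                                     texture_threshold = 0))
  path <- file.path(dir, "disp.tif")
  write_disparity(dm, path)
  back <- read_disparity(path)
  expect_identical(back$valid, dm$valid == TRUE)
  expect_lt(max(abs(back$values - dm$values), na.rm = TRUE), 1 / 16)
  expect_identical(back$disparity_range, dm$disparity_range)
})
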