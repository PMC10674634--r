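# independent even-odd point-in-polygon oracle (crossing number per pixel
# center, half-open like the rasterizer's documented rule)
pip_oracle <- function(verts, W, H) {
  n <- nrow(verts)
  x1 <- verts[, 1]; y1 <- verts[, 2]
  x2 <- verts[c(2:n, 1), 1]; y2 <- verts[c(2:n, 1), 2]
  mask <- matrix(FALSE, H, W)
  for (py in 0:(H - 1)) for (px in 0:(W - 1)) {
    crossings <- 0
    for (e in 1:n) {
      if ((y1[e] > py) != (y2[e] > py)) {
        xint <- x1[e] + (py - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
        if (px < xint) crossings <- crossings + 1
      }
    }
    mask[py + 1, px + 1] <- crossings %% 2 == 1
  }
  mask
}

test_that("rectangles rasterize to exact pixel counts under the centers rule", {
  rect <- annotation_polygon(rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20)),
                             frame_id = "f1")
  m <- rasterize_polygons(list(rect), c(32, 32))
  expect_equal(sum(m$values), 100L)
  expect_true(all(which(m$values, arr.ind = TRUE)[, 1] %in% 11:20))

  # two disjoint rectangles: areas add
  r2 <- annotation_polygon(rbind(c(1, 1), c(5, 1), c(5, 4), c(1, 4)))
  m2 <- rasterize_polygons(list(rect, r2), c(32, 32))
  expect_equal(sum(m2$values), 100L + 12L)

  # empty polygon list: all-zero mask
  expect_equal(sum(rasterize_polygons(list(), c(16, 8))$values), 0L)
})

test_that("rasterization agrees with a point-in-polygon oracle", {
  shapes <- list(
    rbind(c(2.5, 1.2), c(13.7, 3.4), c(9.1, 11.8)),              # triangle
    rbind(c(1, 1), c(14, 2), c(12, 13), c(8, 6), c(2, 12)),      # concave
    rbind(c(0.5, 7.5), c(7.5, 0.5), c(14.5, 7.5), c(7.5, 14.5))  # diamond
  )
  for (v in shapes) {
    got <- rasterize_polygons(list(annotation_polygon(v)), c(16, 16))
    expect_identical(got$values, pip_oracle(v, 16, 16))
  }
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(annotation_polygon(rbind(c(0, 0), c(5, 5)), frame_id = "f9"),
               "f9")
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(annotation_polygon(bowtie, frame_id = "f3"),
               "self-intersecting")
})

test_that("IoU obeys its definition, conventions and symmetry", {
  a <- matrix(FALSE, 20, 20); a[3:12, 3:12] <- TRUE      # 100 px
  expect_equal(iou(a, a), 1.0)
  b <- matrix(FALSE, 20, 20); b[15:18, 15:18] <- TRUE
  expect_equal(iou(a, b), 0.0)
  # 200 px region fully inside a 400 px region
  inner <- matrix(FALSE, 30, 30); inner[1:10, 1:20] <- TRUE
  outer <- matrix(FALSE, 30, 30); outer[1:20, 1:20] <- TRUE
  expect_equal(iou(inner, outer), 0.5)
  # conventions for empty masks
  e <- matrix(FALSE, 20, 20)
  expect_equal(iou(e, e), 1.0)
  expect_equal(iou(e, a), 0.0)
  expect_error(iou(a, matrix(FALSE, 10, 10)), "mismatch")

  for (seed in 1:5) {
    x <- matrix(local_seed_test(seed, stats::runif(400) < 0.3), 20, 20)
    y <- matrix(local_seed_test(seed + 50, stats::runif(400) < 0.3), 20, 20)
    expect_equal(iou(x, y), iou(y, x))
    expect_equal(iou(x, y),
                 sum(x & y) / max(sum(x | y), 1) + (sum(x | y) == 0))
  }
})

test_that("IoU decreases along nested mask chains", {
  a <- matrix(FALSE, 30, 30); a[5:14, 5:14] <- TRUE
  b <- a; b[5:14, 15:19] <- TRUE
  c <- b; c[15:24, 5:19] <- TRUE
  expect_gte(iou(a, b), iou(a, c))
  expect_gt(iou(a, b), 0); expect_gt(iou(a, c), 0)
})

test_that("classical segmentation is exact on clean renders, empty on water", {
  clean <- small_scene(seed = 21, noise_sigma = 0, beta = 0)
  iset <- render_stereo_set(clean)
  seg <- classical_segment(iset$rgb_image)
  expect_equal(iou(seg, iset$truth_mask), 1.0)
  expect_identical(seg$source, "classical")

  water <- render_stereo_set(scene_spec(list(), camera = small_camera(),
                                        noise_sigma = 3, rng_seed = 4))
  expect_equal(sum(classical_segment(water$rgb_image)$values), 0L)
})

test_that("classical segmentation stays accurate under noise and haze", {
  hard <- small_scene(seed = 33, noise_sigma = 5, beta = 0.3)
  iset <- render_stereo_set(hard)
  seg <- classical_segment(iset$rgb_image)
  expect_gte(iou(seg, iset$truth_mask), 0.9)
})

test_that("segmentation quality degrades monotonically with turbidity", {
  mean_iou <- vapply(c(0, 0.3, 0.6), function(beta) {
    mean(vapply(1:10, function(s) {
      iset <- render_stereo_set(small_scene(seed = 300 + s, noise_sigma = 5,
                                            beta = beta))
      iou(classical_segment(iset$rgb_image), iset$truth_mask)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_iou) <= 1e-12))
  expect_gt(mean_iou[1], 0.95)
})

test_that("the external segmenter hook validates its contract", {
  dir <- withr::local_tempdir()
  iset <- render_stereo_set(small_scene(seed = 8))
  frame <- file.path(dir, "frame.png")
  png::writePNG(iset$rgb_image / 255, frame)
  good_mask <- file.path(dir, "good_mask.png")
  write_mask_png(iset$truth_mask, good_mask)

  stub <- file.path(dir, "segmenter.sh")
  writeLines(c("#!/bin/sh", sprintf("cp %s \"$2\"", shQuote(good_mask))), stub)
  Sys.chmod(stub, "0755")
  out <- external_segmenter_hook(frame, list(command = stub), frame_id = "f1")
  expect_identical(out$values, iset$truth_mask$values)
  expect_identical(out$source, "external-model")

  # wrong-size mask is rejected with the frame id
  bad_mask <- file.path(dir, "bad_mask.png")
  png::writePNG(matrix(1, 4, 4), bad_mask)
  bad <- file.path(dir, "bad.sh")
  writeLines(c("#!/bin/sh", sprintf("cp %s \"$2\"", shQuote(bad_mask))), bad)
  Sys.chmod(bad, "0755")
  expect_error(external_segmenter_hook(frame, list(command = bad),
                                       frame_id = "f7"), "f7")

  # a failing or missing segmenter is a configuration error
  fail <- file.path(dir, "fail.sh")
  writeLines(c("#!/bin/sh", "exit 3"), fail)
  Sys.chmod(fail, "0755")
  expect_error(external_segmenter_hook(frame, list(command = fail)), "status")
  expect_error(external_segmenter_hook(frame,
                                       list(command = "/no/such/model")),
               "not found")
})

test_that("CVAT XML polygons import into the internal schema", {
  xml <- c('<?xml version="1.0" encoding="utf-8"?>',
           '<annotations>',
           '  <version>1.1</version>',
           '  <image id="0" name="frame_0001" width="64" height="48">',
           '    <polygon label="seaweed" points="4.0,4.0;20.0,6.0;18.0,30.0;5.0,28.0" z_order="0"/>',
           '    <polygon label="rigging" points="40.0,0.0;44.0,0.0;44.0,47.0;40.0,47.0" z_order="0"/>',
           '  </image>',
           '</annotations>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  all_polys <- read_cvat_polygons(path)
  expect_named(all_polys, "frame_0001")
  expect_length(all_polys$frame_0001, 2L)
  kelp <- read_cvat_polygons(path, label = "seaweed")$frame_0001
  expect_length(kelp, 1L)
  expect_equal(kelp[[1]]$vertices[2, ], c(20, 6))
  expect_identical(kelp[[1]]$frame_id, "frame_0001")

  # JSON round trip preserves geometry
  jp <- withr::local_tempfile(fileext = ".json")
  write_polygons_json(kelp, jp)
  back <- read_polygons_json(jp)
  expect_equal(back[[1]]$vertices, kelp[[1]]$vertices)
})
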