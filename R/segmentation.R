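#' Binary segmentation mask
#'
#' @param values Logical (or 0/1) matrix, `TRUE` = seaweed.
#' @param frame_id Frame identifier.
#' @param source One of `"annotation"`, `"classical"`, `"external-model"`.
#' @return An object of class `segmentation_mask` with a logical `values`
#'   matrix.
#' @export
segmentation_mask <- function(values, frame_id = NA_character_,
                              source = c("annotation", "classical",
                                         "external-model")) {
  source <- match.arg(source)
  if (!is_binary_raster(values)) {
    stop("mask values must be a strictly binary matrix")
  }
  storage.mode(values) <- "logical"
  structure(list(values = values, frame_id = frame_id, source = source),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %s [%s]: %d / %d px foreground\n",
              x$frame_id, x$source, sum(x$values), length(x$values)))
  invisible(x)
}

#' Polygon annotation for one frame
#'
#' A closed ring of pixel-coordinate vertices (0-based, x rightward,
#' y downward), as produced by polygon annotation tools. Validated to have
#' at least 3 vertices and no self-intersections.
#'
#' @param vertices Two-column numeric matrix (x, y), one row per vertex;
#'   the closing edge back to the first vertex is implicit.
#' @param frame_id Frame identifier (quoted in error messages).
#' @param label Class label; default `"seaweed"`.
#' @return An object of class `annotation_polygon`.
#' @export
annotation_polygon <- function(vertices, frame_id = NA_character_,
                               label = "seaweed") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop(sprintf("frame %s: degenerate polygon (need >= 3 (x, y) vertices)",
                 frame_id))
  }
  storage.mode(vertices) <- "double"
  if (ring_self_intersects(vertices)) {
    stop(sprintf("frame %s: polygon ring is self-intersecting", frame_id))
  }
  structure(list(vertices = unname(vertices), frame_id = frame_id,
                 label = label),
            class = "annotation_polygon")
}

# Proper-crossing test between non-adjacent ring edges (shared endpoints of
# adjacent edges are not intersections).
ring_self_intersects <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  cross <- function(o, p, q) {
    (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    j <- (i + 2):jmax
    for (k in j) {
      d1 <- cross(a[i, ], b[i, ], a[k, ])
      d2 <- cross(a[i, ], b[i, ], b[k, ])
      d3 <- cross(a[k, ], b[k, ], a[i, ])
      d4 <- cross(a[k, ], b[k, ], b[i, ])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rasterize polygon annotations to a binary mask
#'
#' Even-odd (crossing-number) fill under the pixel-centers rule: a pixel
#' belongs to the mask when its center (integer coordinates) lies inside
#' the ring; boundaries are half-open so an axis-aligned `W x H` rectangle
#' covers exactly `W * H` pixels. Multiple polygons are unioned.
#'
#' @param polys List of [annotation_polygon()] objects (may be empty).
#' @param image_size Integer `c(width, height)`.
#' @param frame_id Identifier for the resulting mask.
#' @return A [segmentation_mask()] with `source = "annotation"`.
#' @export
rasterize_polygons <- function(polys, image_size, frame_id = NA_character_) {
  W <- as.integer(image_size[1]); H <- as.integer(image_size[2])
  mask <- matrix(FALSE, H, W)
  for (p in polys) {
    if (!inherits(p, "annotation_polygon")) {
      p <- annotation_polygon(p, frame_id = frame_id)
    }
    v <- p$vertices
    n <- nrow(v)
    x1 <- v[, 1]; y1 <- v[, 2]
    x2 <- v[c(2:n, 1), 1]; y2 <- v[c(2:n, 1), 2]
    for (row in 0:(H - 1)) {
      # edges whose half-open y-span covers the scanline through centers
      crosses <- (y1 > row) != (y2 > row)
      if (!any(crosses)) next
      xi <- x1[crosses] +
        (row - y1[crosses]) / (y2[crosses] - y1[crosses]) *
        (x2[crosses] - x1[crosses])
      xi <- sort(xi)
      # even-odd fill between successive crossings, half-open in x
      for (k in seq(1, length(xi) - 1, by = 2)) {
        lo <- max(ceiling(xi[k]), 0)
        hi <- min(ceiling(xi[k + 1]) - 1, W - 1)
        if (hi >= lo) mask[row + 1, (lo:hi) + 1] <- TRUE
      }
    }
  }
  segmentation_mask(mask, frame_id = frame_id, source = "annotation")
}

#' Intersection over union of two binary masks
#'
#' `|A & B| / |A | B|`. Two empty masks are defined to agree perfectly
#' (IoU = 1); an empty mask against a non-empty one scores 0.
#'
#' @param a,b [segmentation_mask()] objects (or binary matrices) of
#'   identical size.
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  av <- if (inherits(a, "segmentation_mask")) a$values else a
  bv <- if (inherits(b, "segmentation_mask")) b$values else b
  if (!identical(dim(av), dim(bv))) stop("mask size mismatch")
  uni <- sum(av | bv)
  if (uni == 0L) return(1.0)
  sum(av & bv) / uni
}

#' Classical color-index segmentation
#'
#' A deterministic, training-free segmenter for synthetic scenes: kelp
#' blades reflect more red than blue while the open-water airlight veil is
#' strongly blue, so thresholding the per-pixel red-minus-blue index
#' separates sheet from water even under heavy haze (haze moves both
#' classes toward the airlight index but preserves their order).
#' Morphological opening and closing with a square kernel removes
#' salt-and-pepper noise flips, and connected components below a minimum
#' pixel area are discarded.
#'
#' This is a stand-in for a trained CNN segmenter on field imagery, where
#' lighting varies far beyond what a fixed color index can separate; plug
#' real models in through [external_segmenter_hook()].
#'
#' @param rgb_frame 8-bit H x W x 3 integer array.
#' @param index_threshold Red-minus-blue threshold (intensity units);
#'   pixels strictly above it are foreground. The default -60 sits between
#'   the airlight index (-80 for the default water color) and the fully
#'   hazed sheet index.
#' @param kernel_size Edge of the square morphology kernel (odd).
#' @param min_area Minimum connected-component area in pixels.
#' @param frame_id Identifier for the resulting mask.
#' @return A [segmentation_mask()] with `source = "classical"`.
#' @export
classical_segment <- function(rgb_frame, index_threshold = -60,
                              kernel_size = 3L, min_area = 50L,
                              frame_id = NA_character_) {
  stopifnot(length(dim(rgb_frame)) == 3L, dim(rgb_frame)[3] >= 3L)
  idx <- rgb_frame[, , 1] - rgb_frame[, , 3]
  mask <- idx > index_threshold
  if (any(mask)) {
    kern <- EBImage::makeBrush(as.integer(kernel_size), shape = "box")
    img <- EBImage::Image(t(mask) * 1)  # EBImage is column-major (x, y)
    img <- EBImage::closing(EBImage::opening(img, kern), kern)
    lab <- EBImage::bwlabel(img)
    counts <- table(lab[lab > 0])
    keep <- as.integer(names(counts)[counts >= min_area])
    mask <- t(matrix(as.integer(lab) %in% keep, nrow = nrow(lab)))
  }
  segmentation_mask(mask, frame_id = frame_id, source = "classical")
}

#' Run an external segmentation model on one frame
#'
#' Contract for slotting a trained model (e.g. an encoder-decoder CNN) into
#' the pipeline: `command_spec` names an executable that is called as
#' `command args... <frame_png> <mask_png>` and must write a binary
#' (0/255) mask PNG of the same size as the frame. The mask is validated
#' on load; failures raise an error carrying the frame id so the pipeline
#' can flag the frame and continue.
#'
#' @param frame_png Path to the input RGB frame.
#' @param command_spec List with `command` (executable path/name) and
#'   optional `args` (character vector inserted before the input/output
#'   paths). Checked for existence up front.
#' @param frame_id Identifier for the resulting mask.
#' @return A [segmentation_mask()] with `source = "external-model"`.
#' @export
external_segmenter_hook <- function(frame_png, command_spec,
                                    frame_id = NA_character_) {
  if (is.null(command_spec$command) ||
      (Sys.which(command_spec$command) == "" &&
       !file.exists(command_spec$command))) {
    stop("external segmenter not found: ",
         if (is.null(command_spec$command)) "<missing command>"
         else command_spec$command)
  }
  out_png <- tempfile(fileext = ".png")
  on.exit(unlink(out_png))
  status <- suppressWarnings(system2(
    command_spec$command,
    c(command_spec$args, shQuote(frame_png), shQuote(out_png)),
    stdout = FALSE, stderr = FALSE))
  if (status != 0L || !file.exists(out_png)) {
    stop(sprintf("frame %s: external segmenter exited with status %d",
                 frame_id, status))
  }
  mask <- read_gray_png(out_png)
  frame <- png::readPNG(frame_png)
  fdim <- dim(frame)[1:2]
  if (!identical(dim(mask), fdim)) {
    stop(sprintf("frame %s: external mask size %dx%d != frame %dx%d",
                 frame_id, ncol(mask), nrow(mask), fdim[2], fdim[1]))
  }
  if (!all(mask %in% c(0L, 255L))) {
    stop(sprintf("frame %s: external mask is not binary 0/255", frame_id))
  }
  segmentation_mask(mask == 255L, frame_id = frame_id,
                    source = "external-model")
}

#' Import polygon annotations from CVAT XML 1.1
#'
#' Reads the `<image ...><polygon label=... points="x1,y1;x2,y2;..."/>`
#' dialect exported by the CVAT annotation tool. Import-only: internal
#' storage is the plain [annotation_polygon()] schema.
#'
#' @param path XML file path.
#' @param label Keep only polygons with this label; `NULL` keeps all.
#' @return Named list (by frame name) of lists of [annotation_polygon()].
#' @export
read_cvat_polygons <- function(path, label = NULL) {
  doc <- xml2::read_xml(path)
  images <- xml2::xml_find_all(doc, ".//image")
  out <- list()
  for (img in images) {
    fid <- xml2::xml_attr(img, "name")
    polys <- list()
    for (pg in xml2::xml_find_all(img, "./polygon")) {
      lab <- xml2::xml_attr(pg, "label")
      if (!is.null(label) && !identical(lab, label)) next
      pts <- strsplit(xml2::xml_attr(pg, "points"), ";")[[1]]
      xy <- do.call(rbind, lapply(strsplit(pts, ","), as.numeric))
      polys[[length(polys) + 1L]] <-
        annotation_polygon(xy, frame_id = fid, label = lab)
    }
    out[[fid]] <- polys
  }
  out
}

#' Write/read polygons in the package's JSON schema
#'
#' @param polys List of [annotation_polygon()].
#' @param path JSON path.
#' @return `write_polygons_json` returns `path` invisibly;
#'   `read_polygons_json` returns a list of [annotation_polygon()].
#' @export
write_polygons_json <- function(polys, path) {
  jsonlite::write_json(lapply(polys, function(p) {
    list(frame_id = p$frame_id, label = p$label,
         vertices = p$vertices)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_json
#' @export
read_polygons_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(p) {
    v <- p$vertices
    if (!is.matrix(v)) v <- do.call(rbind, lapply(v, unlist))
    annotation_polygon(v, frame_id = p$frame_id, label = p$label)
  })
}

#' Write a mask as an 8-bit 0/255 PNG
#'
#' @param mask A [segmentation_mask()].
#' @param path PNG path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  png::writePNG(to_unit(mask$values * 255), path)
  invisible(path)
}

#' Read a 0/255 PNG as a segmentation mask
#'
#' @param path PNG path.
#' @inheritParams segmentation_mask
#' @return A [segmentation_mask()].
#' @export
read_mask_png <- function(path, frame_id = NA_character_,
                          source = "annotation") {
  m <- read_gray_png(path)
  segmentation_mask(m >= 128L, frame_id = frame_id, source = source)
}
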