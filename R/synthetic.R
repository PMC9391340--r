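#' Specification for a synthetic annotated slide
#'
#' Describes a fake brightfield slide: stained-tissue blobs on a white
#' background carrying colored, blob-shaped target objects of one or more
#' classes. The same spec and seed always produce bit-identical pixels and
#' ground-truth polygons, making the generator usable as a deterministic
#' fixture for every stage of the pipeline (masking, sampling, training,
#' inference, evaluation).
#'
#' Default conditions: a 1024 x 1024 base image, three tissue blobs, and two
#' object classes ("glomerulus": 12 round objects 40-80 px across;
#' "artery": 8 objects 24-50 px across) in colors separable from the tissue
#' background, mimicking darkly stained structures in a lightly stained
#' cortex.
#'
#' @param base_width,base_height base-resolution size in px
#' @param classes data.frame with columns `name`, `count`, `min_size`,
#'   `max_size` (object diameter range, px) and `color` (hex)
#' @param tissue_blobs number of tissue regions
#' @param tissue_radius numeric `c(min, max)` blob radius in px; `NULL`
#'   (default) scales with the slide: 15-25% of the shorter side
#' @param tissue_color,background hex colors (background is white)
#' @param levels integer downsample factors of the pyramid (must start at 1)
#' @param mpp microns per pixel at base resolution
#' @param seed integer RNG seed
#' @return an object of class `synthetic_slide_spec`
#' @export
synthetic_slide_spec <- function(base_width = 1024, base_height = 1024,
                                 classes = default_synthetic_classes(),
                                 tissue_blobs = 3,
                                 tissue_radius = NULL,
                                 tissue_color = "#EECDD5",
                                 background = "#FFFFFF",
                                 levels = c(1L, 2L, 4L),
                                 mpp = 0.25,
                                 seed = 1L) {
  stopifnot(is.data.frame(classes),
            all(c("name", "count", "min_size", "max_size", "color") %in% names(classes)),
            levels[1] == 1L, !is.unsorted(levels, strictly = TRUE))
  tissue_radius <- tissue_radius %||%
    (c(0.15, 0.25) * min(base_width, base_height))
  structure(
    list(base_width = as.integer(base_width), base_height = as.integer(base_height),
         classes = classes, tissue_blobs = as.integer(tissue_blobs),
         tissue_radius = tissue_radius, tissue_color = tissue_color,
         background = background, levels = as.integer(levels),
         mpp = mpp, seed = as.integer(seed)),
    class = "synthetic_slide_spec"
  )
}

#' @rdname synthetic_slide_spec
#' @export
default_synthetic_classes <- function() {
  data.frame(
    name = c("glomerulus", "artery"),
    count = c(12L, 8L),
    min_size = c(40, 24),
    max_size = c(80, 50),
    color = c("#6A4A93", "#B14A4A"),
    stringsAsFactors = FALSE
  )
}

hex_to_rgb01 <- function(hex) as.numeric(grDevices::col2rgb(hex)) / 255

# Smooth star-convex blob polygon: an ellipse with low-order radial wobble.
blob_polygon <- function(cx, cy, rx, ry, rot = 0, wobble = 0.08, n = 48L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- 1 + wobble * (stats::runif(1, -1, 1) * cos(2 * th + stats::runif(1, 0, 2 * pi)) +
                     stats::runif(1, -1, 1) * cos(3 * th + stats::runif(1, 0, 2 * pi)))
  ex <- rx * r * cos(th); ey <- ry * r * sin(th)
  cbind(x = cx + ex * cos(rot) - ey * sin(rot),
        y = cy + ex * sin(rot) + ey * cos(rot))
}

paint_polygon <- function(img, ring, color) {
  bb <- c(floor(min(ring[, 1])), floor(min(ring[, 2])),
          ceiling(max(ring[, 1])), ceiling(max(ring[, 2])))
  bb[1] <- max(bb[1], 0); bb[2] <- max(bb[2], 0)
  bb[3] <- min(bb[3], ncol(img)); bb[4] <- min(bb[4], nrow(img))
  w <- bb[3] - bb[1]; h <- bb[4] - bb[2]
  if (w < 1 || h < 1) return(img)
  fill <- rasterize_ring(ring[, 1] - bb[1], ring[, 2] - bb[2], w, h)
  rows <- (bb[2] + 1L):bb[4]; cols <- (bb[1] + 1L):bb[3]
  for (k in 1:3) {
    ch <- img[rows, cols, k]
    ch[fill] <- color[k]
    img[rows, cols, k] <- ch
  }
  img
}

#' Generate a synthetic annotated slide
#'
#' Draws the slide described by a [synthetic_slide_spec()] and returns both
#' the pyramid and the ground-truth annotations. Object polygons are placed
#' entirely inside tissue blobs (and do not overlap each other); each object
#' is painted by rasterizing exactly the polygon stored in the annotation
#' document, so drawn pixel counts match the polygon rasterization by
#' construction. Pixel values are quantized to the 8-bit grid so the
#' in-memory pyramid equals what [write_slide()] stores on disk.
#'
#' @param spec a [synthetic_slide_spec()]
#' @param path optional file path; when given the pyramid is also written as
#'   a multi-page TIFF
#' @param max_tries placement attempts per object before failing
#' @return list with `slide` (a [slide_pyramid()]) and `doc`
#'   (an [annotation_document()] with one layer per class)
#' @export
generate_synthetic_slide <- function(spec, path = NULL, max_tries = 400L) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  w <- spec$base_width; h <- spec$base_height
  img <- array(rep(hex_to_rgb01(spec$background), each = h * w), c(h, w, 3L))
  tissue <- matrix(FALSE, h, w)
  tcol <- hex_to_rgb01(spec$tissue_color)

  for (b in seq_len(spec$tissue_blobs)) {
    r <- stats::runif(1, spec$tissue_radius[1], spec$tissue_radius[2])
    rmax <- r * 1.2  # wobble + aspect headroom
    if (2 * rmax >= min(w, h))
      stopf("tissue radius %g does not fit a %d x %d slide", r, w, h)
    cx <- stats::runif(1, rmax, w - rmax)
    cy <- stats::runif(1, rmax, h - rmax)
    ring <- blob_polygon(cx, cy, r, r * stats::runif(1, 0.7, 1), stats::runif(1, 0, pi))
    fill <- rasterize_ring(ring[, 1], ring[, 2], w, h)
    tissue <- tissue | fill
    for (k in 1:3) { ch <- img[, , k]; ch[fill] <- tcol[k]; img[, , k] <- ch }
  }

  occupied <- matrix(FALSE, h, w)
  layers <- stats::setNames(vector("list", nrow(spec$classes)), spec$classes$name)
  for (ci in seq_len(nrow(spec$classes))) {
    cls <- spec$classes[ci, ]
    ccol <- hex_to_rgb01(cls$color)
    layers[[cls$name]] <- list()
    for (obj in seq_len(cls$count)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        dia <- stats::runif(1, cls$min_size, cls$max_size)
        rx <- dia / 2; ry <- rx * stats::runif(1, 0.65, 1)
        cx <- stats::runif(1, rx, w - rx)
        cy <- stats::runif(1, rx, h - rx)
        ring <- blob_polygon(cx, cy, rx, ry, stats::runif(1, 0, pi), wobble = 0.06)
        fill <- rasterize_ring(ring[, 1], ring[, 2], w, h)
        if (!any(fill)) next
        if (all(tissue[fill]) && !any(occupied[fill])) {
          occupied <- occupied | fill
          for (k in 1:3) { ch <- img[, , k]; ch[fill] <- ccol[k]; img[, , k] <- ch }
          layers[[cls$name]] <- c(layers[[cls$name]],
                                  list(polygon_annotation(ring, cls$name)))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("could not place object %d of class '%s' inside tissue", obj, cls$name)
    }
  }

  img <- round(img * 255) / 255
  levels <- lapply(spec$levels, function(f) round(block_downsample(img, f) * 255) / 255)
  slide_id <- sprintf("synthetic-seed%d", spec$seed)
  slide <- slide_pyramid(levels, slide_id = slide_id, mpp = spec$mpp)
  palette <- stats::setNames(spec$classes$color, spec$classes$name)
  doc <- annotation_document(layers, slide_id = slide_id, palette = palette)
  if (!is.null(path)) write_slide(slide, path)
  list(slide = slide, doc = doc)
}
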