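#' Polygon annotation
#'
#' A closed polygon in base-resolution pixel coordinates. The first vertex is
#' implicitly joined to the last; at least three vertices are required. The
#' bounding box is derived from the vertex extrema and carried along so that
#' rasterization can skip polygons that do not intersect a requested region.
#'
#' @param vertices numeric n x 2 matrix of (x, y) coordinates, n >= 3
#' @param class_label character class name
#' @return an object of class `slide_polygon`
#' @export
polygon_annotation <- function(vertices, class_label) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stopf("a polygon needs a numeric n x 2 vertex matrix with n >= 3")
  if (anyNA(vertices)) stopf("polygon vertices contain NA")
  colnames(vertices) <- c("x", "y")
  structure(
    list(
      vertices = vertices,
      class_label = as.character(class_label),
      bbox = c(
        min_x = min(vertices[, 1]), min_y = min(vertices[, 2]),
        max_x = max(vertices[, 1]), max_y = max(vertices[, 2])
      )
    ),
    class = "slide_polygon"
  )
}

#' @export
print.slide_polygon <- function(x, ...) {
  cat(sprintf(
    "<slide_polygon> class '%s', %d vertices, bbox [%.1f, %.1f] x [%.1f, %.1f]\n",
    x$class_label, nrow(x$vertices),
    x$bbox["min_x"], x$bbox["max_x"], x$bbox["min_y"], x$bbox["max_y"]
  ))
  invisible(x)
}

#' Annotation document
#'
#' Named annotation layers, each holding class-labelled polygons in base
#' coordinates. Every polygon's class label must match the name of its layer
#' (layers double as classes, as in slide-viewer annotation layers). Layer
#' order is meaningful: during rasterization later layers overwrite earlier
#' ones where polygons overlap.
#'
#' @param layers named list; each element a list of [polygon_annotation()]s
#' @param slide_id character identifier of the slide the annotations refer to
#' @param palette optional named character vector of display colors per layer
#' @return an object of class `annotation_document`
#' @export
annotation_document <- function(layers = list(), slide_id = "", palette = NULL) {
  if (length(layers)) {
    if (is.null(names(layers)) || anyDuplicated(names(layers)))
      stopf("annotation layers must have unique names")
    for (nm in names(layers)) {
      for (p in layers[[nm]]) {
        if (!inherits(p, "slide_polygon"))
          stopf("layer '%s' contains a non-polygon element", nm)
        if (p$class_label != nm)
          stopf("polygon with class '%s' found in layer '%s'", p$class_label, nm)
      }
    }
  }
  structure(
    list(layers = layers, slide_id = as.character(slide_id), palette = palette),
    class = "annotation_document"
  )
}

#' @export
print.annotation_document <- function(x, ...) {
  cat(sprintf("<annotation_document> slide '%s', %d layer(s)\n",
              x$slide_id, length(x$layers)))
  for (nm in names(x$layers))
    cat(sprintf("  %s: %d polygon(s)\n", nm, length(x$layers[[nm]])))
  invisible(x)
}

#' Number of polygons per layer
#' @param doc an [annotation_document()]
#' @return named integer vector
#' @export
layer_sizes <- function(doc) {
  vapply(doc$layers, length, integer(1))
}

# Even-odd scanline fill of one closed ring in local 0-based pixel
# coordinates. A pixel is filled when its center (col + 0.5, row + 0.5) lies
# inside the ring under the even-odd rule; crossings use half-open edge
# intervals so shared edges between adjacent polygons are not double-filled.
rasterize_ring <- function(vx, vy, w, h) {
  out <- matrix(FALSE, h, w)
  if (h < 1L || w < 1L) return(out)
  n <- length(vx)
  x1 <- vx; y1 <- vy
  x2 <- vx[c(2:n, 1L)]; y2 <- vy[c(2:n, 1L)]
  keep <- y1 != y2                      # horizontal edges never cross a scanline
  if (!any(keep)) return(out)
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  j0 <- max(0L, floor(min(c(y1, y2)) - 0.5))
  j1 <- min(h - 1L, ceiling(max(c(y1, y2))))
  if (j1 < j0) return(out)
  for (j in j0:j1) {
    yc <- j + 0.5
    cross <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(cross)) next
    xs <- sort(x1[cross] + (yc - y1[cross]) * (x2[cross] - x1[cross]) / (y2[cross] - y1[cross]))
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      # columns whose centers fall in [xs[k], xs[k+1])
      i_lo <- max(0L, ceiling(xs[k] - 0.5))
      i_hi <- min(w - 1L, ceiling(xs[k + 1L] - 0.5) - 1L)
      if (i_hi >= i_lo) out[j + 1L, (i_lo:i_hi) + 1L] <- TRUE
    }
  }
  out
}

bbox_intersects <- function(bbox, x, y, w, h) {
  bbox["max_x"] > x && bbox["min_x"] < x + w &&
    bbox["max_y"] > y && bbox["min_y"] < y + h
}

#' Rasterize annotation polygons into a label mask
#'
#' Renders the polygons of an [annotation_document()] that intersect a
#' rectangular region of the slide into an integer label raster. Only
#' polygons whose bounding box intersects the region are considered (the
#' bounding-box index is a pure speed-up; it never changes the result).
#' Layers are drawn in document order and later layers overwrite earlier
#' ones where polygons overlap. The fill rule is even-odd on pixel centers.
#'
#' @param doc an [annotation_document()]
#' @param region numeric `c(x, y, w, h)` in base-resolution pixels
#' @param downsample positive scale factor; the output raster has dimensions
#'   `floor(h / downsample)` x `floor(w / downsample)`
#' @param class_map named integer vector mapping layer name to label value
#'   (> 0); layers absent from `class_map` raise an error when requested
#' @param layers layer names to draw, default all layers named in `class_map`
#'   that exist in the document
#' @param init optional existing integer matrix to draw onto
#' @return integer label matrix; 0 where no polygon covers the pixel
#' @export
rasterize_annotations <- function(doc, region, downsample = 1, class_map,
                                  layers = NULL, init = NULL) {
  stopifnot(length(region) == 4L, downsample > 0)
  x <- region[1]; y <- region[2]; w <- region[3]; h <- region[4]
  out_w <- floor(w / downsample); out_h <- floor(h / downsample)
  if (is.null(layers)) layers <- intersect(names(doc$layers), names(class_map))
  missing_layers <- setdiff(layers, names(doc$layers))
  if (length(missing_layers))
    stopf("unknown annotation layer(s): %s", paste(missing_layers, collapse = ", "))
  unmapped <- setdiff(layers, names(class_map))
  if (length(unmapped))
    stopf("class_map does not cover layer(s): %s", paste(unmapped, collapse = ", "))
  mask <- if (is.null(init)) matrix(0L, out_h, out_w) else init
  stopifnot(nrow(mask) == out_h, ncol(mask) == out_w)
  for (nm in layers) {
    val <- as.integer(class_map[[nm]])
    for (p in doc$layers[[nm]]) {
      if (!bbox_intersects(p$bbox, x, y, w, h)) next
      fill <- rasterize_ring(
        (p$vertices[, 1] - x) / downsample,
        (p$vertices[, 2] - y) / downsample,
        out_w, out_h
      )
      mask[fill] <- val
    }
  }
  mask
}

#' Rasterize an annotation region (mask-from-contours)
#'
#' Thin alias of [rasterize_annotations()] matching the historical
#' contours-to-mask naming used by slide annotation pipelines.
#' @inheritParams rasterize_annotations
#' @export
xml_to_mask <- function(doc, region, downsample = 1, class_map, layers = NULL) {
  rasterize_annotations(doc, region, downsample, class_map, layers)
}

# Trace one connected component (logical matrix) into a polygon ring.
# EBImage::ocontour yields 0-based boundary pixel indices; vertices are
# placed at boundary-pixel centers and pushed 0.5 px outward from the
# component centroid so that re-rasterization recovers the boundary pixels
# of blob-like (roughly star-convex) components.
trace_component <- function(bw) {
  oc <- EBImage::ocontour(EBImage::Image(t(bw)))[[1]]
  cx <- oc[, 1] + 0.5
  cy <- oc[, 2] + 0.5
  mx <- mean(cx); my <- mean(cy)
  dx <- cx - mx; dy <- cy - my
  nrm <- sqrt(dx^2 + dy^2)
  nrm[nrm == 0] <- 1
  cbind(x = cx + 0.5 * dx / nrm, y = cy + 0.5 * dy / nrm)
}

#' Vectorize a label mask into polygon annotations
#'
#' The inverse of [rasterize_annotations()]: extracts one polygon per
#' connected component per class and transforms vertices back to base
#' resolution (`base = origin + scale * local`). Components smaller than
#' `min_size` pixels are dropped. The round trip mask -> polygons -> mask is
#' approximate at the one-pixel boundary level, which for blob-like objects
#' keeps the pixel overlap (IoU) above 0.98.
#'
#' @param mask integer label matrix
#' @param origin numeric `c(x, y)` base-resolution offset of mask pixel (0,0)
#' @param scale factor from mask pixels to base pixels
#' @param class_map named integer vector (layer name -> label value); every
#'   non-zero label present in `mask` must appear among its values
#' @param slide_id slide identifier stored in the output document
#' @param min_size minimum component pixel count, default 3
#' @return an [annotation_document()]
#' @export
mask_to_annotations <- function(mask, origin = c(0, 0), scale = 1, class_map,
                                slide_id = "", min_size = 3L) {
  vals <- sort(setdiff(unique(as.integer(mask)), 0L))
  bad <- setdiff(vals, as.integer(class_map))
  if (length(bad))
    stopf("mask labels not in class_map: %s", paste(bad, collapse = ", "))
  layers <- stats::setNames(
    vector("list", length(class_map)), names(class_map)
  )
  for (nm in names(class_map)) {
    layers[[nm]] <- list()
    val <- as.integer(class_map[[nm]])
    if (!val %in% vals) next
    lab <- EBImage::bwlabel(EBImage::Image(t(mask == val)))
    lab <- t(EBImage::imageData(lab))
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      if (sum(comp) < min_size) next
      ring <- trace_component(comp)
      if (nrow(ring) < 3L) next
      verts <- cbind(origin[1] + scale * ring[, 1], origin[2] + scale * ring[, 2])
      layers[[nm]] <- c(layers[[nm]], list(polygon_annotation(verts, nm)))
    }
  }
  annotation_document(layers, slide_id = slide_id)
}

#' @rdname mask_to_annotations
#' @export
mask_to_xml <- mask_to_annotations
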