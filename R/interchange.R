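#' Write annotations as ImageScope-compatible XML
#'
#' Serializes an [annotation_document()] in the Aperio-style dialect
#' `Annotations/Annotation/Regions/Region/Vertices/Vertex`, with vertex
#' coordinates as `X`/`Y` attributes at base resolution. Each layer becomes
#' one `Annotation` element; polygon bounding boxes are stored as
#' `MinX`/`MinY`/`MaxX`/`MaxY` attributes on each `Region` so readers can
#' index which contours fall inside a requested region without parsing
#' vertices. Coordinates are printed with 17 significant digits, so
#' write-then-read reproduces the document exactly.
#'
#' @param doc an [annotation_document()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_aperio_xml <- function(doc, path) {
  stopifnot(inherits(doc, "annotation_document"))
  root <- xml2::xml_new_root("Annotations")
  if (nzchar(doc$slide_id)) xml2::xml_set_attr(root, "SlideId", doc$slide_id)
  num <- function(x) sprintf("%.17g", x)
  for (i in seq_along(doc$layers)) {
    nm <- names(doc$layers)[i]
    ann <- xml2::xml_add_child(root, "Annotation", Id = as.character(i), Name = nm)
    if (!is.null(doc$palette) && nm %in% names(doc$palette))
      xml2::xml_set_attr(ann, "LineColor", doc$palette[[nm]])
    regions <- xml2::xml_add_child(ann, "Regions")
    for (j in seq_along(doc$layers[[i]])) {
      p <- doc$layers[[i]][[j]]
      reg <- xml2::xml_add_child(
        regions, "Region", Id = as.character(j),
        MinX = num(p$bbox[["min_x"]]), MinY = num(p$bbox[["min_y"]]),
        MaxX = num(p$bbox[["max_x"]]), MaxY = num(p$bbox[["max_y"]])
      )
      verts <- xml2::xml_add_child(reg, "Vertices")
      for (k in seq_len(nrow(p$vertices))) {
        xml2::xml_add_child(verts, "Vertex",
                            X = num(p$vertices[k, 1]), Y = num(p$vertices[k, 2]))
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read ImageScope-compatible XML annotations
#'
#' Parses the dialect written by [write_aperio_xml()]. Layer order follows
#' element order; the polygon class label is the layer (`Annotation`) name.
#' Stored bounding-box attributes are checked against the vertex extrema.
#'
#' @param path XML file path
#' @return an [annotation_document()]
#' @export
read_aperio_xml <- function(path) {
  x <- tryCatch(xml2::read_xml(path),
                error = function(e) stopf("malformed XML in '%s': %s", path, conditionMessage(e)))
  if (xml2::xml_name(x) != "Annotations")
    stopf("expected <Annotations> root element, found <%s>", xml2::xml_name(x))
  layers <- list()
  palette <- character()
  for (ann in xml2::xml_find_all(x, "./Annotation")) {
    nm <- xml2::xml_attr(ann, "Name")
    if (is.na(nm)) stopf("<Annotation> element without Name attribute")
    col <- xml2::xml_attr(ann, "LineColor")
    if (!is.na(col)) palette[nm] <- col
    polys <- list()
    for (reg in xml2::xml_find_all(ann, "./Regions/Region")) {
      vnodes <- xml2::xml_find_all(reg, "./Vertices/Vertex")
      if (!length(vnodes))
        stopf("<Region Id='%s'> in layer '%s' has no <Vertices>",
              xml2::xml_attr(reg, "Id"), nm)
      verts <- cbind(as.numeric(xml2::xml_attr(vnodes, "X")),
                     as.numeric(xml2::xml_attr(vnodes, "Y")))
      if (anyNA(verts))
        stopf("non-numeric <Vertex> coordinates in layer '%s'", nm)
      polys <- c(polys, list(polygon_annotation(verts, nm)))
    }
    layers[[nm]] <- polys
  }
  annotation_document(layers,
                      slide_id = xml2::xml_attr(x, "SlideId") %||% "",
                      palette = if (length(palette)) palette else NULL)
}

#' Sparse heatmap layer
#'
#' A sparse set of per-pixel class probabilities at a stated scale factor
#' relative to base resolution. Only entries above the sparsification
#' threshold used to build the layer are stored.
#'
#' @param points data.frame/tibble with columns `x`, `y` (0-based pixel
#'   indices at the layer scale) and `value` in [0, 1]
#' @param class_label class the probabilities refer to
#' @param scale_factor layer scale relative to base resolution
#' @return an object of class `heatmap_layer`
#' @export
heatmap_layer <- function(points, class_label, scale_factor) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y", "value") %in% names(points)))
  if (nrow(points) && (min(points$value) < 0 || max(points$value) > 1))
    stopf("heatmap values must lie in [0, 1]")
  structure(list(points = points, class_label = as.character(class_label),
                 scale_factor = scale_factor),
            class = "heatmap_layer")
}

#' @export
print.heatmap_layer <- function(x, ...) {
  cat(sprintf("<heatmap_layer> class '%s', %d entries @ scale %g\n",
              x$class_label, nrow(x$points), x$scale_factor))
  invisible(x)
}

#' JSON annotation interchange
#'
#' `to_json()` serializes an [annotation_document()] or [heatmap_layer()]
#' into the package's versioned JSON schema; `from_json()` parses it back.
#' The round trip is the identity. Heatmap point coordinates are up-sampled
#' to base resolution in the JSON (`x_base = (x + 0.5) * scale_factor`), so
#' viewers can place them without knowing the prediction scale; the scale
#' factor is retained so `from_json()` restores layer-scale indices.
#'
#' Document schema (version 1):
#' \preformatted{{"schema": "slideseg-annotation", "version": 1,
#'   "slide_id": "...",
#'   "layers": [{"name": "...", "color": "#...", "polygons":
#'      [{"vertices": [[x, y], ...]}]}]}}
#' Heatmap schema (version 1):
#' \preformatted{{"schema": "slideseg-heatmap", "version": 1, "class": "...",
#'   "scale_factor": s, "points": [[x_base, y_base, value], ...]}}
#'
#' @param x an [annotation_document()] or [heatmap_layer()]
#' @return `to_json()`: a JSON string; `from_json()`: the parsed object
#' @export
to_json <- function(x) UseMethod("to_json")

#' @export
to_json.annotation_document <- function(x) {
  layers <- lapply(seq_along(x$layers), function(i) {
    nm <- names(x$layers)[i]
    list(
      name = jsonlite::unbox(nm),
      color = jsonlite::unbox(
        if (!is.null(x$palette) && nm %in% names(x$palette)) x$palette[[nm]] else NA
      ),
      polygons = lapply(x$layers[[i]], function(p) list(vertices = unname(p$vertices)))
    )
  })
  jsonlite::toJSON(
    list(schema = jsonlite::unbox("slideseg-annotation"),
         version = jsonlite::unbox(1L),
         slide_id = jsonlite::unbox(x$slide_id),
         layers = layers),
    digits = NA, null = "null", na = "null"
  )
}

#' @export
to_json.heatmap_layer <- function(x) {
  pts <- cbind((x$points$x + 0.5) * x$scale_factor,
               (x$points$y + 0.5) * x$scale_factor,
               x$points$value)
  jsonlite::toJSON(
    list(schema = jsonlite::unbox("slideseg-heatmap"),
         version = jsonlite::unbox(1L),
         class = jsonlite::unbox(x$class_label),
         scale_factor = jsonlite::unbox(x$scale_factor),
         points = pts),
    digits = NA
  )
}

json_abort <- function(path, msg) stopf("invalid annotation JSON at %s: %s", path, msg)

#' @rdname to_json
#' @param text JSON string (or path to a JSON file)
#' @export
from_json <- function(text) {
  if (length(text) == 1L && !grepl("^\\s*\\{", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  schema <- x$schema %||% json_abort("$.schema", "missing")
  if (schema == "slideseg-annotation") {
    layers <- list()
    palette <- character()
    for (i in seq_along(x$layers)) {
      ly <- x$layers[[i]]
      nm <- ly$name %||% json_abort(sprintf("$.layers[%d].name", i), "missing")
      if (!is.null(ly$color) && !is.na(ly$color)) palette[nm] <- ly$color
      polys <- lapply(seq_along(ly$polygons), function(j) {
        v <- ly$polygons[[j]]$vertices %||%
          json_abort(sprintf("$.layers[%d].polygons[%d].vertices", i, j), "missing")
        polygon_annotation(do.call(rbind, lapply(v, unlist)), nm)
      })
      layers[[nm]] <- polys
    }
    annotation_document(layers, slide_id = x$slide_id %||% "",
                        palette = if (length(palette)) palette else NULL)
  } else if (schema == "slideseg-heatmap") {
    sf <- x$scale_factor %||% json_abort("$.scale_factor", "missing")
    pts <- do.call(rbind, lapply(x$points, unlist))
    if (is.null(pts)) pts <- matrix(numeric(), 0, 3)
    heatmap_layer(
      tibble::tibble(x = pts[, 1] / sf - 0.5, y = pts[, 2] / sf - 0.5,
                     value = pts[, 3]),
      class_label = x$class %||% json_abort("$.class", "missing"),
      scale_factor = sf
    )
  } else {
    json_abort("$.schema", sprintf("unknown schema '%s'", schema))
  }
}
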