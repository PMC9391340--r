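square_doc <- function(x0, y0, x1, y1, label = "A") {
  annotation_document(stats::setNames(list(list(polygon_annotation(
    rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)), label
  ))), label))
}

test_that("polygon and document constructors enforce their invariants", {
  expect_error(polygon_annotation(rbind(c(0, 0), c(1, 1)), "A"), "n >= 3")
  p <- polygon_annotation(rbind(c(2, 1), c(9, 3), c(4, 8)), "A")
  expect_equal(unname(p$bbox), c(2, 1, 9, 8))
  expect_error(annotation_document(list(B = list(p))), "found in layer")
  expect_error(annotation_document(stats::setNames(list(list(p), list(p)),
                                                   c("A", "A"))),
               "unique")
})

test_that("rasterization matches a brute-force point-in-polygon oracle", {
  doc <- square_doc(10, 10, 20, 20)
  m <- xml_to_mask(doc, c(0, 0, 32, 32), 1, c(A = 1L))
  oracle <- brute_force_fill(c(10, 20, 20, 10), c(10, 10, 20, 20), 32, 32)
  expect_identical(m == 1L, oracle)
  expect_equal(sum(m), 100)

  # irregular polygon, non-trivial region offset and downsample
  set.seed(4)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  vx <- 40 + (12 + runif(12, -4, 4)) * cos(th)
  vy <- 35 + (12 + runif(12, -4, 4)) * sin(th)
  doc2 <- annotation_document(list(A = list(polygon_annotation(cbind(vx, vy), "A"))))
  m2 <- xml_to_mask(doc2, c(20, 15, 48, 44), 1, c(A = 1L))
  oracle2 <- brute_force_fill(vx - 20, vy - 15, 48, 44)
  expect_identical(m2 == 1L, oracle2)

  # polygon entirely outside the region
  m3 <- xml_to_mask(square_doc(100, 100, 120, 120), c(0, 0, 32, 32), 1, c(A = 1L))
  expect_true(all(m3 == 0L))

  expect_error(xml_to_mask(doc, c(0, 0, 32, 32), 1, c(A = 1L), layers = "B"),
               "unknown annotation layer")
})

test_that("overlapping layers resolve by document order (later layer wins)", {
  pa <- polygon_annotation(rbind(c(5, 5), c(25, 5), c(25, 25), c(5, 25)), "A")
  pb <- polygon_annotation(rbind(c(15, 15), c(35, 15), c(35, 35), c(15, 35)), "B")
  doc <- annotation_document(list(A = list(pa), B = list(pb)))
  m <- xml_to_mask(doc, c(0, 0, 40, 40), 1, c(A = 1L, B = 2L))
  # oracle: enumerate pixels, apply precedence
  fa <- brute_force_fill(c(5, 25, 25, 5), c(5, 5, 25, 25), 40, 40)
  fb <- brute_force_fill(c(15, 35, 35, 15), c(15, 15, 35, 35), 40, 40)
  oracle <- matrix(0L, 40, 40)
  oracle[fa] <- 1L
  oracle[fb] <- 2L
  expect_identical(m, oracle)
})

test_that("rasterization is scale-consistent and the bbox index is a pure speed-up", {
  g <- fixture_small()
  cm <- c(glomerulus = 1L)
  m1 <- xml_to_mask(g$doc, c(0, 0, 384, 384), 1, cm)
  for (d in c(2, 4)) {
    md <- xml_to_mask(g$doc, c(0, 0, 384, 384), d, cm)
    # object bboxes at downsample d, upscaled by d, match base bboxes within d px
    doc_d <- mask_to_annotations(md, scale = d, class_map = cm)
    doc_1 <- mask_to_annotations(m1, scale = 1, class_map = cm)
    expect_length(doc_d$layers$glomerulus, length(doc_1$layers$glomerulus))
    bb_d <- sapply(doc_d$layers$glomerulus, function(p) p$bbox)
    bb_1 <- sapply(doc_1$layers$glomerulus, function(p) p$bbox)
    ord_d <- order(bb_d["min_x", ], bb_d["min_y", ])
    ord_1 <- order(bb_1["min_x", ], bb_1["min_y", ])
    expect_lt(max(abs(bb_d[, ord_d] - bb_1[, ord_1])), d + 1e-9)
  }

  # restricting to a sub-region (which engages the bbox skip) equals cropping
  full <- xml_to_mask(g$doc, c(0, 0, 384, 384), 1, cm)
  sub <- xml_to_mask(g$doc, c(100, 60, 150, 150), 1, cm)
  expect_identical(sub, full[61:210, 101:250])
})

test_that("mask vectorization inverts rasterization on blob-like components", {
  # all-zero raster -> empty layers
  empty <- mask_to_annotations(matrix(0L, 16, 16), class_map = c(A = 1L))
  expect_identical(unname(layer_sizes(empty)), 0L)

  # single filled square at scale 8: bbox spans ~80 px per side
  sq <- matrix(0L, 20, 20)
  sq[6:15, 6:15] <- 1L
  doc <- mask_to_annotations(sq, origin = c(0, 0), scale = 8, class_map = c(A = 1L))
  expect_length(doc$layers$A, 1L)
  bb <- doc$layers$A[[1]]$bbox
  expect_lt(abs((bb[["max_x"]] - bb[["min_x"]]) - 80), 8 + 1e-9)
  expect_lt(abs((bb[["max_y"]] - bb[["min_y"]]) - 80), 8 + 1e-9)

  # round trip on generated blobs: pixel agreement >= 0.98 per class
  g <- fixture_slide()
  cm <- fixture_class_map()
  mask <- xml_to_mask(g$doc, c(0, 0, 1024, 1024), 1, cm)
  back <- xml_to_mask(mask_to_annotations(mask, class_map = cm),
                      c(0, 0, 1024, 1024), 1, cm)
  for (v in cm)
    expect_gte(mask_iou(mask == v, back == v), 0.98)

  expect_error(mask_to_annotations(matrix(c(0L, 3L), 4, 4), class_map = c(A = 1L)),
               "not in class_map")
})

test_that("ImageScope XML round trips exactly, including bbox metadata", {
  # empty document -> Annotations root without children
  f <- withr::local_tempfile(fileext = ".xml")
  write_aperio_xml(annotation_document(slide_id = "s0"), f)
  x <- xml2::read_xml(f)
  expect_identical(xml2::xml_name(x), "Annotations")
  expect_length(xml2::xml_children(x), 0L)
  expect_identical(read_aperio_xml(f)$slide_id, "s0")

  # one triangle: 3 Vertex nodes, exact re-read
  tri <- polygon_annotation(rbind(c(1.25, 2.5), c(10.125, 2.5), c(5, 9.875)), "t")
  doc <- annotation_document(list(t = list(tri)), slide_id = "s1",
                             palette = c(t = "#FF0000"))
  write_aperio_xml(doc, f)
  x <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(x, "//Vertex"), 3L)
  doc2 <- read_aperio_xml(f)
  expect_equal(doc2, doc)
  expect_identical(doc2$layers$t[[1]]$vertices, tri$vertices)

  # bbox metadata survives in Region attributes
  reg <- xml2::xml_find_first(x, "//Region")
  expect_equal(as.numeric(xml2::xml_attr(reg, "MinX")), 1.25)
  expect_equal(as.numeric(xml2::xml_attr(reg, "MaxY")), 9.875)

  # full fixture document (irrational coordinates) round trips exactly
  g <- fixture_small()
  write_aperio_xml(g$doc, f)
  expect_equal(read_aperio_xml(f), g$doc)

  # malformed input names the problem
  writeLines("<Annotations><Annotation Name='a'><Regions><Region Id='1'/></Regions></Annotation></Annotations>", f)
  expect_error(read_aperio_xml(f), "no <Vertices>")
  writeLines("<Oops/>", f)
  expect_error(read_aperio_xml(f), "Annotations")
})

test_that("JSON interchange round trips documents and heatmaps", {
  empty_json <- to_json(annotation_document(slide_id = "e"))
  expect_match(as.character(empty_json), '"layers":\\s*\\[\\]')

  g <- fixture_small()
  doc2 <- from_json(to_json(g$doc))
  expect_equal(doc2, g$doc)

  hm <- heatmap_layer(tibble::tibble(x = c(1, 5, 7), y = c(2, 3, 9),
                                     value = c(0.2, 0.8, 1)),
                      "glomerulus", scale_factor = 8)
  hm2 <- from_json(to_json(hm))
  expect_equal(hm2, hm)
  expect_true(all(hm2$points$value >= 0 & hm2$points$value <= 1))
  expect_error(heatmap_layer(tibble::tibble(x = 1, y = 1, value = 1.4), "c", 8),
               "\\[0, 1\\]")

  expect_error(from_json('{"schema": "something-else"}'), "unknown schema")
  expect_error(from_json('{"schema": "slideseg-heatmap", "class": "c"}'),
               "scale_factor")
})
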