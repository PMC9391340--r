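# Shared fixtures, generated once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# default two-class synthetic slide + annotations
fixture_slide <- function() memo("default", {
  generate_synthetic_slide(synthetic_slide_spec(seed = 42L))
})

# small single-class slide for fast pixel-level work
fixture_small <- function() memo("small", {
  generate_synthetic_slide(synthetic_slide_spec(
    base_width = 384L, base_height = 384L, tissue_blobs = 1L,
    tissue_radius = c(110, 150),
    classes = data.frame(name = "glomerulus", count = 4L, min_size = 30,
                         max_size = 50, color = "#6A4A93",
                         stringsAsFactors = FALSE),
    seed = 13L
  ))
})

fixture_class_map <- function() c(glomerulus = 1L, artery = 2L)

fixture_tissue <- function() memo("tissue", {
  compute_tissue_mask(fixture_slide()$slide, cache_dir = FALSE)
})

# Prototype colors of the synthetic palette: background, tissue, then the
# two default object classes. Used to build color-oracle segmenters.
fixture_prototypes <- function() {
  to_rgb <- function(hex) as.numeric(grDevices::col2rgb(hex)) / 255
  rbind(c(1, 1, 1), to_rgb("#EECDD5"), to_rgb("#6A4A93"), to_rgb("#B14A4A"))
}

# Independent brute-force rasterization oracle: even-odd crossing test at
# every pixel center, one pixel at a time.
brute_force_fill <- function(vx, vy, w, h) {
  out <- matrix(FALSE, h, w)
  n <- length(vx)
  nxt <- c(2:n, 1L)
  for (j in seq_len(h)) {
    yc <- j - 0.5
    for (i in seq_len(w)) {
      xc <- i - 0.5
      inside <- FALSE
      for (e in seq_len(n)) {
        y1 <- vy[e]; y2 <- vy[nxt[e]]
        if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
          xint <- vx[e] + (yc - y1) * (vx[nxt[e]] - vx[e]) / (y2 - y1)
          if (xc < xint) inside <- !inside
        }
      }
      out[j, i] <- inside
    }
  }
  out
}

# IoU of two logical masks
mask_iou <- function(a, b) sum(a & b) / sum(a | b)

# Match predicted against ground-truth objects (lists of polygons) by
# rasterized IoU at a given downsample; returns object-level counts.
object_match <- function(pred_polys, gt_polys, extent, downsample = 8,
                         iou_threshold = 0.5) {
  rast <- function(p) {
    doc <- annotation_document(stats::setNames(list(list(p)), p$class_label))
    rasterize_annotations(doc, c(0, 0, extent[1], extent[2]), downsample,
                          stats::setNames(1L, p$class_label)) > 0
  }
  pm <- lapply(pred_polys, rast)
  gm <- lapply(gt_polys, rast)
  matched_gt <- logical(length(gm))
  tp <- 0L
  for (p in pm) {
    ious <- vapply(seq_along(gm), function(i)
      if (matched_gt[i]) 0 else mask_iou(p, gm[[i]]), numeric(1))
    if (length(ious) && max(ious) >= iou_threshold) {
      tp <- tp + 1L
      matched_gt[which.max(ious)] <- TRUE
    }
  }
  list(tp = tp, fp = length(pm) - tp, fn = sum(!matched_gt))
}
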