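make_tissue <- function(mask, downsample, base_w, base_h, id = "t") {
  slideseg:::new_tissue_mask(
    mask, downsample,
    list(slide_id = id, base_width = base_w, base_height = base_h)
  )
}

test_that("grid planning covers tissue with a stride lattice and skips background", {
  # tissue fits one patch
  m <- matrix(FALSE, 16, 16); m[4:8, 4:8] <- TRUE
  tis <- make_tissue(m, 32, 512, 512)
  cfg <- inference_config(patch_size = 256L, stride = 128L,
                          prediction_downsample = 2L, border_trim = 8L)
  plan <- plan_grid(tis, cfg)
  expect_identical(nrow(plan$origins), 1L)
  expect_identical(plan$origins[1, ], c(x = 0L, y = 0L))

  # empty mask -> empty plan
  plan0 <- plan_grid(make_tissue(matrix(FALSE, 16, 16), 32, 512, 512), cfg)
  expect_identical(nrow(plan0$origins), 0L)

  # tissue bbox 3000 x 1000 at prediction scale: lattice rule enumerable
  mw <- matrix(TRUE, 1000 %/% 8, 3000 %/% 8)
  tis2 <- make_tissue(mw, 16, 6000, 2000)
  cfg2 <- inference_config(patch_size = 2000L, stride = 1000L,
                           prediction_downsample = 2L)
  plan2 <- plan_grid(tis2, cfg2)
  xs_expected <- sort(unique(c(seq(0, 3000 - 2000, by = 1000), 1000)))
  expect_identical(sort(unique(plan2$origins[, "x"])), as.integer(xs_expected))
  expect_identical(unique(plan2$origins[, "y"]), 0L)
  expect_identical(nrow(plan2$origins), length(xs_expected))

  # row-major ordering
  g <- fixture_slide()
  planf <- plan_grid(fixture_tissue(),
                     inference_config(patch_size = 256L, stride = 128L,
                                      prediction_downsample = 2L,
                                      border_trim = 16L))
  o <- planf$origins
  expect_false(is.unsorted(order(o[, "y"], o[, "x"])))
})

test_that("overlap averaging is the unweighted mean of contributing patches", {
  # all-tissue toy slide, two overlapping patches along x
  tis <- make_tissue(matrix(TRUE, 8, 12), 8, 96, 64)
  cfg <- inference_config(patch_size = 32L, stride = 16L,
                          prediction_downsample = 1L, border_trim = 0L)
  # stateful model: returns constant logits 0, 1, 2, ... per call for class 1
  counter <- local({ n <- 0L; function() { n <<- n + 1L; n - 1L } })
  model <- patch_segmenter(function(img) {
    v <- counter()
    array(rep(c(v, 0), each = 32 * 32), c(32, 32, 2))
  }, n_classes = 2, stride = 1L)
  vol <- run_tiled_inference(slide_pyramid(list(array(0.5, c(64, 96, 3)))),
                             model, cfg, tis)
  # origins: x = 0, 16, 32, 48, 64; patches emit 0, 1, 2, 3, 4
  # column 20 (0-based) is covered by patches at x = 0 and 16 -> mean 0.5
  expect_equal(vol$data[10, 21, 1], 0.5)
  expect_identical(vol$counts[10, 21], 2L)
  # equal-valued overlap stays at that value: class-2 logits are all 0
  expect_equal(vol$data[10, 21, 2], 0)
})

test_that("tiled stitching equals a brute-force per-pixel accumulator", {
  g <- fixture_small()
  protos <- fixture_prototypes()[1:3, ]
  model <- color_prototype_segmenter(protos, stride = 4L)
  tis <- compute_tissue_mask(g$slide, downsample = 16, cache_dir = FALSE)
  cfg <- inference_config(patch_size = 96L, stride = 48L,
                          prediction_downsample = 2L, border_trim = 8L)
  vol <- run_tiled_inference(g$slide, model, cfg, tis)

  plan <- plan_grid(tis, cfg, align = 4L)
  os <- 4L; pd <- 2L
  lp <- cfg$patch_size %/% os
  trim <- cfg$border_trim %/% os
  vw <- plan$pred_width %/% os; vh <- plan$pred_height %/% os
  acc <- array(0, c(vh, vw, 3)); cnt <- matrix(0L, vh, vw)
  for (i in seq_len(nrow(plan$origins))) {
    ox <- plan$origins[i, 1]; oy <- plan$origins[i, 2]
    img <- read_region(g$slide, ox * pd, oy * pd,
                       cfg$patch_size * pd, cfg$patch_size * pd, pd)
    lg <- predict_logits(model, img)
    tl <- if (ox > 0) trim else 0L; tt <- if (oy > 0) trim else 0L
    tr <- if (ox + cfg$patch_size < plan$pred_width) trim else 0L
    tb <- if (oy + cfg$patch_size < plan$pred_height) trim else 0L
    for (r in seq_len(lp)) for (cc in seq_len(lp)) {
      if (r <= tt || r > lp - tb || cc <= tl || cc > lp - tr) next
      gy <- oy %/% os + r; gx <- ox %/% os + cc
      if (gy > vh || gx > vw) next
      acc[gy, gx, ] <- acc[gy, gx, ] + lg[r, cc, ]
      cnt[gy, gx] <- cnt[gy, gx] + 1L
    }
  }
  for (k in 1:3) {
    ch <- acc[, , k]
    ch[cnt > 0] <- ch[cnt > 0] / cnt[cnt > 0]
    acc[, , k] <- ch
  }
  expect_identical(vol$counts, cnt)
  expect_lt(max(abs(vol$data - acc)), 1e-6)
})

test_that("mask assembly applies argmax with deterministic tie-breaking at 1/8 scale", {
  # defaults: prediction downsample 2 x decoder stride 4 -> 1/8 of base
  g <- fixture_slide()
  model <- color_prototype_segmenter(fixture_prototypes(), stride = 4L)
  model$class_map <- c(tissue = 1L, glomerulus = 2L, artery = 3L)
  vol <- run_tiled_inference(g$slide, model, inference_config(), fixture_tissue())
  mask <- volume_to_mask(vol)
  expect_identical(dim(mask), c(1024L %/% 8L, 1024L %/% 8L))
  expect_identical(attr(mask, "scale_factor"), 8L)

  # single-class volume -> uniform mask; zero-coverage pixels stay background
  vol1 <- structure(list(
    data = array(c(rep(0, 16), rep(3, 16)), c(4, 4, 2)),
    counts = matrix(c(rep(1L, 12), rep(0L, 4)), 4, 4),
    scale_factor = 8, classes = c("background", "a")
  ), class = "logit_volume")
  m1 <- volume_to_mask(vol1)
  expect_true(all(m1[, 1:3] == 1L))
  expect_true(all(m1[, 4] == 0L))

  # exact ties break toward the lower class index
  vol2 <- structure(list(
    data = array(1, c(2, 2, 3)),
    counts = matrix(1L, 2, 2),
    scale_factor = 8, classes = c("background", "a", "b")
  ), class = "logit_volume")
  expect_true(all(volume_to_mask(vol2) == 0L))
})

test_that("contour and heatmap export up-sample coordinates to base resolution", {
  # one 10x10 blob at scale 8 -> bbox about 80 x 80 base px
  m <- matrix(0L, 32, 32)
  m[11:20, 11:20] <- 1L
  doc <- export_contours(m, scale_factor = 8, class_map = c(a = 1L))
  expect_length(doc$layers$a, 1L)
  bb <- doc$layers$a[[1]]$bbox
  expect_lt(abs((bb[["max_x"]] - bb[["min_x"]]) - 80), 8 + 1e-9)

  # empty mask -> empty document
  doc0 <- export_contours(matrix(0L, 8, 8), scale_factor = 8,
                          class_map = c(a = 1L))
  expect_identical(unname(layer_sizes(doc0)), 0L)

  # heatmap with threshold 0 keeps exactly the covered pixels
  g <- fixture_small()
  model <- color_prototype_segmenter(fixture_prototypes()[1:3, ], stride = 4L)
  model$class_map <- c(tissue = 1L, glomerulus = 2L)
  vol <- run_tiled_inference(g$slide, model,
                             inference_config(patch_size = 96L, stride = 48L,
                                              prediction_downsample = 2L,
                                              border_trim = 8L),
                             compute_tissue_mask(g$slide, downsample = 16,
                                                 cache_dir = FALSE))
  hm <- export_heatmap(vol, "glomerulus", threshold = 0)
  expect_identical(nrow(hm$points), sum(vol$counts > 0))
  expect_identical(hm$scale_factor, vol$scale_factor)
  hm05 <- export_heatmap(vol, "glomerulus", threshold = 0.5)
  expect_lt(nrow(hm05$points), nrow(hm$points))
  expect_true(all(hm05$points$value > 0.5))
  expect_error(export_heatmap(vol, "nope"), "unknown class")
})

test_that("a color-oracle segmenter recovers every well-separated object end to end", {
  g <- generate_synthetic_slide(synthetic_slide_spec(
    base_width = 768L, base_height = 768L, tissue_blobs = 2L,
    tissue_radius = c(180, 240),
    classes = data.frame(name = "glomerulus", count = 6L, min_size = 50,
                         max_size = 80, color = "#6A4A93",
                         stringsAsFactors = FALSE),
    seed = 55L
  ))
  model <- color_prototype_segmenter(fixture_prototypes()[1:3, ], stride = 4L)
  model$class_map <- c(tissue = 1L, glomerulus = 2L)
  vol <- run_tiled_inference(g$slide, model,
                             inference_config(patch_size = 256L, stride = 128L,
                                              prediction_downsample = 2L,
                                              border_trim = 16L))
  mask <- volume_to_mask(vol)
  pred_doc <- export_contours(mask, vol$scale_factor,
                              class_map = c(tissue = 1L, glomerulus = 2L))
  mm <- object_match(pred_doc$layers$glomerulus, g$doc$layers$glomerulus,
                     extent = c(768, 768))
  expect_identical(mm$fp, 0L)
  expect_identical(mm$fn, 0L)
  expect_identical(mm$tp, 6L)
})
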