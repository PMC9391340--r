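#' Inference configuration
#'
#' Controls deterministic whole-slide prediction. The slide is processed at
#' `prediction_downsample` on an overlapping grid of `patch_size` patches
#' spaced `stride` apart (defaults 2000 / 1000 px: half-patch overlap, a
#' compromise between context and compute that suppresses patch-edge
#' artifacts). Predicted logits of overlapping patches are averaged;
#' additionally a `border_trim` rim of each patch prediction is discarded
#' (default 100 px in patch coordinates) except along sides where the patch
#' abuts the slide boundary, where trimming would leave tissue unpredicted.
#'
#' @param patch_size patch side at prediction scale (default 2000)
#' @param stride grid spacing at prediction scale (default 1000)
#' @param prediction_downsample read scale relative to base (default 2)
#' @param border_trim trimmed rim in patch pixels (default 100); rounded
#'   down to whole logit pixels of the model in use
#' @param mode `"contours"` or `"heatmap"` output flavor for the driver
#' @return an object of class `inference_config`
#' @export
inference_config <- function(patch_size = 2000L, stride = 1000L,
                             prediction_downsample = 2L, border_trim = 100L,
                             mode = c("contours", "heatmap")) {
  stopifnot(stride <= patch_size, stride >= 1, border_trim >= 0,
            border_trim < patch_size / 2, prediction_downsample >= 1)
  structure(
    list(patch_size = as.integer(patch_size), stride = as.integer(stride),
         prediction_downsample = as.integer(prediction_downsample),
         border_trim = as.integer(border_trim), mode = match.arg(mode)),
    class = "inference_config"
  )
}

# Origin lattice along one axis: stride-spaced origins plus a final origin
# aligned down/up to `align` so that [0, extent) is fully covered even when
# extent is not a lattice point (the final patch may overhang; reads pad
# with white).
axis_origins <- function(extent, patch, stride, align) {
  if (extent <= patch) return(0L)
  xs <- seq.int(0L, extent - patch, by = stride)
  last <- as.integer(align * ceiling((extent - patch) / align))
  sort(unique(c(xs, last)))
}

#' Plan the overlapping inference grid
#'
#' Enumerates, in row-major order, the prediction-scale origins of all
#' patches that intersect tissue. The union of planned patches covers every
#' tissue pixel (asserted); non-tissue areas contribute no patches, which is
#' where the speed saving of tissue masking comes from.
#'
#' @param tissue a tissue mask from [compute_tissue_mask()]
#' @param cfg an [inference_config()]
#' @param align origins are kept on multiples of this value (the model's
#'   decoder stride) so logit grids of all patches align; default 4
#' @return object of class `grid_plan`: `origins` (n x 2 matrix of `(x, y)`
#'   at prediction scale), `patch_size`, `prediction_downsample`,
#'   `pred_width`/`pred_height`, `slide_id`
#' @export
plan_grid <- function(tissue, cfg, align = 4L) {
  stopifnot(inherits(tissue, "tissue_mask"), inherits(cfg, "inference_config"))
  if (cfg$stride %% align || cfg$patch_size %% align)
    stopf("patch_size and stride must be multiples of align = %d", align)
  pd <- cfg$prediction_downsample
  pw <- as.integer(tissue$base_width %/% pd)
  ph <- as.integer(tissue$base_height %/% pd)
  p <- cfg$patch_size
  empty <- !any(tissue$mask)
  xs <- axis_origins(pw, p, cfg$stride, align)
  ys <- axis_origins(ph, p, cfg$stride, align)
  ds <- tissue$downsample / pd   # tissue-mask pixels per prediction pixel
  mh <- nrow(tissue$mask); mw <- ncol(tissue$mask)
  keep <- matrix(FALSE, length(ys), length(xs))
  covered <- matrix(FALSE, mh, mw)
  if (!empty) {
    for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
      c0 <- clamp(floor(xs[ix] / ds) + 1L, 1L, mw)
      c1 <- clamp(ceiling((xs[ix] + p) / ds), 1L, mw)
      r0 <- clamp(floor(ys[iy] / ds) + 1L, 1L, mh)
      r1 <- clamp(ceiling((ys[iy] + p) / ds), 1L, mh)
      if (any(tissue$mask[r0:r1, c0:c1])) {
        keep[iy, ix] <- TRUE
        covered[r0:r1, c0:c1] <- TRUE
      }
    }
    if (any(tissue$mask & !covered))
      stopf("internal error: inference grid leaves tissue uncovered")  # nocov
  }
  origins <- cbind(
    x = rep(xs, times = length(ys)),
    y = rep(ys, each = length(xs))
  )[as.logical(t(keep)), , drop = FALSE]
  structure(
    list(origins = origins, patch_size = p, prediction_downsample = pd,
         pred_width = pw, pred_height = ph, slide_id = tissue$slide_id),
    class = "grid_plan"
  )
}

#' @export
print.grid_plan <- function(x, ...) {
  cat(sprintf("<grid_plan> '%s': %d patch(es) of %d px at downsample %d\n",
              x$slide_id, nrow(x$origins), x$patch_size, x$prediction_downsample))
  invisible(x)
}

#' Tiled whole-slide inference with logit averaging
#'
#' Runs the patch segmenter over the planned grid and stitches the per-patch
#' logits into a slide-level logit volume: each output pixel is the
#' unweighted mean of all contributing patch logits, after discarding the
#' trimmed border of every patch (trimming is suppressed along slide
#' boundaries). The volume lives at `scale_factor = prediction_downsample *
#' stride` relative to base resolution — with the defaults (downsample 2,
#' decoder stride 4) one-eighth of base per side; predictions are never
#' up-sampled.
#'
#' @param slide a [slide_pyramid()]
#' @param model a [patch_segmenter()]
#' @param cfg an [inference_config()]
#' @param tissue tissue mask from [compute_tissue_mask()]
#' @param verbose report percent-complete via `message()` (default FALSE)
#' @return object of class `logit_volume`: `data` (array `[vh, vw,
#'   n_classes]` of averaged logits; 0 where uncovered), `counts`
#'   (contributing-patch count per pixel), `scale_factor`, `classes`
#'   (character: "background" then foreground layer names when known), and
#'   `slide_id`
#' @export
run_tiled_inference <- function(slide, model, cfg = inference_config(),
                                tissue = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "patch_segmenter"))
  if (is.null(tissue)) tissue <- compute_tissue_mask(slide, cache_dir = FALSE)
  os <- model$stride
  plan <- plan_grid(tissue, cfg, align = os)
  pd <- cfg$prediction_downsample
  vw <- plan$pred_width %/% os
  vh <- plan$pred_height %/% os
  k <- model$n_classes
  sums <- array(0, c(vh, vw, k))
  counts <- matrix(0L, vh, vw)
  trim <- cfg$border_trim %/% os        # whole logit pixels
  lp <- plan$patch_size %/% os
  n <- nrow(plan$origins)
  last_pct <- -10
  for (i in seq_len(n)) {
    ox <- plan$origins[i, 1]; oy <- plan$origins[i, 2]
    img <- read_region(slide, ox * pd, oy * pd,
                       plan$patch_size * pd, plan$patch_size * pd, pd)
    lg <- tryCatch(predict_logits(model, img), error = function(e)
      stopf("patch at (%d, %d): %s", ox, oy, conditionMessage(e)))
    tl <- if (ox > 0) trim else 0L
    tt <- if (oy > 0) trim else 0L
    tr <- if (ox + plan$patch_size < plan$pred_width) trim else 0L
    tb <- if (oy + plan$patch_size < plan$pred_height) trim else 0L
    gx0 <- ox %/% os + tl; gx1 <- ox %/% os + lp - tr
    gy0 <- oy %/% os + tt; gy1 <- oy %/% os + lp - tb
    cx0 <- max(gx0, 0L); cx1 <- min(gx1, vw)
    cy0 <- max(gy0, 0L); cy1 <- min(gy1, vh)
    if (cx1 <= cx0 || cy1 <= cy0) next
    rows <- (cy0 + 1L):cy1; cols <- (cx0 + 1L):cx1
    lrows <- (cy0 - oy %/% os + 1L):(cy1 - oy %/% os)
    lcols <- (cx0 - ox %/% os + 1L):(cx1 - ox %/% os)
    sums[rows, cols, ] <- sums[rows, cols, , drop = FALSE] +
      lg[lrows, lcols, , drop = FALSE]
    counts[rows, cols] <- counts[rows, cols] + 1L
    if (verbose) {
      pct <- floor(100 * i / n)
      if (pct >= last_pct + 10) { message(sprintf("inference %d%%", pct)); last_pct <- pct }
    }
  }
  nz <- counts > 0L
  for (j in seq_len(k)) {
    ch <- sums[, , j]
    ch[nz] <- ch[nz] / counts[nz]
    sums[, , j] <- ch
  }
  classes <- if (!is.null(model$class_map))
    c("background", names(model$class_map)) else paste0("class", seq_len(k) - 1L)
  structure(
    list(data = sums, counts = counts, scale_factor = pd * os,
         classes = classes, slide_id = slide$slide_id),
    class = "logit_volume"
  )
}

#' @export
print.logit_volume <- function(x, ...) {
  cat(sprintf("<logit_volume> '%s' %d x %d x %d @ 1/%g of base, %.1f%% covered\n",
              x$slide_id, ncol(x$counts), nrow(x$counts), dim(x$data)[3],
              x$scale_factor, 100 * mean(x$counts > 0)))
  invisible(x)
}

#' Collapse a logit volume to a label mask
#'
#' Per-pixel argmax over classes; ties break toward the lower class index
#' for determinism. Pixels never covered by a patch are background (0).
#' The returned mask carries the volume's scale factor as attribute
#' `scale_factor` (1/8 of base resolution per side under the defaults).
#'
#' @param vol a `logit_volume`
#' @return integer label matrix (0 = background, k = k-th foreground class)
#'   with attribute `scale_factor`
#' @export
volume_to_mask <- function(vol) {
  stopifnot(inherits(vol, "logit_volume"))
  k <- dim(vol$data)[3]
  flat <- matrix(vol$data, ncol = k)
  lab <- max.col(flat, ties.method = "first") - 1L
  lab[as.numeric(vol$counts) == 0] <- 0L
  structure(matrix(lab, nrow(vol$counts), ncol(vol$counts)),
            scale_factor = vol$scale_factor)
}

#' Export a predicted mask as contour annotations
#'
#' Vectorizes the label mask ([mask_to_annotations()]) and up-samples the
#' contour coordinates by the mask's scale factor into base resolution.
#'
#' @param mask integer label mask (e.g. from [volume_to_mask()])
#' @param scale_factor mask scale relative to base; defaults to the mask's
#'   `scale_factor` attribute
#' @param class_map named integer vector (layer name -> mask label)
#' @param slide_id stored in the output document
#' @return an [annotation_document()] in base coordinates
#' @export
export_contours <- function(mask, scale_factor = attr(mask, "scale_factor"),
                            class_map, slide_id = "") {
  stopifnot(!is.null(scale_factor))
  mask_to_annotations(mask, origin = c(0, 0), scale = scale_factor,
                      class_map = class_map, slide_id = slide_id)
}

#' Export one class of a logit volume as a sparse heatmap
#'
#' Converts logits to softmax probabilities and keeps, for pixels covered by
#' at least one patch, the entries whose probability exceeds the
#' sparsification threshold. Heatmaps communicate confidence for structures
#' with poorly defined boundaries better than binary contours.
#'
#' @param vol a `logit_volume`
#' @param class class name (one of `vol$classes`) or index
#' @param threshold sparsification threshold on the softmax probability
#'   (default 0.05); entries with `value > threshold` are stored
#' @return a [heatmap_layer()] at the volume's scale factor
#' @export
export_heatmap <- function(vol, class, threshold = 0.05) {
  stopifnot(inherits(vol, "logit_volume"))
  if (is.character(class)) {
    ci <- match(class, vol$classes)
    if (is.na(ci)) stopf("unknown class '%s' (have: %s)", class,
                         paste(vol$classes, collapse = ", "))
  } else ci <- as.integer(class)
  k <- dim(vol$data)[3]
  pr <- softmax_rows(matrix(vol$data, ncol = k))[, ci]
  keep <- as.numeric(vol$counts) > 0 & pr > threshold
  idx <- which(matrix(keep, nrow(vol$counts), ncol(vol$counts)), arr.ind = TRUE)
  heatmap_layer(
    tibble::tibble(x = idx[, 2] - 1L, y = idx[, 1] - 1L,
                   value = pr[keep]),
    class_label = vol$classes[ci], scale_factor = vol$scale_factor
  )
}
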