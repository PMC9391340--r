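#' Training-patch sampler configuration
#'
#' Controls on-the-fly extraction of training patches from an annotated
#' slide. Patches are drawn at a downsample factor cycled uniformly at
#' random from `downsample_list`, mirroring multi-resolution training.
#' With probability `background_prob` a draw is routed through the
#' background-eligible branch: its location is unconstrained, so the patch
#' may contain no tissue at all (occasional background patches help
#' generalize normalization statistics during training). All remaining
#' draws are class-balanced when `balance` is on: a target class is chosen
#' uniformly over classes, then a polygon uniformly within the class, and
#' the patch is centered on that polygon with a uniform jitter of up to half
#' a patch per axis.
#'
#' @param patch_size patch side length in pixels at the sampled downsample
#'   (default 512)
#' @param downsample_list integer downsample factors cycled during training
#'   (default 1:4)
#' @param background_prob probability of a background-eligible draw
#'   (default 0.1)
#' @param ignore_label integer label reserved for excluded regions
#'   (default 255); pixels inside layers listed in `ignore_layers` receive it
#' @param ignore_layers names of annotation layers treated as ignore regions
#'   (default "ignore")
#' @param balance proactively balance classes (default TRUE); when off, the
#'   patch center is uniform over the tissue bounding box
#' @return an object of class `sampler_config`
#' @export
sampler_config <- function(patch_size = 512L, downsample_list = 1:4,
                           background_prob = 0.1, ignore_label = 255L,
                           ignore_layers = "ignore", balance = TRUE) {
  stopifnot(patch_size >= 1, length(downsample_list) >= 1, all(downsample_list >= 1),
            background_prob >= 0, background_prob <= 1)
  structure(
    list(patch_size = as.integer(patch_size),
         downsample_list = as.integer(downsample_list),
         background_prob = background_prob,
         ignore_label = as.integer(ignore_label),
         ignore_layers = ignore_layers,
         balance = isTRUE(balance)),
    class = "sampler_config"
  )
}

#' Overwrite label pixels covered by ignore regions
#'
#' @param label integer label raster
#' @param doc an [annotation_document()] holding the ignore layer(s)
#' @param region `c(x, y, w, h)` base-resolution geometry of `label`
#' @param downsample scale of `label` relative to base
#' @param ignore_label value written inside ignore polygons
#' @param ignore_layers layer names to apply (missing layers are skipped)
#' @return the label raster with ignore pixels overwritten
#' @export
apply_ignore_regions <- function(label, doc, region, downsample = 1,
                                 ignore_label = 255L, ignore_layers = "ignore") {
  present <- intersect(ignore_layers, names(doc$layers))
  if (!length(present)) return(label)
  cm <- stats::setNames(rep(as.integer(ignore_label), length(present)), present)
  rasterize_annotations(doc, region, downsample, cm, layers = present, init = label)
}

#' Draw one training patch
#'
#' Implements the sampling rule described in [sampler_config()]. Labelled
#' classes are the annotation layers named in `class_map`; classes with zero
#' polygons are skipped from balancing with a warning. The patch location is
#' clamped so that the patch lies within slide bounds. Uses R's RNG: seed
#' the stream with `set.seed()` for reproducible draws.
#'
#' @param slide a [slide_pyramid()]
#' @param doc an [annotation_document()]
#' @param tissue a tissue mask from [compute_tissue_mask()]
#' @param cfg a [sampler_config()]
#' @param class_map named integer vector mapping layer names to label values
#' @param pixels when `FALSE`, return only the draw's provenance (location,
#'   class, downsample, background flag) without reading pixels; useful for
#'   auditing sampling statistics over many draws
#' @return object of class `patch_sample`: list with `image` (RGB array),
#'   `label` (integer matrix), `slide_id`, `location` (base-resolution
#'   `c(x, y)` of the top-left corner), `downsample`, `background`
#'   (logical: drawn through the background-eligible branch), and
#'   `target_class` (NA for background draws)
#' @export
sample_patch <- function(slide, doc, tissue, cfg, class_map, pixels = TRUE) {
  stopifnot(inherits(slide, "slide_pyramid"), inherits(cfg, "sampler_config"))
  p <- cfg$patch_size
  d <- cfg$downsample_list[sample.int(length(cfg$downsample_list), 1L)]
  span <- p * d   # patch extent in base pixels
  background <- stats::runif(1) < cfg$background_prob
  target_class <- NA_character_
  if (background) {
    cx <- stats::runif(1, 0, slide$base_width)
    cy <- stats::runif(1, 0, slide$base_height)
  } else if (cfg$balance) {
    sizes <- layer_sizes(doc)[names(class_map)]
    usable <- names(sizes)[!is.na(sizes) & sizes > 0]
    empty <- setdiff(names(class_map), usable)
    if (length(empty))
      warnf("class(es) without polygons skipped from balancing: %s",
            paste(empty, collapse = ", "))
    if (!length(usable)) stopf("no annotated polygons available for balanced sampling")
    target_class <- usable[sample.int(length(usable), 1L)]
    poly <- doc$layers[[target_class]][[sample.int(length(doc$layers[[target_class]]), 1L)]]
    ctr <- colMeans(poly$vertices)
    cx <- ctr[1] + stats::runif(1, -span / 2, span / 2)
    cy <- ctr[2] + stats::runif(1, -span / 2, span / 2)
  } else {
    # uniform over tissue: pick a foreground mask pixel, then jitter inside it
    idx <- which(tissue$mask, arr.ind = TRUE)
    if (!nrow(idx)) stopf("tissue mask is empty")
    ds <- tissue$downsample
    k <- sample.int(nrow(idx), 1L)
    cx <- (idx[k, 2] - 1) * ds + stats::runif(1, 0, ds)
    cy <- (idx[k, 1] - 1) * ds + stats::runif(1, 0, ds)
  }
  x <- unname(clamp(round(cx - span / 2), 0, max(0, slide$base_width - span)))
  y <- unname(clamp(round(cy - span / 2), 0, max(0, slide$base_height - span)))
  out <- structure(
    list(image = NULL, label = NULL, slide_id = slide$slide_id,
         location = c(x = x, y = y), downsample = d,
         background = background, target_class = target_class,
         patch_size = p),
    class = "patch_sample"
  )
  if (!pixels) return(out)
  out$image <- read_region(slide, x, y, span, span, d)
  label <- rasterize_annotations(doc, c(x, y, span, span), d, class_map)
  out$label <- apply_ignore_regions(label, doc, c(x, y, span, span), d,
                                    cfg$ignore_label, cfg$ignore_layers)
  out
}

#' Draw a stream of training patches
#'
#' Convenience wrapper drawing `n` patches with a fixed seed; the same seed
#' reproduces the stream bit-exactly.
#'
#' @inheritParams sample_patch
#' @param n number of draws
#' @param seed integer seed for the draw stream
#' @return list of `patch_sample` objects
#' @export
sample_patches <- function(slide, doc, tissue, cfg, class_map, n, seed = 1L,
                           pixels = TRUE) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  lapply(seq_len(n), function(i)
    sample_patch(slide, doc, tissue, cfg, class_map, pixels = pixels))
}
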