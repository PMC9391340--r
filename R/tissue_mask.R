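#' Tissue-region masking
#'
#' Whole-slide inference and training sampling both restrict work to tissue.
#' Tissue is located by fast color thresholding on a low-resolution rendition
#' of the slide: after Gaussian smoothing, a pixel is tissue when its darkest
#' RGB channel falls below a white threshold (stained tissue is never pure
#' white on a brightfield scan), and small speckle components are removed.
#' The mask is cached as a PNG keyed by slide content and parameters so
#' repeated runs reload it bit-exactly instead of recomputing.
#'
#' @param slide a [slide_pyramid()]
#' @param downsample mask scale relative to base resolution (default 32);
#'   mask dimensions are `floor(base / downsample)`
#' @param white_threshold tissue where `min(R, G, B) < white_threshold`
#'   (0-1 scale, default 228/255)
#' @param smooth_sigma Gaussian pre-smoothing in mask-scale pixels (default 1;
#'   0 disables)
#' @param min_component minimum connected-component size in mask pixels
#'   (default 100); smaller islands are removed
#' @param cache_dir directory for the PNG cache; `NULL` (default) uses
#'   `tools::R_user_dir("slideseg", "cache")`; `FALSE` disables caching
#' @return object of class `tissue_mask`: list with `mask` (logical matrix),
#'   `downsample`, `slide_id`, and `cache_path` (NA when uncached)
#' @export
compute_tissue_mask <- function(slide, downsample = 32,
                                white_threshold = 228 / 255,
                                smooth_sigma = 1,
                                min_component = 100L,
                                cache_dir = NULL) {
  stopifnot(inherits(slide, "slide_pyramid"))
  cache_path <- NA_character_
  if (!identical(cache_dir, FALSE)) {
    cache_dir <- cache_dir %||% tools::R_user_dir("slideseg", "cache")
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    key <- object_hash(list(slide$slide_id, slide$base_width, slide$base_height,
                            downsample, white_threshold, smooth_sigma, min_component))
    cache_path <- file.path(cache_dir, paste0("tissue-", key, ".png"))
    if (file.exists(cache_path)) {
      m <- png::readPNG(cache_path)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      return(new_tissue_mask(m > 0.5, downsample, slide, cache_path))
    }
  }
  img <- read_region(slide, 0, 0, slide$base_width, slide$base_height, downsample)
  if (smooth_sigma > 0) {
    for (k in 1:3) {
      img[, , k] <- t(EBImage::imageData(
        EBImage::gblur(EBImage::Image(t(img[, , k])), sigma = smooth_sigma)
      ))
    }
  }
  mask <- pmin(img[, , 1], img[, , 2], img[, , 3]) < white_threshold
  if (min_component > 0L && any(mask)) {
    lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
    keep <- which(tabulate(lab) >= min_component)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!is.na(cache_path)) png::writePNG(mask * 1, cache_path)
  new_tissue_mask(mask, downsample, slide, cache_path)
}

new_tissue_mask <- function(mask, downsample, slide, cache_path = NA_character_) {
  structure(
    list(mask = mask, downsample = downsample, slide_id = slide$slide_id,
         base_width = slide$base_width, base_height = slide$base_height,
         cache_path = cache_path),
    class = "tissue_mask"
  )
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> '%s' %d x %d @ downsample %g, %.1f%% tissue\n",
              x$slide_id, ncol(x$mask), nrow(x$mask), x$downsample,
              100 * mean(x$mask)))
  invisible(x)
}

#' Fraction of mask pixels marked as tissue
#' @param tissue a `tissue_mask`
#' @return numeric scalar in [0, 1]
#' @export
tissue_fraction <- function(tissue) mean(tissue$mask)
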