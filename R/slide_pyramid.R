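#' Slide pyramid
#'
#' In-memory multi-resolution representation of a whole-slide image. Each
#' level stores an RGB raster together with its downsample factor relative to
#' the base (full) resolution; downsamples are strictly increasing from 1.
#' All public coordinates are 0-based base-resolution pixels.
#'
#' @param levels list of RGB arrays `[h, w, 3]`, base resolution first; each
#'   subsequent level must be a downsampled rendition of the base
#' @param slide_id character identifier (defaults to a content hash)
#' @param mpp optional microns per pixel at base resolution
#' @return an object of class `slide_pyramid`
#' @export
slide_pyramid <- function(levels, slide_id = NULL, mpp = NULL) {
  if (!length(levels)) stopf("a slide needs at least one pyramid level")
  levels <- lapply(levels, function(l) {
    if (length(dim(l)) == 2L) l <- array(rep(l, 3L), c(dim(l), 3L))
    if (length(dim(l)) != 3L) stopf("pyramid levels must be [h, w, 3] arrays")
    l[, , 1:3, drop = FALSE]
  })
  bw <- ncol(levels[[1]]); bh <- nrow(levels[[1]])
  ds <- vapply(levels, function(l) bw / ncol(l), numeric(1))
  if (is.unsorted(ds, strictly = TRUE) || ds[1] != 1)
    stopf("level downsamples must increase strictly from 1")
  structure(
    list(
      levels = levels,
      downsamples = ds,
      base_width = bw, base_height = bh,
      slide_id = slide_id %||% substr(object_hash(levels[[length(levels)]]), 1, 12),
      mpp = mpp
    ),
    class = "slide_pyramid"
  )
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat(sprintf("<slide_pyramid> '%s' %d x %d px, levels at downsample %s\n",
              x$slide_id, x$base_width, x$base_height,
              paste(format(x$downsamples), collapse = ", ")))
  invisible(x)
}

#' @export
dim.slide_pyramid <- function(x) c(x$base_height, x$base_width)

#' Read a rectangular region from a slide
#'
#' Reads the region `[x, x+w) x [y, y+h)` (base-resolution pixels) rendered
#' at the requested downsample. The raster is produced from the finest
#' pyramid level whose downsample does not exceed the request and block-mean
#' averaged down to the target, so reads at different downsamples agree up
#' to interpolation. The output has dimensions `floor(h/d)` x `floor(w/d)`.
#' Reads extending beyond the slide bounds are padded with white, so that
#' edge patches of an inference grid stay full-size.
#'
#' @param slide a [slide_pyramid()]
#' @param x,y top-left corner, base-resolution pixels (may be negative)
#' @param w,h region extent in base-resolution pixels
#' @param downsample requested downsample factor (>= 1)
#' @return RGB array `[floor(h/d), floor(w/d), 3]` in [0, 1]
#' @export
read_region <- function(slide, x, y, w, h, downsample = 1) {
  stopifnot(inherits(slide, "slide_pyramid"), downsample >= 1, w >= 1, h >= 1)
  if (abs(downsample - round(downsample)) > 1e-9)
    stopf("read_region supports integer downsample factors (got %g)", downsample)
  downsample <- round(downsample)
  out_w <- floor(w / downsample); out_h <- floor(h / downsample)
  if (out_w < 1L || out_h < 1L) stopf("region %gx%g too small at downsample %g", w, h, downsample)
  # pick the finest level usable with an integer residual block factor
  cand <- which(slide$downsamples <= downsample + 1e-9 &
                  abs(downsample / slide$downsamples - round(downsample / slide$downsamples)) < 1e-9)
  lev <- if (length(cand)) max(cand) else 1L
  d0 <- slide$downsamples[lev]
  f <- as.integer(round(downsample / d0))
  lw <- ncol(slide$levels[[lev]]); lh <- nrow(slide$levels[[lev]])
  # level-resolution source window large enough for out dims after block mean
  lx <- floor(x / d0); ly <- floor(y / d0)
  need_w <- out_w * f; need_h <- out_h * f
  out <- white_raster(need_h, need_w)
  sx0 <- max(0L, lx); sy0 <- max(0L, ly)
  sx1 <- min(lw, lx + need_w); sy1 <- min(lh, ly + need_h)
  if (sx1 > sx0 && sy1 > sy0) {
    out[(sy0 - ly + 1L):(sy1 - ly), (sx0 - lx + 1L):(sx1 - lx), ] <-
      slide$levels[[lev]][(sy0 + 1L):sy1, (sx0 + 1L):sx1, , drop = FALSE]
  }
  block_downsample(out, f)
}

#' Read a whole slide file as a pyramid
#'
#' Multi-page TIFF files are interpreted as pyramids (pages sorted by
#' decreasing width; the largest page is the base level). Single-page TIFF
#' and PNG files become degenerate one-level pyramids.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file
#' @param slide_id optional identifier; defaults to the file name sans extension
#' @param mpp optional microns per pixel at base resolution
#' @return a [slide_pyramid()]
#' @export
read_slide <- function(path, slide_id = NULL, mpp = NULL) {
  if (!file.exists(path)) stopf("cannot read slide: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  pages <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path, all = TRUE),
    "png" = list(png::readPNG(path)),
    stopf("unsupported slide format '.%s' (TIFF or PNG expected)", ext)
  )
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L && dim(p)[3] > 3L) p <- p[, , 1:3, drop = FALSE]
    p
  })
  pages <- pages[order(-vapply(pages, ncol, numeric(1)))]
  slide_pyramid(pages, slide_id = slide_id %||% tools::file_path_sans_ext(basename(path)),
                mpp = mpp)
}

#' Write a slide pyramid as a multi-page TIFF
#'
#' Levels are written largest first, one TIFF directory per level (the
#' standard multi-resolution layout readable by [read_slide()]).
#'
#' @param slide a [slide_pyramid()]
#' @param path output `.tif` path
#' @return `path`, invisibly
#' @export
write_slide <- function(slide, path) {
  tiff::writeTIFF(slide$levels, path, bits.per.sample = 8L, compression = "LZW")
  invisible(path)
}
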