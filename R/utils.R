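#' @keywords internal
"_PACKAGE"

# Conventions used throughout:
#  - RGB rasters are numeric arrays [height, width, 3] with values in [0, 1].
#  - Label rasters are integer matrices [height, width]; 0 is background.
#  - Coordinates are 0-based and half-open: x indexes columns, y indexes rows,
#    pixel (x0, y0) covers [x0, x0+1) x [y0, y0+1) with center (x0+0.5, y0+0.5).
#  - Public APIs take base-resolution pixel coordinates unless stated.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Block-mean downsampling of a raster
#'
#' Averages non-overlapping `f` x `f` blocks. Output dimensions are
#' `floor(dim / f)`; trailing rows/columns that do not fill a block are
#' dropped. Used both to build pyramid levels and to resample region reads,
#' so that reads at different downsamples are mutually consistent.
#'
#' @param img numeric matrix or [h, w, c] array
#' @param f integer downsampling factor (>= 1)
#' @return downsampled matrix/array
#' @export
block_downsample <- function(img, f) {
  f <- as.integer(f)
  if (f == 1L) return(img)
  d <- dim(img)
  h <- (d[1] %/% f) * f
  w <- (d[2] %/% f) * f
  if (h == 0L || w == 0L) stopf("raster %dx%d too small for downsample %d", d[1], d[2], f)
  down_mat <- function(m) {
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    # average over f x f blocks via two matrix reshapes
    m1 <- matrix(colMeans(matrix(m, nrow = f)), nrow = h %/% f)         # rows
    t(matrix(colMeans(matrix(t(m1), nrow = f)), nrow = w %/% f))        # cols
  }
  if (length(d) == 2L) return(down_mat(img))
  out <- array(0, c(h %/% f, w %/% f, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- down_mat(img[, , k])
  out
}

#' Nearest-neighbour upscaling of a matrix by an integer factor
#' @keywords internal
upscale_nn <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f), drop = FALSE]
}

#' Row-wise softmax
#' @param x numeric matrix (rows = observations, cols = classes)
#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Deterministic short hash of an R object (for cache filenames).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

# Solid white RGB array.
white_raster <- function(h, w) array(1, c(h, w, 3L))
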