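#' Patch-segmenter contract
#'
#' Tiled whole-slide inference is agnostic to the model that segments
#' individual patches. Any model can be plugged in by wrapping it into this
#' contract: a `predict` function mapping an RGB patch (`[H, W, 3]` array,
#' values in [0, 1], `H` and `W` divisible by `stride`) to a logit array
#' `[H/stride, W/stride, n_classes]`. `stride` is the decoder output stride:
#' predictions are emitted at a reduced spatial resolution and never
#' up-sampled; instead, contour/heatmap coordinates are up-sampled at export
#' time. Class 1 of the logit array is background; classes 2..n follow the
#' order of the model's `class_map`.
#'
#' @param predict_fn function(img) -> logit array
#' @param n_classes number of classes including background
#' @param stride decoder output stride (default 4)
#' @param class_map named integer vector (annotation layer -> label value)
#'   describing the foreground classes, optional for ad-hoc models
#' @return an object of class `patch_segmenter`
#' @export
patch_segmenter <- function(predict_fn, n_classes, stride = 4L, class_map = NULL) {
  stopifnot(is.function(predict_fn), n_classes >= 2, stride >= 1)
  structure(
    list(predict = predict_fn, n_classes = as.integer(n_classes),
         stride = as.integer(stride), class_map = class_map),
    class = "patch_segmenter"
  )
}

#' Predict patch logits under the contract
#'
#' Calls the model and verifies the output shape is exactly
#' `[H/stride, W/stride, n_classes]`.
#'
#' @param model a [patch_segmenter()]
#' @param img RGB array `[H, W, 3]`
#' @return logit array
#' @export
predict_logits <- function(model, img) {
  d <- dim(img)
  if (d[1] %% model$stride || d[2] %% model$stride)
    stopf("patch %dx%d not divisible by decoder stride %d", d[2], d[1], model$stride)
  out <- model$predict(img)
  want <- c(d[1] %/% model$stride, d[2] %/% model$stride, model$n_classes)
  if (!identical(dim(out), as.integer(want)))
    stopf("segmenter contract violation: expected logits [%s], got [%s]",
          paste(want, collapse = ", "), paste(dim(out), collapse = ", "))
  out
}

#' Training configuration
#'
#' Hyperparameters of the reference trainer: SGD with momentum and a
#' polynomially decaying learning rate, the schedule commonly used to train
#' semantic-segmentation networks (base rate 1e-3, momentum 0.9). Defaults
#' are scaled to a desk-size reference model; large networks in the
#' literature use the same schedule with 50,000-400,000 steps.
#'
#' @param steps total optimization steps (default 500)
#' @param base_lr base learning rate (default 1e-3)
#' @param lr_power polynomial decay power (default 0.9); the rate reaches 0
#'   at `steps`
#' @param momentum momentum coefficient in [0, 1) (default 0.9)
#' @param batch_size patches per step (default 2)
#' @param patch_size training patch side in px (default 512)
#' @param train_batchnorm kept for interface parity with large-model
#'   trainers; the reference model has no normalization layers (default
#'   FALSE)
#' @return an object of class `train_config`
#' @export
train_config <- function(steps = 500L, base_lr = 1e-3, lr_power = 0.9,
                         momentum = 0.9, batch_size = 2L, patch_size = 512L,
                         train_batchnorm = FALSE) {
  stopifnot(steps >= 1, base_lr > 0, momentum >= 0, momentum < 1, batch_size >= 1)
  structure(
    list(steps = as.integer(steps), base_lr = base_lr, lr_power = lr_power,
         momentum = momentum, batch_size = as.integer(batch_size),
         patch_size = as.integer(patch_size), train_batchnorm = train_batchnorm),
    class = "train_config"
  )
}

#' Learning rate under polynomial decay
#'
#' `base_lr * (1 - step / steps) ^ lr_power`, reaching zero at the final
#' step.
#'
#' @param cfg a [train_config()]
#' @param step step index in `[0, steps]`
#' @return learning rate
#' @export
lr_at_step <- function(cfg, step) {
  if (any(step < 0 | step > cfg$steps))
    stopf("step must lie in [0, %d]", cfg$steps)
  cfg$base_lr * (1 - step / cfg$steps)^cfg$lr_power
}

# ---- reference model ----------------------------------------------------
#
# A deliberately small convolutional segmenter: a fixed bank of Gaussian
# smoothing convolutions over the RGB channels provides local context, and a
# learned 1x1 convolution (multinomial logistic layer) maps the per-pixel
# feature vector to class logits on the stride-reduced grid. Inputs are
# rescaled to [-1, 1]. It trains in seconds on a CPU and segments anything
# whose classes are color-separable, which is all the synthetic fixture
# requires; it makes no attempt to match a deep network's capacity.

reference_features <- function(img, sigmas, stride) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rows <- seq.int(stride %/% 2 + 1L, h, by = stride)
  cols <- seq.int(stride %/% 2 + 1L, w, by = stride)
  feats <- matrix(0, length(rows) * length(cols), 3L * (1L + length(sigmas)))
  fi <- 1L
  for (k in 1:3) {
    feats[, fi] <- as.numeric(img[rows, cols, k] * 2 - 1); fi <- fi + 1L
  }
  for (s in sigmas) {
    for (k in 1:3) {
      bl <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img[, , k])), sigma = s)))
      feats[, fi] <- as.numeric(bl[rows, cols] * 2 - 1); fi <- fi + 1L
    }
  }
  list(x = cbind(feats, 1), rows = rows, cols = cols)  # trailing 1 = bias
}

new_reference_segmenter <- function(W, class_map, stride, sigmas) {
  n_classes <- ncol(W)
  model <- patch_segmenter(
    predict_fn = function(img) {
      ft <- reference_features(img, sigmas, stride)
      array(ft$x %*% W, c(length(ft$rows), length(ft$cols), n_classes))
    },
    n_classes = n_classes, stride = stride, class_map = class_map
  )
  model$W <- W
  model$sigmas <- sigmas
  class(model) <- c("reference_segmenter", class(model))
  model
}

#' Train the reference segmenter
#'
#' Streams class-balanced training patches from one or more annotated
#' slides ([sample_patch()]) and fits the reference model by momentum SGD
#' on the softmax cross-entropy, with the polynomial learning-rate decay of
#' [lr_at_step()]. Pixels carrying the sampler's ignore label are excluded
#' from the loss. Because small foreground structures occupy few pixels
#' even in patches centered on them, the per-pixel loss is weighted by
#' inverse in-batch class frequency by default (`class_balance = TRUE`),
#' complementing the sampler's patch-level balancing; without it rare
#' classes converge far too slowly at desk-scale step counts. Runs are
#' deterministic given `seed`.
#'
#' @param slides a [slide_pyramid()] or list of them
#' @param docs matching [annotation_document()] or list
#' @param class_map named integer vector (layer -> label value 1..K)
#' @param cfg a [train_config()]
#' @param sampler a [sampler_config()]; its `patch_size` is overridden by
#'   `cfg$patch_size`
#' @param stride decoder output stride of the model (default 4)
#' @param sigmas Gaussian scales of the fixed feature bank (default
#'   `c(2, 4)`)
#' @param init optional checkpoint path or `reference_segmenter` to start
#'   from (transfer learning); must match stride/sigmas/classes
#' @param class_balance weight the loss by inverse in-batch class frequency
#'   (default TRUE)
#' @param seed RNG seed for patch sampling
#' @return a `reference_segmenter` with attribute fields `loss_trace`
#'   (per-step mean cross-entropy) and `trained_steps`
#' @export
train_reference <- function(slides, docs, class_map, cfg = train_config(),
                            sampler = sampler_config(), stride = 4L,
                            sigmas = c(2, 4), init = NULL,
                            class_balance = TRUE, seed = 1L) {
  if (inherits(slides, "slide_pyramid")) slides <- list(slides)
  if (inherits(docs, "annotation_document")) docs <- list(docs)
  stopifnot(length(slides) == length(docs))
  if (sum(unlist(lapply(docs, function(d) sum(layer_sizes(d)[names(class_map)] > 0, na.rm = TRUE)))) == 0)
    stopf("no annotated pixels: every slide is missing polygons for the requested classes")
  sampler$patch_size <- cfg$patch_size
  n_classes <- length(class_map) + 1L   # background + foreground classes
  n_feat <- 3L * (1L + length(sigmas)) + 1L
  if (!is.null(init)) {
    if (is.character(init)) init <- load_checkpoint(init)
    stopifnot(inherits(init, "reference_segmenter"))
    if (!identical(dim(init$W), c(n_feat, n_classes)) || init$stride != stride)
      stopf("checkpoint architecture does not match requested model")
    W <- init$W
  } else {
    W <- matrix(0, n_feat, n_classes)
  }
  vel <- matrix(0, n_feat, n_classes)
  tissues <- lapply(slides, compute_tissue_mask, cache_dir = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  loss_trace <- numeric(cfg$steps)
  # label values seen at the stride grid: 0 = background, class_map values,
  # sampler$ignore_label excluded
  for (step in seq_len(cfg$steps)) {
    xs <- vector("list", cfg$batch_size)
    ys <- vector("list", cfg$batch_size)
    for (b in seq_len(cfg$batch_size)) {
      si <- sample.int(length(slides), 1L)
      ps <- sample_patch(slides[[si]], docs[[si]], tissues[[si]], sampler, class_map)
      ft <- reference_features(ps$image, sigmas, stride)
      lab <- ps$label[ft$rows, ft$cols]
      xs[[b]] <- ft$x
      ys[[b]] <- as.integer(lab)
    }
    x <- do.call(rbind, xs)
    yv <- unlist(ys)
    keep <- yv != sampler$ignore_label
    if (!any(keep)) { loss_trace[step] <- NA_real_; next }
    x <- x[keep, , drop = FALSE]
    y <- match(yv[keep], c(0L, as.integer(class_map)))  # 1..n_classes
    wts <- if (class_balance) {
      cnt <- tabulate(y, n_classes)
      length(y) / (sum(cnt > 0) * cnt[y])
    } else rep(1, length(y))
    pr <- softmax_rows(x %*% W)
    ce <- -log(pmax(pr[cbind(seq_along(y), y)], 1e-12))
    loss_trace[step] <- sum(wts * ce) / sum(wts)
    grad_out <- pr
    grad_out[cbind(seq_along(y), y)] <- grad_out[cbind(seq_along(y), y)] - 1
    grad <- crossprod(x, grad_out * wts) / sum(wts)
    vel <- cfg$momentum * vel - lr_at_step(cfg, step - 1L) * grad
    W <- W + vel
  }
  model <- new_reference_segmenter(W, class_map, as.integer(stride), sigmas)
  model$loss_trace <- loss_trace
  model$trained_steps <- cfg$steps
  model
}

#' Save / load a reference-segmenter checkpoint
#'
#' Checkpoints store the learned weights plus the architecture metadata
#' (stride, feature scales, class map) needed to rebuild the model; they can
#' seed further training via the `init` argument of [train_reference()].
#'
#' @param model a `reference_segmenter`
#' @param path checkpoint file path (RDS)
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: the
#'   restored model
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "reference_segmenter"))
  saveRDS(list(format = "slideseg-reference-checkpoint", version = 1L,
               W = model$W, class_map = model$class_map,
               stride = model$stride, sigmas = model$sigmas),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("no such checkpoint: '%s'", path)
  ck <- tryCatch(readRDS(path), error = function(e)
    stopf("cannot read checkpoint '%s': %s", path, conditionMessage(e)))
  if (!identical(ck$format, "slideseg-reference-checkpoint"))
    stopf("'%s' is not a reference-segmenter checkpoint", path)
  new_reference_segmenter(ck$W, ck$class_map, ck$stride, ck$sigmas)
}

#' Color-prototype baseline segmenter
#'
#' A training-free [patch_segmenter()] that scores every pixel by negative
#' squared distance to a set of prototype colors (background prototype
#' first). Useful as a deterministic oracle for exercising the tiled
#' inference machinery, and as the simplest possible plug-in example.
#'
#' @param prototypes numeric K x 3 matrix of RGB prototypes in [0, 1]; row 1
#'   is background
#' @param stride decoder output stride (default 1); the patch is block-mean
#'   downsampled before scoring
#' @param sharpness multiplier on the negative squared distance (default 50)
#' @return a [patch_segmenter()]
#' @export
color_prototype_segmenter <- function(prototypes, stride = 1L, sharpness = 50) {
  prototypes <- as.matrix(prototypes)
  stopifnot(ncol(prototypes) == 3L, nrow(prototypes) >= 2L)
  patch_segmenter(
    predict_fn = function(img) {
      img <- block_downsample(img, stride)
      h <- dim(img)[1]; w <- dim(img)[2]
      px <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]), as.numeric(img[, , 3]))
      d2 <- outer(rowSums(px^2), rowSums(prototypes^2), "+") - 2 * px %*% t(prototypes)
      array(-sharpness * d2, c(h, w, nrow(prototypes)))
    },
    n_classes = nrow(prototypes), stride = stride
  )
}

#' Pixel accuracy of a segmenter on sampled patches
#'
#' Convenience helper: runs the model on each patch and compares the argmax
#' prediction with the ground-truth label subsampled to the logit grid,
#' skipping ignore pixels.
#'
#' @param model a [patch_segmenter()] with a `class_map`
#' @param patches list of `patch_sample` objects (with pixels)
#' @param ignore_label label value excluded from scoring (default 255)
#' @return overall pixel accuracy
#' @export
pixel_accuracy <- function(model, patches, ignore_label = 255L) {
  good <- 0; total <- 0
  vals <- c(0L, as.integer(model$class_map))
  for (ps in patches) {
    lg <- predict_logits(model, ps$image)
    pred <- apply(lg, c(1, 2), which.max)
    rows <- seq.int(model$stride %/% 2 + 1L, nrow(ps$label), by = model$stride)
    cols <- seq.int(model$stride %/% 2 + 1L, ncol(ps$label), by = model$stride)
    lab <- ps$label[rows, cols]
    keep <- lab != ignore_label
    good <- good + sum(vals[pred[keep]] == lab[keep])
    total <- total + sum(keep)
  }
  good / total
}
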