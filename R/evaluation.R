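#' Pixel-wise confusion counts (one-vs-rest)
#'
#' @param pred,gt integer label masks of identical shape
#' @param class label value scored as positive
#' @return object of class `confusion_counts`: TP, FP, FN, TN
#' @export
confusion <- function(pred, gt, class) {
  if (!identical(dim(pred), dim(gt)))
    stopf("prediction and ground truth differ in shape (%s vs %s)",
          paste(dim(pred), collapse = "x"), paste(dim(gt), collapse = "x"))
  p <- pred == class; g <- gt == class
  structure(
    list(TP = sum(p & g), FP = sum(p & !g), FN = sum(!p & g), TN = sum(!p & !g),
         class = class),
    class = "confusion_counts"
  )
}

#' Segmentation metrics from confusion counts
#'
#' Standard closed forms: Matthews correlation coefficient, F-score,
#' Cohen's kappa, intersection-over-union, sensitivity, specificity,
#' precision, accuracy. A metric whose denominator is zero is reported as 0
#' and the result is flagged degenerate.
#'
#' @param counts a [confusion()] result
#' @return tibble with one row of metrics plus a `degenerate` flag
#' @export
seg_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  fn <- as.numeric(counts$FN); tn <- as.numeric(counts$TN)
  n <- tp + fp + fn + tn
  degenerate <- FALSE
  safe <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  # kappa: observed vs chance agreement
  po <- safe(tp + tn, n)
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) { degenerate <- TRUE; 0 } else (po - pe) / (1 - pe)
  tibble::tibble(
    class = counts$class,
    mcc = safe(tp * tn - fp * fn, mcc_den),
    f_score = safe(2 * tp, 2 * tp + fp + fn),
    kappa = kappa,
    iou = safe(tp, tp + fp + fn),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    precision = safe(tp, tp + fp),
    accuracy = safe(tp + tn, n),
    degenerate = degenerate
  )
}

#' Evaluate a multi-class segmentation one-vs-rest
#'
#' @param pred,gt integer label masks
#' @param classes named integer vector (class name -> label value); default
#'   all non-zero labels in `gt`
#' @return tibble, one row of [seg_metrics()] per class, with class names
#' @export
evaluate_segmentation <- function(pred, gt, classes = NULL) {
  if (is.null(classes)) {
    v <- sort(setdiff(unique(as.integer(gt)), 0L))
    classes <- stats::setNames(v, paste0("class", v))
  }
  out <- lapply(seq_along(classes), function(i) {
    m <- seg_metrics(confusion(pred, gt, classes[[i]]))
    m$class <- names(classes)[i]
    m
  })
  do.call(rbind, out)
}

#' ROC curve and AUC from continuous scores
#'
#' Threshold sweep over the scores with trapezoidal AUC (computed via the
#' pROC package). Scores are typically softmax probabilities of one class of
#' a stitched logit volume; any monotone transform of the logits leaves the
#' AUC unchanged.
#'
#' @param scores numeric vector
#' @param labels logical (or 0/1) vector, TRUE = positive
#' @return list with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stopf("ROC needs both positive and negative ground-truth pixels")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 quiet = TRUE, direction = "<", levels = c(FALSE, TRUE))
  ord <- order(1 - r$specificities, r$sensitivities)
  list(
    points = tibble::tibble(threshold = r$thresholds[ord],
                            fpr = (1 - r$specificities)[ord],
                            tpr = r$sensitivities[ord]),
    auc = as.numeric(pROC::auc(r))
  )
}

#' ROC/AUC of one class of a logit volume against a ground-truth mask
#'
#' Softmax probabilities of the chosen class, restricted to pixels covered
#' by at least one prediction patch, scored against the ground-truth label
#' mask at the volume's scale.
#'
#' @param vol a `logit_volume`
#' @param gt integer label mask with the volume's dimensions (0 background,
#'   k = k-th foreground class as in [volume_to_mask()])
#' @param class class name in `vol$classes` or label index
#' @return as [roc_auc()]
#' @export
volume_roc <- function(vol, gt, class) {
  stopifnot(inherits(vol, "logit_volume"))
  if (is.character(class)) {
    ci <- match(class, vol$classes)
    if (is.na(ci)) stopf("unknown class '%s'", class)
  } else ci <- as.integer(class) + 1L   # label k -> slab k+1
  if (!identical(dim(gt), dim(vol$counts)))
    stopf("ground-truth mask does not match volume dimensions")
  k <- dim(vol$data)[3]
  pr <- softmax_rows(matrix(vol$data, ncol = k))[, ci]
  keep <- as.numeric(vol$counts) > 0
  roc_auc(pr[keep], as.numeric(gt)[keep] == (ci - 1L))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater: the inter-rater
#' reliability model for continuous scores where both slides and raters are
#' random samples. Estimated from the two-way ANOVA mean squares
#' (`MSR` rows/subjects, `MSC` columns/raters, `MSE` residual):
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' The p-value tests r = 0 against r > 0 via `F = MSR/MSE` with
#' `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param mat numeric matrix, slides (subjects) in rows, raters in columns,
#'   no missing cells
#' @return list with `icc`, `F`, `df1`, `df2`, `p`, and a `degenerate` flag
#'   (TRUE when there is no variance across slides)
#' @export
icc <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stopf("ICC needs a complete rating matrix")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) stopf("ICC needs >= 2 slides and >= 2 raters")
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- msr <= .Machine$double.eps
  icc_val <- if (degenerate) 0 else
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  f <- if (mse == 0) Inf else msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  list(icc = icc_val, F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       degenerate = degenerate)
}

#' Cohen's kappa for two categorical vectors
#'
#' @param a,b factors/vectors of equal length
#' @return kappa in [-1, 1]
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- union(unique(a), unique(b))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' UMAP + KNN class separability
#'
#' Quantifies how separable labelled groups are in a feature space:
#' features are embedded into two dimensions with UMAP, then a K-nearest
#' neighbor classifier is cross-validated on the embedding and Cohen's
#' kappa computed per neighborhood size; the maximum over the k grid is the
#' separability score. Deterministic given `seed`.
#'
#' @param features numeric matrix or data frame (non-numeric columns are
#'   dropped), one row per object
#' @param labels group label per row (>= 2 groups; every group needs at
#'   least `folds` members)
#' @param k_list neighborhood sizes to try (default odd 1..25)
#' @param folds cross-validation folds (default 10; figure captions in the
#'   field use 5 or 10 — it is a parameter here)
#' @param seed RNG seed for the embedding and fold assignment
#' @param n_neighbors UMAP neighborhood size (default 15, capped at n-1)
#' @return list with `kappa_per_k` (tibble `k`, `kappa`), `max_kappa`,
#'   `best_k`, and `embedding` (n x 2 matrix)
#' @export
separability <- function(features, labels, k_list = seq(1L, 25L, by = 2L),
                         folds = 10L, seed = 1L, n_neighbors = 15L) {
  if (is.data.frame(features))
    features <- as.matrix(features[vapply(features, is.numeric, logical(1))])
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stopf("separability needs >= 2 label groups")
  counts <- table(labels)
  if (any(counts < folds))
    stopf("group(s) smaller than the number of folds: %s",
          paste(names(counts)[counts < folds], collapse = ", "))
  keep <- apply(features, 2, function(col) stats::sd(col) > 0)
  x <- scale(features[, keep, drop = FALSE])
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  emb <- uwot::umap(x, n_components = 2L,
                    n_neighbors = min(n_neighbors, nrow(x) - 1L),
                    n_threads = 1L, n_sgd_threads = 0L)
  # stratified fold assignment
  fold <- integer(nrow(x))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  kappa <- vapply(k_list, function(k) {
    pred <- character(nrow(x))
    for (f in seq_len(folds)) {
      te <- fold == f
      pred[te] <- as.character(class::knn(emb[!te, , drop = FALSE],
                                          emb[te, , drop = FALSE],
                                          labels[!te], k = k))
    }
    cohen_kappa(pred, as.character(labels))
  }, numeric(1))
  list(kappa_per_k = tibble::tibble(k = as.integer(k_list), kappa = kappa),
       max_kappa = max(kappa), best_k = k_list[which.max(kappa)],
       embedding = emb)
}

#' Write a metrics table as JSON and CSV
#'
#' @param metrics tibble (e.g. from [evaluate_segmentation()])
#' @param stem output path without extension; writes `<stem>.json` and
#'   `<stem>.csv`
#' @return character vector of the two paths, invisibly
#' @export
export_metrics <- function(metrics, stem) {
  jp <- paste0(stem, ".json"); cp <- paste0(stem, ".csv")
  jsonlite::write_json(metrics, jp, dataframe = "rows", digits = NA)
  utils::write.csv(as.data.frame(metrics), cp, row.names = FALSE)
  invisible(c(jp, cp))
}
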