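counts_of <- function(tp, fp, fn, tn)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn, class = 1L),
            class = "confusion_counts")

test_that("segmentation metrics follow their closed forms", {
  # perfect prediction
  perfect <- seg_metrics(counts_of(50, 0, 0, 50))
  for (col in c("mcc", "f_score", "kappa", "iou", "sensitivity",
                "specificity", "precision", "accuracy"))
    expect_equal(perfect[[col]], 1)
  expect_false(perfect$degenerate)

  # hand-evaluated case
  m <- seg_metrics(counts_of(40, 10, 10, 40))
  expect_equal(m$mcc, 0.6)
  expect_equal(m$f_score, 0.8)
  expect_equal(m$kappa, 0.6)
  expect_equal(m$iou, 40 / 60)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$accuracy, 0.8)

  # empty ground truth and empty prediction: flagged degenerate, MCC 0
  d <- seg_metrics(counts_of(0, 0, 0, 100))
  expect_true(d$degenerate)
  expect_equal(d$mcc, 0)

  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3), 1),
               "differ in shape")
})

test_that("MCC is symmetric in pred/gt and invariant to joint relabelling", {
  set.seed(12)
  for (i in 1:20) {
    pred <- matrix(sample(0:2, 400, replace = TRUE), 20, 20)
    gt <- matrix(sample(0:2, 400, replace = TRUE), 20, 20)
    m1 <- seg_metrics(confusion(pred, gt, 1L))
    m2 <- seg_metrics(confusion(gt, pred, 1L))
    expect_equal(m1$mcc, m2$mcc)
    # swap labels 1 <-> 2 in both masks: class-2 metrics become class-1's
    swap <- function(m) { s <- m; s[m == 1] <- 2L; s[m == 2] <- 1L; s }
    m3 <- seg_metrics(confusion(swap(pred), swap(gt), 2L))
    m1$class <- m3$class <- NULL
    expect_equal(m1, m3)
  }
})

test_that("multi-class evaluation reports one-vs-rest rows per class", {
  pred <- matrix(c(0, 1, 2, 2), 2, 2)
  gt <- matrix(c(0, 1, 2, 1), 2, 2)
  tb <- evaluate_segmentation(pred, gt, c(a = 1L, b = 2L))
  expect_identical(tb$class, c("a", "b"))
  expect_equal(tb$sensitivity[1], 0.5)
  # identical masks: all ones
  tb2 <- evaluate_segmentation(gt, gt)
  expect_true(all(tb2$mcc == 1))
})

test_that("ROC/AUC agrees with rank-pair enumeration (Mann-Whitney)", {
  # perfectly separating scores
  expect_equal(roc_auc(c(9, 8, 2, 1) / 10, c(1, 1, 0, 0))$auc, 1)
  # constant scores carry no information
  expect_equal(roc_auc(rep(0.5, 20), rep(c(0, 1), 10))$auc, 0.5)
  # 4-pixel hand case
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_true(all(diff(r$points$tpr) >= 0))

  # random instances: AUC equals the normalized Mann-Whitney U
  set.seed(3)
  for (i in 1:10) {
    scores <- round(runif(40), 2)   # ties likely
    labels <- runif(40) < 0.4
    if (length(unique(labels)) < 2) next
    pos <- scores[labels]; neg <- scores[!labels]
    u <- 0
    for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
    expect_equal(roc_auc(scores, labels)$auc, u / (length(pos) * length(neg)),
                 tolerance = 1e-6)
  }

  expect_error(roc_auc(runif(5), rep(TRUE, 5)), "both positive and negative")
})

test_that("ROC from a logit volume scores the requested class on covered pixels", {
  vol <- structure(list(
    data = array(c(0, 0, 0, 0, 5, -5, 5, -5), c(2, 2, 2)),
    counts = matrix(c(1L, 1L, 1L, 0L), 2, 2),
    scale_factor = 8, classes = c("background", "a")
  ), class = "logit_volume")
  gt <- matrix(c(1L, 0L, 1L, 1L), 2, 2)   # last pixel uncovered -> dropped
  r <- volume_roc(vol, gt, "a")
  expect_equal(r$auc, 1)
  expect_error(volume_roc(vol, gt, "zz"), "unknown class")
  expect_error(volume_roc(vol, matrix(0L, 3, 3), "a"), "dimensions")
})

test_that("ICC(2,1) matches a two-way ANOVA variance-component oracle", {
  # identical raters: perfect reliability
  mat <- matrix(rep(c(2, 4, 6, 8, 10), 3), 5, 3)
  r <- icc(mat)
  expect_equal(r$icc, 1)
  expect_lt(r$p, 0.01)

  # textbook-style 6 slides x 4 raters matrix vs an independent aov() fit
  sf <- rbind(c(9, 2, 5, 8), c(6, 1, 3, 2), c(8, 4, 6, 8),
              c(7, 1, 2, 6), c(10, 5, 6, 9), c(6, 2, 4, 7))
  r2 <- icc(sf)
  df <- data.frame(y = as.vector(sf),
                   subject = factor(rep(1:6, 4)),
                   rater = factor(rep(1:4, each = 6)))
  av <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- av["subject", "Mean Sq"]; msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + (4 - 1) * mse + 4 * (msc - mse) / 6)
  expect_equal(r2$icc, oracle, tolerance = 1e-6)
  f_oracle <- msr / mse
  expect_equal(r2$F, f_oracle, tolerance = 1e-6)
  expect_equal(r2$p, stats::pf(f_oracle, 5, 15, lower.tail = FALSE),
               tolerance = 1e-9)

  # independent noise raters: ICC near zero
  set.seed(7)
  noise <- matrix(rnorm(50 * 3), 50, 3)
  rn <- icc(noise)
  expect_lt(abs(rn$icc), 3 / sqrt(50))

  # zero variance across slides: flagged degenerate
  rz <- icc(matrix(5, 4, 3))
  expect_true(rz$degenerate)
  expect_equal(rz$icc, 0)

  expect_error(icc(matrix(1:3, 3, 1)), ">= 2")
  expect_error(icc(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("Cohen's kappa matches its contingency-table definition", {
  a <- c("x", "x", "y", "y", "x", "y")
  b <- c("x", "y", "y", "y", "x", "x")
  tab <- table(a, b)
  po <- sum(diag(tab)) / 6
  pe <- sum(rowSums(tab) * colSums(tab)) / 36
  expect_equal(cohen_kappa(a, b), (po - pe) / (1 - pe))
  expect_equal(cohen_kappa(a, a), 1)
})

test_that("UMAP+KNN separability scores separated clusters high and permuted labels near zero", {
  set.seed(99)
  n <- 100L
  x <- matrix(rnorm(2 * n * 315), 2 * n, 315)
  # shift the second cluster by a fixed offset in every 5th dimension
  x[(n + 1):(2 * n), seq(1, 315, by = 5)] <-
    x[(n + 1):(2 * n), seq(1, 315, by = 5)] + 3
  labels <- rep(c("control", "disease"), each = n)

  sep <- separability(x, labels, folds = 10, seed = 1)
  expect_gte(sep$max_kappa, 0.9)
  expect_identical(nrow(sep$kappa_per_k), 13L)

  # deterministic given the seed
  sep2 <- separability(x, labels, folds = 10, seed = 1)
  expect_identical(sep$kappa_per_k, sep2$kappa_per_k)

  # permuted labels: no structure
  set.seed(5)
  perm <- sample(labels)
  sep0 <- separability(x, perm, folds = 10, seed = 1)
  expect_lt(abs(sep0$max_kappa), 0.25)

  expect_error(separability(x, rep("one", 2 * n)), ">= 2 label groups")
  expect_error(separability(x[1:15, ], rep(c("a", "b"), c(10, 5))),
               "smaller than the number of folds")
})
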