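test_that("stratified folds balance classes to within one sample", {
  y <- rep(c(0L, 1L), c(41, 119))
  fold <- stratified_kfold(y, k = 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  per_fold_min <- table(fold[y == 0])
  expect_true(all(per_fold_min %in% c(8, 9)))   # 41 = 5*8 + 1
  per_fold_maj <- table(fold[y == 1])
  expect_true(all(abs(per_fold_maj - 119 / 5) <= 1))
  expect_identical(stratified_kfold(y, 5, seed = 3), fold)
  expect_error(stratified_kfold(y, k = 1), "at least 2")
  expect_error(stratified_kfold(c(0, 1, 1, 1, 1, 1), k = 5), "at least k")
})

test_that("metric formulas match brute-force confusion arithmetic", {
  m <- compute_metrics(c(TP = 3, TN = 5, FP = 1, FN = 1))
  expect_equal(m[["sensitivity"]], 0.75)
  expect_equal(m[["specificity"]], 5 / 6, tolerance = 1e-4)
  expect_equal(m[["f1"]], 0.75)
  expect_equal(m[["acc"]], 0.8)
  # random prediction sets vs direct counting
  set.seed(19)
  for (i in 1:50) {
    truth <- sample(0:1, 30, replace = TRUE)
    pred <- sample(0:1, 30, replace = TRUE)
    cts <- confusion_counts(pred, truth, positive = 1)
    expect_equal(sum(cts), 30)
    expect_equal(cts[["TP"]], sum(pred == 1 & truth == 1))
    m <- compute_metrics(cts)
    if (any(truth == 1)) {
      expect_equal(m[["sensitivity"]],
                   sum(pred == 1 & truth == 1) / sum(truth == 1))
    }
    expect_equal(m[["acc"]], mean(pred == truth))
  }
})

test_that("AUROC equals pairwise-ordering count and the Mann-Whitney U", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0)), 0.75)
  set.seed(29)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    pos <- which(lab == 1); neg <- which(lab == 0)
    pairs <- expand.grid(p = pos, n = neg)
    brute <- mean(ifelse(sc[pairs$p] > sc[pairs$n], 1,
                         ifelse(sc[pairs$p] == sc[pairs$n], 0.5, 0)))
    expect_equal(auroc(sc, lab), brute, tolerance = 1e-12)
    u <- suppressWarnings(wilcox.test(sc[lab == 1], sc[lab == 0]))$statistic
    expect_equal(auroc(sc, lab), unname(u) / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  sc <- rnorm(60)
  lab <- sample(0:1, 60, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(sc, lab), ref, tolerance = 1e-12)
})

test_that("SVM fold training separates constructed clusters", {
  set.seed(41)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  y <- rep(c(0, 1), each = 30)
  tr <- c(1:20, 31:50); te <- setdiff(1:60, tr)
  ev <- train_eval_fold(X[tr, ], y[tr], X[te, ], y[te])
  m <- compute_metrics(ev$counts, ev$scores, y[te])
  expect_equal(m[["acc"]], 1)
  expect_equal(m[["auroc"]], 1)
  # scores orient toward the positive class
  expect_gt(mean(ev$scores[y[te] == 1]), mean(ev$scores[y[te] == 0]))
  # duplicating every training sample leaves predictions unchanged
  ev2 <- train_eval_fold(X[c(tr, tr), ], y[c(tr, tr)], X[te, ], y[te])
  expect_equal(ev2$predictions, ev$predictions)
  expect_error(train_eval_fold(X[1:10, ], rep(0, 10), X[te, ], y[te]),
               "single-class")
})

test_that("cross-validation is leakage-safe and calibrated", {
  set.seed(43)
  n <- 200; p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c(0L, 1L), each = 100)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + 2.5
  rep1 <- cross_validate(X, y, k = 5, seed = 7, variance_threshold = 1e-8)
  expect_gt(rep1$mean[["auroc"]], 0.9)
  expect_false(rep1$partial)
  # identical metric across folds -> SD 0 (degenerate check on acc of a
  # perfectly separable problem)
  Xs <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
              matrix(rnorm(100, 9, 0.1), 50, 2))
  colnames(Xs) <- c("a", "b")
  ys <- rep(c(0L, 1L), each = 50)
  rs <- cross_validate(Xs, ys, k = 5, seed = 1, variance_threshold = 1e-8,
                       alpha = 0.5)
  expect_equal(unname(rs$sd[["acc"]]), 0)
  # permuted labels: mean AUROC near one half
  yp <- sample(y)
  rep0 <- cross_validate(X, yp, k = 5, seed = 7, variance_threshold = 1e-8)
  expect_gt(rep0$mean[["auroc"]], 0.3)
  expect_lt(rep0$mean[["auroc"]], 0.7)
  # determinism given the seed
  rep1b <- cross_validate(X, y, k = 5, seed = 7, variance_threshold = 1e-8)
  expect_identical(rep1$per_fold, rep1b$per_fold)
})

test_that("per-map reports follow the study-table layout", {
  set.seed(47)
  n <- 80
  X <- cbind(matrix(rnorm(n * 4), n, 4), matrix(rnorm(n * 4), n, 4))
  colnames(X) <- c(paste0("MSI__original__firstorder__", c("a", "b", "c", "d")),
                   paste0("rCBV__original__firstorder__", c("a", "b", "c", "d")))
  y <- rep(c(0L, 1L), each = n / 2)
  X[y == 1, 1:2] <- X[y == 1, 1:2] + 2
  res <- per_map_cv(list(features = X, labels = y), maps = c("MSI", "rCBV"),
                    k = 4, seed = 3, variance_threshold = 1e-8)
  expect_equal(rownames(res$summary), c("MSI", "rCBV"))
  expect_equal(colnames(res$summary),
               c("sensitivity", "specificity", "f1", "acc", "auroc"))
  expect_equal(res$best_map, "MSI")
  expect_gt(res$summary["MSI", "auroc"], res$summary["rCBV", "auroc"])
})
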