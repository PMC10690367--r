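# Stratified cross-validated SVM-RBF classification with the full
# per-fold pipeline (selection -> z-scoring -> SMOTE -> SVM) fitted on
# training data only, and evaluation on untouched test folds.

#' Stratified k-fold assignment
#'
#' Shuffles each class separately (seeded) and deals samples round-robin
#' into k folds, so per-fold class counts differ from proportional by at
#' most 1. Deterministic given the seed.
#'
#' @param labels class labels.
#' @param k number of folds (>= 2; every class must have >= k members).
#' @param seed RNG seed.
#' @return integer vector of fold indices (1..k) per sample.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be at least 2 (no test set otherwise)",
                  call. = FALSE)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " samples", call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(derive_seed(seed, "fold"), {
    for (cl in names(tab)) {
      idx <- which(labels == type.convert(cl, as.is = TRUE))
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' SVM-RBF configuration
#'
#' Defaults follow the flat (no inner grid search) scheme: cost C = 1 and
#' RBF bandwidth gamma = 1 / (p * var(X)) (the "scale" heuristic), both
#' overridable.
#'
#' @param cost SVM cost parameter.
#' @param gamma RBF bandwidth; NULL = scale heuristic at train time.
#' @return list of class \code{svm_config}.
#' @export
svm_config <- function(cost = 1, gamma = NULL) {
  structure(list(cost = cost, gamma = gamma), class = "svm_config")
}

#' Train an SVM-RBF on one fold and evaluate on its test set
#'
#' The features arrive already selected/standardized/balanced by the caller
#' (see [cross_validate()] for the leakage-safe orchestration). Returns hard
#' predictions, decision scores oriented so larger = more positive-class,
#' and the confusion counts.
#'
#' @param X_train,y_train training features and labels (binary; the larger
#'   label value is the positive class).
#' @param X_test,y_test test features and labels.
#' @param config an [svm_config()].
#' @return list with \code{counts} (TP/TN/FP/FN), \code{scores},
#'   \code{predictions}, \code{model}.
#' @export
train_eval_fold <- function(X_train, y_train, X_test, y_test,
                            config = svm_config()) {
  if (length(unique(y_train)) < 2) {
    stop("degenerate single-class training fold", call. = FALSE)
  }
  pos <- max(y_train)
  gamma <- config$gamma
  if (is.null(gamma)) {
    v <- var(as.vector(X_train))
    gamma <- if (v > 0) 1 / (ncol(X_train) * v) else 1 / ncol(X_train)
  }
  fit <- e1071::svm(X_train, factor(y_train), kernel = "radial",
                    cost = config$cost, gamma = gamma, scale = FALSE,
                    probability = FALSE)
  pr <- predict(fit, X_test, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # e1071 orients the decision value toward the first level in the
  # colname "a/b": positive value favors class a. Re-orient toward `pos`.
  dv_name <- colnames(attr(pr, "decision.values"))[1]
  first_cls <- strsplit(dv_name, "/")[[1]][1]
  scores <- if (first_cls == as.character(pos)) dv else -dv
  pred <- as.numeric(as.character(pr))
  counts <- confusion_counts(pred, y_test, positive = pos)
  list(counts = counts, scores = unname(scores), predictions = pred,
       model = fit)
}

#' Confusion counts for binary predictions
#' @param pred,truth label vectors.
#' @param positive the positive-class label value.
#' @return named integer vector TP, TN, FP, FN.
#' @export
confusion_counts <- function(pred, truth, positive = max(truth)) {
  c(TP = sum(pred == positive & truth == positive),
    TN = sum(pred != positive & truth != positive),
    FP = sum(pred == positive & truth != positive),
    FN = sum(pred != positive & truth == positive))
}

#' Classification metrics from confusion counts and scores
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(FP+TN),
#' F1 = TP/(TP + 0.5 (FP+FN)), ACC = (TP+TN)/total; AUROC is the
#' Mann-Whitney pairwise-ordering statistic of the scores (ties count 1/2).
#' Metrics whose denominator is empty are NA and flagged.
#'
#' @param counts named vector TP/TN/FP/FN.
#' @param scores decision scores (larger = more positive).
#' @param labels binary labels matching \code{scores}.
#' @return named numeric vector sensitivity, specificity, f1, acc, auroc.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (FP + TN > 0) TN / (FP + TN) else NA_real_
  f1 <- if (TP + 0.5 * (FP + FN) > 0) TP / (TP + 0.5 * (FP + FN)) else NA_real_
  acc <- (TP + TN) / (TP + TN + FP + FN)
  auc <- if (!is.null(scores)) auroc(scores, labels) else NA_real_
  c(sensitivity = sens, specificity = spec, f1 = f1, acc = acc, auroc = auc)
}

#' Area under the ROC curve by rank statistic
#'
#' Equals the fraction of (positive, negative) score pairs ordered
#' correctly, ties counting one half (the Mann-Whitney U statistic divided
#' by n+ * n-).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels; positive class = larger value.
#' @return AUROC in [0, 1], or NA if a class is absent.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == max(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated per-map classification pipeline
#'
#' Runs the study pipeline inside each training fold only: three-step
#' feature selection ([select_features()]), z-scoring with train-fold
#' statistics, SMOTE balancing, then SVM-RBF training; the untouched test
#' fold is projected through the fitted selection/scaling and scored.
#'
#' @param X raw feature matrix (samples x features).
#' @param y binary labels (0/1; 1 = positive class).
#' @param k number of folds.
#' @param seed global seed (fold/SMOTE streams derived from it).
#' @param variance_threshold,alpha,C selection-chain thresholds.
#' @param smote_ratio target minority/majority ratio inside training folds
#'   (NULL disables SMOTE).
#' @param config an [svm_config()].
#' @return object of class \code{cv_report}: \code{per_fold} (metric
#'   matrix), \code{mean}, \code{sd}, \code{folds}, \code{selected} (per
#'   fold), \code{partial} flag.
#' @export
cross_validate <- function(X, y, k = 5L, seed = 1L,
                           variance_threshold = 0.5, alpha = 0.05, C = 0.3,
                           smote_ratio = 1, config = svm_config()) {
  fold <- stratified_kfold(y, k, seed)
  metrics <- matrix(NA_real_, nrow = k, ncol = 5,
                    dimnames = list(NULL, c("sensitivity", "specificity",
                                            "f1", "acc", "auroc")))
  selected <- vector("list", k)
  partial <- FALSE
  for (f in seq_len(k)) {
    res <- tryCatch({
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
      sel <- select_features(Xtr, ytr, variance_threshold, alpha, C)
      # fall back one step at a time if a later stage eliminates everything,
      # so every fold still produces a classifier on comparable inputs
      feats <- if (length(sel$step3)) sel$step3 else
        if (length(sel$step2)) sel$step2 else sel$step1
      mu <- colMeans(Xtr[, feats, drop = FALSE])
      sdv <- apply(Xtr[, feats, drop = FALSE], 2, sd)
      Ztr <- scale_with(Xtr[, feats, drop = FALSE], mu, sdv)
      Zte <- scale_with(Xte[, feats, drop = FALSE], mu, sdv)
      if (!is.null(smote_ratio)) {
        bal <- smote(Ztr, ytr, target_ratio = smote_ratio,
                     seed = derive_seed(seed, "smote") + f)
        Ztr <- bal$X; ytr <- bal$y
      }
      ev <- train_eval_fold(Ztr, ytr, Zte, yte, config)
      list(metrics = compute_metrics(ev$counts, ev$scores, yte),
           selected = feats)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      partial <- TRUE
      next
    }
    metrics[f, ] <- res$metrics
    selected[[f]] <- res$selected
  }
  structure(list(per_fold = metrics,
                 mean = colMeans(metrics, na.rm = TRUE),
                 sd = apply(metrics, 2, sd, na.rm = TRUE),
                 folds = fold, selected = selected, partial = partial),
            class = "cv_report")
}

scale_with <- function(X, mu, sdv) {
  sdv[sdv == 0] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, `/`)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report (", nrow(x$per_fold), "folds )\n")
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(100 * m, 1))
  if (x$partial) cat("NOTE: one or more folds failed; report is partial\n")
  invisible(x)
}

#' Per-map cross-validated benchmark over a phantom cohort
#'
#' The end-to-end study design: one classifier per parametric map, each run
#' through the leakage-safe [cross_validate()] pipeline; reports mean +/- SD
#' metrics per map (rows = maps, the study-table layout) and the
#' best-accuracy map.
#'
#' @param table cohort feature table from [cohort_feature_table()].
#' @param maps character vector of map names present in the table columns.
#' @param ... passed to [cross_validate()].
#' @return list with \code{reports} (per map), \code{summary} (matrix of
#'   mean metrics x maps), \code{best_map} (highest mean accuracy).
#' @export
per_map_cv <- function(table, maps, ...) {
  reports <- lapply(maps, function(m) {
    cols <- grep(paste0("^", m, "__"), colnames(table$features), value = TRUE)
    if (!length(cols)) stop("no feature columns for map ", m, call. = FALSE)
    cross_validate(table$features[, cols, drop = FALSE], table$labels, ...)
  })
  names(reports) <- maps
  summary <- t(vapply(reports, `[[`, numeric(5), "mean"))
  best <- maps[which.max(summary[, "acc"])]
  list(reports = reports, summary = summary, best_map = best)
}
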