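# Three-step feature selection: variance threshold -> univariate ANOVA ->
# L1-penalized logistic regression, with the survivors of each step nested
# in the previous one.

#' Variance threshold filter
#'
#' Removes near-constant features: keeps columns whose population variance
#' (divisor n, matching the convention of the upstream feature extractor) is
#' at least \code{threshold}.
#'
#' @param X numeric feature matrix (samples x features, named columns).
#' @param threshold minimum variance to keep (default 0.5).
#' @return character vector of surviving column names, with the per-column
#'   variances as attribute \code{variances}.
#' @export
variance_filter <- function(X, threshold = 0.5) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  n <- nrow(X)
  v <- apply(X, 2, function(col) mean((col - mean(col))^2))
  keep <- colnames(X)[v >= threshold]
  if (!length(keep)) {
    stop("variance filter removed every feature; consider rescaling the ",
         "features or lowering the threshold", call. = FALSE)
  }
  structure(keep, variances = v)
}

#' Univariate one-way ANOVA filter for a binary outcome
#'
#' Computes the one-way F statistic of each feature against the class labels
#' and keeps features with p < \code{alpha}. For two groups, F is the square
#' of the equal-variance two-sample t statistic.
#'
#' @param X numeric feature matrix.
#' @param y binary labels (two distinct values, each present).
#' @param alpha retention p-value threshold (default 0.05).
#' @return character vector of surviving column names, with attributes
#'   \code{F} and \code{p} (per input column).
#' @export
anova_filter <- function(X, y, alpha = 0.05) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  groups <- unique(y)
  if (length(groups) < 2) stop("both classes must be present", call. = FALSE)
  n <- nrow(X)
  k <- length(groups)
  gidx <- lapply(groups, function(g) which(y == g))
  ns <- vapply(gidx, length, integer(1))
  grand <- colMeans(X)
  gmeans <- vapply(gidx, function(ix) colMeans(X[ix, , drop = FALSE]),
                   numeric(ncol(X)))
  if (is.vector(gmeans)) gmeans <- matrix(gmeans, nrow = 1)
  ss_between <- drop((gmeans - grand)^2 %*% ns)
  ss_total <- colSums(sweep(X, 2, grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1
  df2 <- n - k
  Fstat <- (ss_between / df1) / (ss_within / df2)
  Fstat[ss_within == 0 & ss_between == 0] <- 0
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  keep <- colnames(X)[is.finite(p) & p < alpha]
  structure(keep, F = Fstat, p = p)
}

#' L1-penalized logistic-regression feature selection
#'
#' Fits an L1-penalized logistic regression at a single penalty expressed in
#' the inverse-regularization convention C (objective
#' \eqn{\sum_i \log(1 + e^{-y_i x_i^T w}) + \|w\|_1 / C}); features with a
#' nonzero coefficient (|w| > 1e-5) survive. Columns are expected
#' standardized; the fit itself does no rescaling so the penalty acts on the
#' caller's scale. Backed by the coordinate-descent solver of \pkg{glmnet}
#' with \code{lambda = 1 / (n C)}.
#'
#' @param X standardized numeric feature matrix.
#' @param y binary labels.
#' @param C inverse regularization strength (default 0.3).
#' @return character vector of surviving column names with attribute
#'   \code{weights} (all input columns).
#' @export
l1_logistic_select <- function(X, y, C = 0.3) {
  stopifnot(is.matrix(X), nrow(X) == length(y), C > 0)
  yf <- as.integer(factor(y)) - 1L
  lambda <- 1 / (nrow(X) * C)
  orig_cols <- colnames(X)
  if (ncol(X) == 1L) {
    # the solver requires >= 2 columns; a zero column is penalty-neutral
    X <- cbind(X, `.zero.pad` = 0)
  }
  fit <- glmnet::glmnet(X, yf, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-10, maxit = 1e5)
  w <- as.numeric(fit$beta)
  names(w) <- colnames(X)
  w <- w[orig_cols]
  if (fit$jerr != 0 && abs(fit$jerr) > 1) {
    stop("L1 logistic solver did not converge (glmnet jerr = ", fit$jerr,
         ")", call. = FALSE)
  }
  keep <- orig_cols[abs(w) > 1e-5]
  structure(keep, weights = w)
}

#' Run the full three-step selection chain
#'
#' Variance filter on the raw features, ANOVA on the survivors, z-scoring
#' (using the supplied matrix's own statistics), then L1-logistic selection.
#' The survivors of each step are nested in the previous step's.
#'
#' @param X raw feature matrix.
#' @param y binary labels.
#' @param variance_threshold step-1 threshold.
#' @param alpha step-2 ANOVA p threshold.
#' @param C step-3 inverse regularization.
#' @return object of class \code{selection_report}: list with
#'   \code{step1, step2, step3} (surviving names), \code{F}, \code{p},
#'   \code{weights}, \code{scaling} (means/sds used for the z-score), and
#'   \code{thresholds}.
#' @export
select_features <- function(X, y, variance_threshold = 0.5, alpha = 0.05,
                            C = 0.3) {
  s1 <- variance_filter(X, variance_threshold)
  X1 <- X[, s1, drop = FALSE]
  s2 <- anova_filter(X1, y, alpha)
  if (!length(s2)) {
    return(structure(list(step1 = as.character(s1), step2 = character(0),
                          step3 = character(0),
                          F = attr(s2, "F"), p = attr(s2, "p"),
                          weights = NULL, scaling = NULL,
                          thresholds = list(variance = variance_threshold,
                                            alpha = alpha, C = C)),
                     class = "selection_report"))
  }
  X2 <- X1[, s2, drop = FALSE]
  mu <- colMeans(X2)
  sd2 <- apply(X2, 2, sd)
  sd2[sd2 == 0] <- 1
  Z <- sweep(sweep(X2, 2, mu), 2, sd2, `/`)
  s3 <- l1_logistic_select(Z, y, C)
  structure(list(step1 = as.character(s1), step2 = as.character(s2),
                 step3 = as.character(s3),
                 F = attr(s2, "F"), p = attr(s2, "p"),
                 weights = attr(s3, "weights"),
                 scaling = list(mean = mu, sd = sd2),
                 thresholds = list(variance = variance_threshold,
                                   alpha = alpha, C = C)),
            class = "selection_report")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' For each synthetic sample: pick a minority sample x, pick one of its
#' \code{k_neighbors} nearest minority neighbors x_nn (Euclidean distance),
#' and emit \eqn{x + \lambda (x_{nn} - x)} with \eqn{\lambda \sim U(0, 1)} —
#' a point on the segment between the two parents. Samples are generated
#' round-robin over the minority set until the minority/majority ratio
#' reaches \code{target_ratio} (1 = full balance).
#'
#' @param X numeric feature matrix.
#' @param y binary labels; the rarer value is the minority class.
#' @param k_neighbors number of nearest neighbors to draw from (default 5,
#'   capped at minority size - 1).
#' @param target_ratio desired minority/majority count ratio after
#'   augmentation.
#' @param seed RNG seed for neighbor and lambda draws.
#' @return list of class \code{balanced_set}: \code{X}, \code{y} (originals
#'   then synthetics), \code{synthetic} (logical), and \code{provenance}
#'   (data.frame: parent row indices i, j and lambda per synthetic sample).
#' @export
smote <- function(X, y, k_neighbors = 5L, target_ratio = 1, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  tab <- sort(table(y))
  minority <- names(tab)[1]
  n_min <- tab[[1]]
  n_maj <- tab[[length(tab)]]
  if (n_min < 2) stop("SMOTE needs at least 2 minority samples",
                      call. = FALSE)
  k <- min(k_neighbors, n_min - 1L)
  n_new <- max(0L, as.integer(round(target_ratio * n_maj)) - n_min)
  min_idx <- which(y == ifelse(is.numeric(y), as.numeric(minority), minority))
  Xm <- X[min_idx, , drop = FALSE]
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(row) order(row)[seq_len(k)]))
  if (k == 1L) nn <- matrix(nn, ncol = 1)

  prov <- data.frame(i = integer(n_new), j = integer(n_new),
                     lambda = numeric(n_new))
  synth <- matrix(NA_real_, nrow = n_new, ncol = ncol(X),
                  dimnames = list(NULL, colnames(X)))
  if (n_new > 0) {
    with_seed(seed, {
      base_seq <- rep(seq_len(n_min), length.out = n_new)
      picks <- sample.int(k, n_new, replace = TRUE)
      lambdas <- runif(n_new)
      for (s in seq_len(n_new)) {
        i <- base_seq[s]
        j <- nn[i, picks[s]]
        synth[s, ] <- Xm[i, ] + lambdas[s] * (Xm[j, ] - Xm[i, ])
        prov$i[s] <- min_idx[i]
        prov$j[s] <- min_idx[j]
        prov$lambda[s] <- lambdas[s]
      }
    })
  }
  y_min_val <- y[min_idx[1]]
  structure(list(X = rbind(X, synth),
                 y = c(y, rep(y_min_val, n_new)),
                 synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)),
                 provenance = prov),
            class = "balanced_set")
}
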