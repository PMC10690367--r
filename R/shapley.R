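# Shapley-value feature attribution for fitted models.
#
# The Shapley value of feature i for an input x is its average marginal
# contribution over all coalitions S of the other features, where "feature
# absent" means its value is drawn from a background data set
# (interventional convention): v(S) = mean over background rows b of
# f(x_S, b_{~S}). Exact mode enumerates all 2^p coalitions (p <= 12);
# sampled mode averages marginal contributions over random feature
# permutations.

#' Shapley attributions for a set of inputs
#'
#' @param predict_fun function taking a numeric matrix (rows = inputs) and
#'   returning a numeric vector of model outputs (e.g. decision scores).
#' @param X_explain matrix of inputs to explain (rows).
#' @param X_background matrix of background samples defining "absence".
#' @param mode "exact" (enumerate all coalitions; requires p <= 12) or
#'   "sampled" (permutation Monte-Carlo).
#' @param n_permutations permutations per explained row in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @return object of class \code{shap_summary}: \code{values} (matrix,
#'   rows = explained samples, cols = features), \code{base_value} (mean
#'   background prediction), \code{ranking} (feature names by decreasing
#'   mean |value|).
#' @export
shapley_summary <- function(predict_fun, X_explain, X_background,
                            mode = c("exact", "sampled"),
                            n_permutations = 200L, seed = 1L) {
  mode <- match.arg(mode)
  X_explain <- as.matrix(X_explain)
  X_background <- as.matrix(X_background)
  p <- ncol(X_explain)
  stopifnot(ncol(X_background) == p)
  if (mode == "exact" && p > 12) {
    stop("exact mode enumerates 2^p coalitions and is limited to p <= 12; ",
         "use mode = \"sampled\"", call. = FALSE)
  }
  vals <- if (mode == "exact") {
    t(apply(X_explain, 1, shap_exact_row, predict_fun = predict_fun,
            B = X_background))
  } else {
    t(vapply(seq_len(nrow(X_explain)), function(i) {
      shap_sampled_row(X_explain[i, ], predict_fun, X_background,
                       n_permutations, seed + i - 1L)
    }, numeric(p)))
  }
  if (p == 1) vals <- matrix(vals, ncol = 1)
  colnames(vals) <- colnames(X_explain)
  base <- mean(predict_fun(X_background))
  rk <- order(colMeans(abs(vals)), decreasing = TRUE)
  structure(list(values = vals, base_value = base,
                 ranking = colnames(X_explain)[rk]),
            class = "shap_summary")
}

# Exact Shapley for one row: enumerate all 2^p coalitions, evaluate
# v(S) = mean_b f(x_S, b_{~S}) with one batched predict call, and combine
# with the Shapley kernel weights |S|!(p-|S|-1)!/p!.
shap_exact_row <- function(x, predict_fun, B) {
  p <- length(x)
  nb <- nrow(B)
  n_coal <- 2^p
  member <- matrix(FALSE, n_coal, p)
  for (j in seq_len(p)) {
    member[, j] <- bitwAnd(seq_len(n_coal) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  # batched evaluation: rows = coalition x background
  big <- B[rep(seq_len(nb), times = n_coal), , drop = FALSE]
  coal_of_row <- rep(seq_len(n_coal), each = nb)
  for (j in seq_len(p)) {
    rows_with_j <- member[coal_of_row, j]
    big[rows_with_j, j] <- x[j]
  }
  preds <- predict_fun(big)
  v <- vapply(split(preds, coal_of_row), mean, numeric(1))
  sizes <- rowSums(member)
  phi <- numeric(p)
  lfact <- lfactorial(0:p)
  for (j in seq_len(p)) {
    without <- which(!member[, j])
    with_j <- without + 2^(j - 1)  # same coalition plus feature j
    s <- sizes[without]
    w <- exp(lfact[s + 1] + lfact[p - s] - lfact[p + 1])
    phi[j] <- sum(w * (v[with_j] - v[without]))
  }
  phi
}

# Permutation-sampling Shapley for one row: for each random permutation,
# walk the features in order, replacing background values by x one at a
# time; the prediction increments are the marginal contributions. One
# background row per permutation, cycled.
shap_sampled_row <- function(x, predict_fun, B, n_perm, seed) {
  p <- length(x)
  nb <- nrow(B)
  with_seed(seed, {
    perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
    b_rows <- rep_len(seq_len(nb), n_perm)
    # build all (p+1) prefix states per permutation and predict in one batch
    states <- matrix(NA_real_, nrow = n_perm * (p + 1), ncol = p)
    for (k in seq_len(n_perm)) {
      st <- B[b_rows[k], ]
      base_row <- (k - 1L) * (p + 1L)
      states[base_row + 1L, ] <- st
      for (step in seq_len(p)) {
        st[perms[[k]][step]] <- x[perms[[k]][step]]
        states[base_row + step + 1L, ] <- st
      }
    }
    preds <- predict_fun(states)
    phi <- numeric(p)
    for (k in seq_len(n_perm)) {
      base_row <- (k - 1L) * (p + 1L)
      inc <- diff(preds[base_row + seq_len(p + 1L)])
      phi[perms[[k]]] <- phi[perms[[k]]] + inc
    }
    phi / n_perm
  })
}
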