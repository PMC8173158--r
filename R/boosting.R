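#' Fit a discrete AdaBoost ensemble of shallow classification trees
#'
#' One hundred depth-limited decision trees are fitted sequentially under the
#' discrete AdaBoost weight scheme: starting from uniform sample weights
#' `D_1 = 1/m`, each round fits a weak tree to the weighted sample, computes
#' the weighted misclassification error `eps_n = sum(D_n[h_n(x_i) != y_i])`,
#' assigns the classifier weight `alpha_n = 0.5 * log((1 - eps_n) / eps_n)`,
#' multiplies misclassified-sample weights by `sqrt((1 - eps_n) / eps_n)` and
#' correctly classified ones by `sqrt(eps_n / (1 - eps_n))`, and
#' renormalizes. A round with zero error terminates boosting with that
#' learner dominant; a round with error at or above one half discards the
#' learner, resets the weights to uniform and refits on a bootstrap
#' resample.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels (0/1), both classes present.
#' @param n_estimators boosting rounds (default 100).
#' @param max_depth weak-learner tree depth (default 2).
#' @param min_leaf minimum samples per leaf (default 1).
#' @param init_weights optional non-uniform starting weights (normalized
#'   internally); used for class-mass balancing.
#' @param seed integer seed (bootstrap resampling on degenerate rounds).
#' @return An object of class `boosted_ensemble` with elements `trees`,
#'   `alphas`, `features`, `errors`.
#' @export
boost_fit <- function(X, y, n_estimators = 100, max_depth = 2,
                      min_leaf = 1, init_weights = NULL, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- as.matrix(X)
  m <- nrow(X)
  set.seed(seed)
  D <- if (is.null(init_weights)) rep(1 / m, m) else init_weights / sum(init_weights)
  fit <- cpp_ada_fit(X, y, D, n_estimators, max_depth, min_leaf)
  structure(list(trees = fit$trees, alphas = fit$alphas,
                 errors = fit$errors,
                 features = colnames(X), classes = c(0L, 1L)),
            class = "boosted_ensemble")
}

#' Predict labels and real-valued margins from a boosted ensemble
#'
#' The margin is `sum_n alpha_n * (2 h_n(x) - 1)`; the label is 1 for a
#' positive margin and 0 otherwise.
#'
#' @param model a `boosted_ensemble`.
#' @param X numeric matrix with the model's feature columns.
#' @return A list `labels` (integer 0/1) and `margins` (numeric).
#' @export
boost_predict <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features)) {
    if (!all(model$features %in% colnames(X)))
      stop("X lacks model features: ",
           paste(setdiff(model$features, colnames(X)), collapse = ", "))
    X <- X[, model$features, drop = FALSE]
  }
  margins <- cpp_ada_margin(model$trees, model$alphas, X)
  list(labels = as.integer(margins > 0), margins = margins)
}

#' @export
print.boosted_ensemble <- function(x, ...) {
  cat(sprintf("<boosted_ensemble> %d weak trees, alpha in [%.3f, %.3f]\n",
              length(x$trees), min(x$alphas), max(x$alphas)))
  invisible(x)
}
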