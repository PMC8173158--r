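make_stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    rows <- which(y == cls)
    fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  fold
}

#' Select the marker dimension by a cross-validated top-k sweep
#'
#' For each `k` up to `k_max`, a boosted ensemble is cross-validated on the
#' top-`k` features of the supplied ranking (stratified folds, shared across
#' all `k`); the `k` maximizing mean CV accuracy is selected, ties broken
#' toward the smallest `k`, and the final model is refitted on all data with
#' that `k`.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels (0/1).
#' @param ranked_sites character vector of feature IDs in rank order
#'   (e.g. from [relieff_rank()]).
#' @param k_max largest candidate dimension (default 50).
#' @param folds CV folds (default 10).
#' @param n_estimators boosting rounds per fit (default 100).
#' @param seed integer seed (fold assignment and boosting streams).
#' @return An object of class `marker_set`: `ranked_site_ids`,
#'   `selected_k`, `selected_sites`, `cv_accuracy_by_k`, `final_model`.
#' @export
select_top_k_cv <- function(X, y, ranked_sites, k_max = 50, folds = 10,
                            n_estimators = 100, seed = 1L) {
  y <- as.integer(y)
  stopifnot(k_max >= 1, folds >= 2, min(table(y)) >= folds)
  ranked_sites <- ranked_sites[ranked_sites %in% colnames(X)]
  k_max <- min(k_max, length(ranked_sites))
  fold <- make_stratified_folds(y, folds, derive_seed(seed, "folds"))
  acc <- matrix(NA_real_, folds, k_max)
  for (k in seq_len(k_max)) {
    feats <- ranked_sites[seq_len(k)]
    for (f in seq_len(folds)) {
      tr <- fold != f
      model <- boost_fit(X[tr, feats, drop = FALSE], y[tr],
                         n_estimators = n_estimators,
                         seed = derive_seed(seed, paste0("boost", k, "_", f)))
      pred <- boost_predict(model, X[!tr, feats, drop = FALSE])$labels
      acc[f, k] <- mean(pred == y[!tr])
    }
  }
  mean_acc <- colMeans(acc)
  selected_k <- which.max(mean_acc)  # which.max takes the first maximum
  feats <- ranked_sites[seq_len(selected_k)]
  final <- boost_fit(X[, feats, drop = FALSE], y,
                     n_estimators = n_estimators,
                     seed = derive_seed(seed, "final"))
  structure(list(ranked_site_ids = ranked_sites,
                 selected_k = selected_k,
                 selected_sites = feats,
                 cv_accuracy_by_k = mean_acc,
                 final_model = final),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> selected k = %d (CV accuracy %.3f)\n",
              x$selected_k, x$cv_accuracy_by_k[x$selected_k]))
  invisible(x)
}

#' Disease marker selection with control subgrouping for class balance
#'
#' The (larger) control sample is partitioned into `n_subgroups` random
#' near-equal subgroups; each subgroup paired with the full disease sample
#' forms a balanced task on which feature ranking and the CV sweep are run.
#' Rankings are aggregated by rank-sum across pairings, the selected
#' dimension is the rounded median of the per-pairing selections, and the
#' final ensemble is trained on all controls plus the disease sample with
#' per-sample weights equalizing the two class masses.
#'
#' @param X_controls,X_disease numeric matrices over identical feature
#'   columns (controls coded 0, disease 1).
#' @param n_subgroups control partitions (study pattern: AD 3, PD 9, PSP 7,
#'   FTD 3).
#' @param k_max,folds,n_estimators,n_neighbors passed to the per-pairing
#'   ranking and sweep.
#' @param seed integer seed.
#' @return A `marker_set` with extra fields `per_pairing_k` and
#'   `rank_sum`.
#' @export
balanced_disease_fit <- function(X_controls, X_disease, n_subgroups,
                                 k_max = 50, folds = 10,
                                 n_estimators = 100, n_neighbors = 30,
                                 seed = 1L) {
  stopifnot(n_subgroups >= 1,
            identical(colnames(X_controls), colnames(X_disease)))
  n_ctrl <- nrow(X_controls)
  n_dis <- nrow(X_disease)
  if (n_ctrl / n_subgroups > 10 * n_dis)
    warning("control subgroups are > 10x the disease sample")
  set.seed(derive_seed(seed, "partition"))
  part <- sample(rep_len(seq_len(n_subgroups), n_ctrl))

  sites <- colnames(X_controls)
  rank_sum <- setNames(numeric(length(sites)), sites)
  per_k <- integer(n_subgroups)
  for (g in seq_len(n_subgroups)) {
    Xg <- rbind(X_controls[part == g, , drop = FALSE], X_disease)
    yg <- c(rep(0L, sum(part == g)), rep(1L, n_dis))
    rk <- relieff_rank(Xg, yg, n_neighbors = n_neighbors,
                       seed = derive_seed(seed, paste0("relieff", g)))
    rank_sum[rk$site_id] <- rank_sum[rk$site_id] + seq_along(rk$site_id)
    ms <- select_top_k_cv(Xg, yg, rk$site_id, k_max = k_max, folds = folds,
                          n_estimators = n_estimators,
                          seed = derive_seed(seed, paste0("cv", g)))
    per_k[g] <- ms$selected_k
  }
  agg_rank <- names(sort(rank_sum))  # smallest rank-sum first; ties by name
  selected_k <- max(1L, as.integer(round(median(per_k))))
  feats <- agg_rank[seq_len(selected_k)]

  X_all <- rbind(X_controls, X_disease)
  y_all <- c(rep(0L, n_ctrl), rep(1L, n_dis))
  w <- ifelse(y_all == 0, 0.5 / n_ctrl, 0.5 / n_dis)
  final <- boost_fit(X_all[, feats, drop = FALSE], y_all,
                     n_estimators = n_estimators, init_weights = w,
                     seed = derive_seed(seed, "final"))
  structure(list(ranked_site_ids = agg_rank,
                 selected_k = selected_k,
                 selected_sites = feats,
                 cv_accuracy_by_k = NULL,
                 per_pairing_k = per_k,
                 rank_sum = rank_sum,
                 final_model = final),
            class = "marker_set")
}

#' Evaluate a classifier on held-out data
#'
#' Accuracy is the fraction of correct labels; the ROC curve is traced over
#' the margin thresholds and the AUC computed by the trapezoid rule.
#'
#' @param model a `boosted_ensemble`.
#' @param X_test,y_test held-out features and 0/1 labels.
#' @return A list `accuracy`, `roc` (data.frame `fpr`, `tpr`), `auc`.
#'   A single-class test set yields `auc = NA` with a warning.
#' @export
evaluate_classifier <- function(model, X_test, y_test) {
  y_test <- as.integer(y_test)
  pred <- boost_predict(model, X_test)
  accuracy <- mean(pred$labels == y_test)
  if (length(unique(y_test)) < 2) {
    warning("single-class test set: AUC undefined")
    return(list(accuracy = accuracy, roc = NULL, auc = NA_real_))
  }
  ord <- order(pred$margins, decreasing = TRUE)
  y_ord <- y_test[ord]
  m_ord <- pred$margins[ord]
  # collapse tied margins to one operating point (diagonal tie segments)
  last_of_block <- c(diff(m_ord) != 0, TRUE)
  tpr <- c(0, (cumsum(y_ord == 1) / sum(y_test == 1))[last_of_block])
  fpr <- c(0, (cumsum(y_ord == 0) / sum(y_test == 0))[last_of_block])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(accuracy = accuracy, roc = data.frame(fpr = fpr, tpr = tpr),
       auc = auc)
}
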