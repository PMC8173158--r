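#' Remove CpG sites by missing-value fraction
#'
#' Sites whose fraction of missing entries is at or above `max_frac` are
#' deleted (the threshold itself is excluded); column order is preserved.
#'
#' @param data a `methyl_dataset`.
#' @param max_frac deletion threshold on the per-site missing fraction.
#' @return A `methyl_dataset` with the surviving sites.
#' @export
filter_sites_by_missingness <- function(data, max_frac = 0.3) {
  stopifnot(max_frac >= 0, max_frac <= 1)
  frac <- colMeans(is.na(data$values))
  keep <- frac < max_frac
  if (!any(keep)) stop("all sites removed by the missingness filter")
  subset_dataset(data, sites = keep)
}

#' K-nearest-neighbour imputation of missing methylation values
#'
#' Each missing entry is replaced by the unweighted mean of that site's
#' values over the `k` nearest samples, with Euclidean distance computed on
#' mutually observed sites and scaled by the number of shared sites. Only
#' samples observed at the target site are candidate neighbours. When
#' `stratify_by` names a metadata column, neighbours are sought within the
#' same stratum, falling back (with a warning) to all samples when a stratum
#' offers fewer than `k` candidates. Observed entries are never altered.
#'
#' @param data a `methyl_dataset`.
#' @param k neighbour count (default 10).
#' @param stratify_by optional metadata column name (e.g. brain region).
#' @return A fully observed `methyl_dataset`.
#' @export
knn_impute <- function(data, k = 10, stratify_by = NULL) {
  stopifnot(k >= 1)
  v <- data$values
  if (!anyNA(v)) return(data)
  obs <- !is.na(v)
  if (any(rowSums(obs) == 0))
    stop("a sample has no observed sites; cannot impute")
  v0 <- v
  v0[!obs] <- 0
  # mean squared difference over mutually observed sites
  cross <- tcrossprod(v0)
  sq <- (v0^2) %*% t(obs)
  shared <- tcrossprod(obs * 1)
  d2 <- (sq + t(sq) - 2 * cross) / shared
  d2[shared == 0] <- Inf
  diag(d2) <- Inf

  strata <- if (is.null(stratify_by)) rep(1L, nrow(v)) else
    data$meta[[stratify_by]]
  fell_back <- FALSE
  out <- v
  for (i in which(rowSums(!obs) > 0)) {
    same <- which(strata == strata[i] & seq_len(nrow(v)) != i)
    ord_all <- order(d2[i, ])
    ord_same <- ord_all[ord_all %in% same]
    for (s in which(!obs[i, ])) {
      cand <- ord_same[obs[ord_same, s]]
      if (length(cand) < k) {
        alt <- ord_all[obs[ord_all, s]]
        if (length(cand) < min(k, length(alt))) {
          fell_back <- fell_back || !is.null(stratify_by)
          cand <- alt
        }
      }
      if (length(cand) == 0)
        stop("site ", colnames(v)[s], " has no observed neighbour")
      out[i, s] <- mean(v[head(cand, k), s])
    }
  }
  if (fell_back)
    warning("some strata had fewer than k candidate neighbours; ",
            "fell back to all samples")
  methyl_dataset(out, data$meta)
}

#' Drop samples without age and early-onset disease samples
#'
#' Samples lacking an age are removed; disease-labelled samples with age
#' at or below 50 (early onset) are removed; young healthy samples are kept
#' regardless of age.
#'
#' @param data a `methyl_dataset`.
#' @return A `methyl_dataset`.
#' @export
filter_samples <- function(data) {
  keep <- !is.na(data$meta$age) &
    !(data$meta$group %in% DISEASE_GROUPS & data$meta$age <= 50)
  if (!any(keep)) stop("all samples removed by the sample filter")
  subset_dataset(data, samples = keep)
}

#' Z-score all samples against a reference group
#'
#' Every sample's site values are transformed to `(x - mu_ref) / sd_ref`
#' with the mean and SD computed on the reference group (healthy aged
#' controls by default) only. Sites with zero reference variance are dropped
#' with a warning.
#'
#' @param data a `methyl_dataset`.
#' @param reference_group group label(s) defining the reference samples.
#' @return A `methyl_dataset` on the reference z-score scale.
#' @export
reference_zscore <- function(data, reference_group = "control") {
  ref <- data$meta$group %in% reference_group
  if (!any(ref)) stop("reference group is empty")
  mu <- colMeans(data$values[ref, , drop = FALSE])
  sdev <- apply(data$values[ref, , drop = FALSE], 2, sd)
  bad <- !is.finite(sdev) | sdev == 0
  if (any(bad)) {
    warning(sum(bad), " site(s) with zero reference variance dropped")
    data <- subset_dataset(data, sites = !bad)
    mu <- mu[!bad]
    sdev <- sdev[!bad]
  }
  v <- sweep(sweep(data$values, 2, mu), 2, sdev, "/")
  methyl_dataset(v, data$meta)
}

#' Remove reference-estimated singular directions from all samples
#'
#' The top right-singular directions are estimated on the centred reference
#' (healthy aged) submatrix; every sample's projection onto those directions
#' is subtracted, eliminating the dominant inter-sample variation they carry.
#'
#' @param data a `methyl_dataset`.
#' @param reference_group group label(s) defining the reference samples.
#' @param n_components number of singular directions to remove (default 3);
#'   reduced to the reference rank with a warning if it exceeds it.
#' @return A `methyl_dataset`.
#' @export
svd_batch_correct <- function(data, reference_group = "control",
                              n_components = 3) {
  stopifnot(n_components >= 1)
  ref <- data$meta$group %in% reference_group
  if (!any(ref)) stop("reference group is empty")
  mu <- colMeans(data$values[ref, , drop = FALSE])
  centred_ref <- sweep(data$values[ref, , drop = FALSE], 2, mu)
  sv <- svd(centred_ref)
  rank <- sum(sv$d > max(dim(centred_ref)) * .Machine$double.eps * sv$d[1])
  if (n_components > rank) {
    warning("n_components reduced to reference rank ", rank)
    n_components <- rank
  }
  V <- sv$v[, seq_len(n_components), drop = FALSE]
  centred <- sweep(data$values, 2, mu)
  corrected <- centred - (centred %*% V) %*% t(V)
  corrected <- sweep(corrected, 2, mu, "+")
  methyl_dataset(corrected, data$meta)
}

#' Stratified train/test split
#'
#' Assigns each sample to the training or test partition, stratified by
#' group label, deterministically under `seed`. Groups with fewer than two
#' samples go entirely to training with a warning.
#'
#' @param data a `methyl_dataset`.
#' @param ratio a string `"a:b"` (train:test, default `"2:1"`) or the
#'   training fraction as a number.
#' @param seed integer seed.
#' @return A `methyl_dataset` with the `split` field filled.
#' @export
split_train_test <- function(data, ratio = "2:1", seed = 1L) {
  frac <- if (is.character(ratio)) {
    ab <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
    if (length(ab) != 2 || any(!is.finite(ab)) || any(ab <= 0))
      stop("ratio must be 'a:b' with positive a, b")
    ab[1] / sum(ab)
  } else {
    stopifnot(ratio > 0, ratio < 1)
    ratio
  }
  set.seed(seed)
  split <- rep("train", nrow(data$meta))
  for (g in sort(unique(data$meta$group))) {
    rows <- which(data$meta$group == g)
    if (length(rows) < 2) {
      warning("group ", g, " has < 2 samples; all assigned to train")
      next
    }
    n_train <- round(length(rows) * frac)
    n_train <- min(max(n_train, 1), length(rows) - 1)
    split[sample(rows, length(rows) - n_train)] <- "test"
  }
  data$meta$split <- split
  data
}

#' Run the full preprocessing chain
#'
#' Applies, in order: site missingness filtering, KNN imputation, sample
#' filtering, reference z-scoring, SVD correction on the reference group,
#' a second reference z-scoring pass, and the stratified train/test split.
#'
#' @param data a raw `methyl_dataset`.
#' @param max_missing site deletion threshold (default 0.3).
#' @param knn_k imputation neighbour count (default 10).
#' @param stratify_by optional imputation stratum column.
#' @param reference_group reference label(s) (default `"control"`).
#' @param n_components singular directions to remove (default 3).
#' @param split_ratio train:test ratio (default `"2:1"`).
#' @param seed integer seed for the split.
#' @return A preprocessed `methyl_dataset` with no missing values.
#' @export
preprocess_pipeline <- function(data, max_missing = 0.3, knn_k = 10,
                                stratify_by = NULL,
                                reference_group = "control",
                                n_components = 3, split_ratio = "2:1",
                                seed = 1L) {
  data <- filter_sites_by_missingness(data, max_missing)
  data <- knn_impute(data, knn_k, stratify_by)
  data <- filter_samples(data)
  data <- reference_zscore(data, reference_group)
  data <- svd_batch_correct(data, reference_group, n_components)
  data <- reference_zscore(data, reference_group)
  split_train_test(data, split_ratio, seed)
}
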