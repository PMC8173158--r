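#' Fit the bagged regression-tree aging/risk scorer
#'
#' One hundred regression trees are fitted to bootstrap resamples of the 0/1
#' group code (young = 0, aged = 1 for the aging score; control = 0,
#' disease = 1 for disease risk scores); the score of a sample is the mean
#' of the tree outputs, a real value that is not clipped to `[0, 1]`.
#'
#' @param X_markers numeric matrix restricted to marker columns.
#' @param y numeric 0/1 group code.
#' @param n_trees ensemble size (default 100).
#' @param seed integer seed for the bootstrap.
#' @return An object of class `bagged_regressor`.
#' @export
fit_score_regressor <- function(X_markers, y, n_trees = 100, seed = 1L) {
  X_markers <- as.matrix(X_markers)
  n <- nrow(X_markers)
  df <- data.frame(X_markers, check.names = FALSE)
  set.seed(seed)
  inbag <- matrix(FALSE, n, n_trees)
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample(n, replace = TRUE)
    inbag[unique(idx), b] <<- TRUE
    dfb <- df[idx, , drop = FALSE]
    dfb$.y <- y[idx]
    # depth-2 trees, matching the classifier's weak learner: many shallow
    # thresholds averaged over the bootstrap give a smooth monotone score
    rpart::rpart(.y ~ ., data = dfb, method = "anova",
                 control = rpart::rpart.control(maxdepth = 2, minsplit = 5,
                                                cp = 0.001,
                                                maxsurrogate = 0,
                                                maxcompete = 0))
  })
  rownames(inbag) <- rownames(X_markers)
  structure(list(trees = trees, features = colnames(X_markers),
                 inbag = inbag),
            class = "bagged_regressor")
}

#' Predict scores from a bagged regression ensemble
#'
#' For rows that were part of the training data (matched by row name),
#' `oob = TRUE` averages only the trees whose bootstrap resample excluded
#' that row, removing the in-bag optimism that would otherwise inflate
#' training-sample scores relative to held-out samples.
#'
#' @param model a `bagged_regressor`.
#' @param X numeric matrix containing the model's feature columns.
#' @param oob use out-of-bag averaging for rows whose names match the
#'   training rows (rows never out of bag fall back to the full ensemble).
#' @return Numeric score vector (mean of tree outputs).
#' @export
predict_score <- function(model, X, oob = FALSE) {
  X <- as.matrix(X)
  if (!all(model$features %in% colnames(X)))
    stop("X lacks model features")
  df <- data.frame(X[, model$features, drop = FALSE], check.names = FALSE)
  preds <- vapply(model$trees, function(tr) unname(predict(tr, df)),
                  numeric(nrow(df)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(df))
  out <- rowMeans(preds)
  if (oob && !is.null(rownames(X)) && !is.null(rownames(model$inbag))) {
    hit <- match(rownames(X), rownames(model$inbag))
    for (i in which(!is.na(hit))) {
      keep <- !model$inbag[hit[i], ]
      if (any(keep)) out[i] <- mean(preds[i, keep])
    }
  }
  out
}

#' Sigmoid transform of chronological age
#'
#' Maps age in years onto `(0, 1)` by the logistic
#' `1 / (1 + exp(-(age - 50) / 50))`, centred at 50 years (the young/aged
#' boundary), strictly increasing.
#'
#' @param age numeric age(s) in years.
#' @return Values in `(0, 1)`.
#' @export
transform_age <- function(age) {
  stopifnot(all(is.finite(age)))
  1 / (1 + exp(-(age - 50) / 50))
}

#' Age-adjust the aging score
#'
#' The transformed age is regressed on the aging score by ordinary least
#' squares (with intercept); only the slope `b` enters the adjustment
#' `adjusted = b * score - transformed_age`.
#'
#' @param scores numeric aging scores (variance must be positive).
#' @param ages numeric ages in years.
#' @return A list `adjusted`, `b`, `transformed_age`.
#' @export
adjust_score <- function(scores, ages) {
  stopifnot(length(scores) == length(ages), length(scores) >= 3)
  if (var(scores) == 0) stop("aging scores have zero variance")
  ta <- transform_age(ages)
  b <- unname(coef(lm(ta ~ scores))[2])
  list(adjusted = b * scores - ta, b = b, transformed_age = ta)
}

#' One-sample Kolmogorov-Smirnov test against a fitted normal
#'
#' Tests whether the scores are compatible with a Normal distribution with
#' the sample mean and SD; the statistic is the sup-distance between the
#' empirical and fitted CDFs, the p-value from the asymptotic K-S
#' distribution.
#'
#' @param scores numeric vector, at least 8 values.
#' @return A list `statistic`, `p`.
#' @export
ks_normality_test <- function(scores) {
  stopifnot(length(scores) >= 8)
  s <- sd(scores)
  if (s == 0) return(list(statistic = 1, p = 0))
  kt <- suppressWarnings(ks.test(scores, "pnorm", mean(scores), s))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Kruskal-Wallis comparison of disease vs control scores by age stratum
#'
#' For each minimum-age threshold, samples with `age >= t` are retained and
#' the scores of disease-labelled vs control samples compared by the
#' Kruskal-Wallis rank test (midranks with the standard tie correction).
#' Strata lacking one of the arms are skipped with a message.
#'
#' @param scores numeric per-sample scores.
#' @param group per-sample group labels.
#' @param age per-sample ages.
#' @param thresholds minimum ages (default 50 to 80 by 5).
#' @param disease_groups labels counted as disease.
#' @return A data.frame `threshold`, `n_nd`, `n_control`, `H`, `p` (skipped
#'   strata omitted).
#' @export
kruskal_wallis_by_age_group <- function(scores, group, age,
                                        thresholds = seq(50, 80, by = 5),
                                        disease_groups = DISEASE_GROUPS) {
  out <- lapply(thresholds, function(t) {
    keep <- age >= t & (group %in% disease_groups | group == "control")
    g <- ifelse(group[keep] %in% disease_groups, "ND", "control")
    if (length(unique(g)) < 2) {
      message("age >= ", t, ": one arm empty, stratum skipped")
      return(NULL)
    }
    kt <- kruskal.test(scores[keep], factor(g))
    data.frame(threshold = t, n_nd = sum(g == "ND"),
               n_control = sum(g == "control"),
               H = unname(kt$statistic), p = kt$p.value)
  })
  do.call(rbind, out)
}

#' Assemble the per-sample score table
#'
#' @param data a preprocessed `methyl_dataset`.
#' @param aging_scorer a `bagged_regressor` over aging-marker columns.
#' @param disease_scorers optional named list of per-disease
#'   `bagged_regressor`s.
#' @return A data.frame with `sample_id`, `age`, `group`, `split`,
#'   `aging_score`, `transformed_age`, `adjusted_score` and one
#'   `score_<disease>` column per disease scorer; the regression slope `b`
#'   is attached as attribute `"b"`.
#' @export
score_table <- function(data, aging_scorer, disease_scorers = list()) {
  sc <- predict_score(aging_scorer, data$values, oob = TRUE)
  adj <- adjust_score(sc, data$meta$age)
  out <- data.frame(sample_id = data$meta$sample_id, age = data$meta$age,
                    group = data$meta$group, split = data$meta$split,
                    aging_score = sc, transformed_age = adj$transformed_age,
                    adjusted_score = adj$adjusted,
                    stringsAsFactors = FALSE)
  for (d in names(disease_scorers)) {
    out[[paste0("score_", d)]] <- predict_score(disease_scorers[[d]],
                                                data$values, oob = TRUE)
  }
  attr(out, "b") <- adj$b
  out
}
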