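sep_fixture <- function(n = 40, p = 10, gap = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- rep(0:1, each = n / 2)
  X[y == 1, 1] <- X[y == 1, 1] + gap
  list(X = X, y = y)
}

test_that("ReliefF scores equal a naive loop recomputation", {
  set.seed(2)
  X <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(0:1, 6)
  X[y == 1, 2] <- X[y == 1, 2] + 1
  got <- relieff_rank(X, y, n_neighbors = 2, seed = 1)
  want <- oracle_relieff(X, y, k = 2)
  expect_equal(got$score[match(c("a", "b", "c"), got$site_id)], want,
               tolerance = 1e-12)
})

test_that("a perfectly separating site ranks first; duplicates tie", {
  fx <- sep_fixture(gap = 4, seed = 3)
  rk <- relieff_rank(fx$X, fx$y, n_neighbors = 5, seed = 1)
  expect_identical(rk$site_id[1], "f01")
  # duplicated feature columns receive identical scores
  X2 <- cbind(fx$X, f11 = fx$X[, 1])
  rk2 <- relieff_rank(X2, fx$y, n_neighbors = 5, seed = 1)
  expect_equal(rk2$score[rk2$site_id == "f01"],
               rk2$score[rk2$site_id == "f11"], tolerance = 1e-12)
})

test_that("under label permutation the planted site loses its rank", {
  fx <- sep_fixture(n = 40, p = 40, gap = 2, seed = 4)
  ranks <- vapply(1:20, function(s) {
    set.seed(s)
    y_null <- sample(fx$y)
    rk <- relieff_rank(fx$X, y_null, n_neighbors = 5, seed = s)
    which(rk$site_id == "f01")
  }, numeric(1))
  expect_gt(median(ranks), 40 / 4)
})

test_that("ReliefF rejects degenerate input", {
  fx <- sep_fixture()
  expect_error(relieff_rank(fx$X, rep(1, nrow(fx$X))), "both classes")
  fx$X[1, 1] <- NA
  expect_error(relieff_rank(fx$X, fx$y), "missing")
})

test_that("boosting matches the textbook oracle round by round", {
  for (s in 1:3) {
    set.seed(s)
    n <- 30 + 10 * s
    X <- matrix(rnorm(n * 5), n, 5)
    y <- as.integer(X[, 1] + 0.7 * X[, 2] + rnorm(n, sd = 0.8) > 0)
    if (length(unique(y)) < 2) next
    fit <- boost_fit(X, y, n_estimators = 15, seed = s)
    orc <- oracle_adaboost(X, y, n_rounds = 15)
    expect_equal(fit$alphas, orc$alphas, tolerance = 1e-12)
    om <- oracle_margins_by_round(orc, X)
    fm <- oracle_margins_by_round(fit, X)
    expect_equal(fm, om, tolerance = 1e-12)
  }
})

test_that("boosting drives training error to zero on a separable fixture", {
  fx <- sep_fixture(gap = 5, seed = 5)
  fit <- boost_fit(fx$X, fx$y, n_estimators = 10, seed = 1)
  pred <- boost_predict(fit, fx$X)
  expect_identical(pred$labels, fx$y)
  expect_true(all(pred$margins[fx$y == 1] > 0))
  expect_true(all(pred$margins[fx$y == 0] < 0))
})

test_that("round bookkeeping stays in bounds and alphas are positive below even odds", {
  set.seed(6)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.integer(X[, 1] + rnorm(50) > 0)
  fit <- boost_fit(X, y, n_estimators = 25, seed = 2)
  expect_true(all(fit$errors >= 0 & fit$errors <= 1))
  expect_true(all((fit$alphas > 0) == (fit$errors < 0.5)))
  expect_equal(length(fit$alphas), length(fit$trees))
})

test_that("a single-learner ensemble predicts like its tree; flipping alphas flips labels", {
  fx <- sep_fixture(seed = 7)
  fit <- boost_fit(fx$X, fx$y, n_estimators = 1, seed = 1)
  tree_pred <- epiaccel:::cpp_tree_predict(fit$trees[[1]], fx$X)
  expect_identical(boost_predict(fit, fx$X)$labels, tree_pred)
  flipped <- fit
  flipped$alphas <- -fit$alphas
  p1 <- boost_predict(fit, fx$X)
  p2 <- boost_predict(flipped, fx$X)
  expect_equal(p2$margins, -p1$margins)
  expect_identical(p2$labels[p1$margins != 0], 1L - p1$labels[p1$margins != 0])
})

test_that("feature-name mismatch is a schema error", {
  fx <- sep_fixture(seed = 8)
  fit <- boost_fit(fx$X, fx$y, n_estimators = 3, seed = 1)
  bad <- fx$X
  colnames(bad) <- paste0("x", seq_len(ncol(bad)))
  expect_error(boost_predict(fit, bad), "lacks model features")
})

test_that("the CV sweep finds a small dimension when only the top sites carry signal", {
  set.seed(9)
  n <- 60
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  y <- rep(0:1, each = n / 2)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + 2
  ms <- select_top_k_cv(X, y, colnames(X), k_max = 15, folds = 5,
                        n_estimators = 20, seed = 1)
  expect_lte(ms$selected_k, 10)
  expect_gte(ms$cv_accuracy_by_k[ms$selected_k], ms$cv_accuracy_by_k[1])
  expect_identical(ms$selected_sites,
                   ms$ranked_site_ids[seq_len(ms$selected_k)])
})

test_that("on null data mean CV accuracy sits at chance", {
  set.seed(10)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  y <- rep(0:1, each = n / 2)
  ms <- select_top_k_cv(X, y, colnames(X), k_max = 8, folds = 5,
                        n_estimators = 10, seed = 3)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(ms$cv_accuracy_by_k) - 0.5), 2.5 * se)
})

test_that("control subgrouping reduces to the plain sweep for one subgroup", {
  set.seed(11)
  Xc <- matrix(rnorm(40 * 12), 40, 12,
               dimnames = list(sprintf("c%02d", 1:40), sprintf("f%02d", 1:12)))
  Xd <- matrix(rnorm(20 * 12), 20, 12,
               dimnames = list(sprintf("d%02d", 1:20), sprintf("f%02d", 1:12)))
  Xd[, 2] <- Xd[, 2] + 2
  ms <- balanced_disease_fit(Xc, Xd, n_subgroups = 1, k_max = 8, folds = 4,
                             n_estimators = 10, seed = 5)
  expect_length(ms$per_pairing_k, 1)
  expect_identical(ms$selected_k, as.integer(ms$per_pairing_k[1]))
  expect_identical(ms$selected_sites,
                   ms$ranked_site_ids[seq_len(ms$selected_k)])
  expect_identical(ms$ranked_site_ids[1], "f02")
})

test_that("the balanced refit equalizes class mass", {
  # the contract: weights 0.5/n_ctrl and 0.5/n_dis give each class total 1/2
  n_ctrl <- 37; n_dis <- 11
  w <- c(rep(0.5 / n_ctrl, n_ctrl), rep(0.5 / n_dis, n_dis))
  y <- c(rep(0, n_ctrl), rep(1, n_dis))
  expect_equal(sum(w[y == 0]), sum(w[y == 1]))
})

test_that("evaluation reports exact accuracy and a Mann-Whitney-consistent AUC", {
  fx <- sep_fixture(gap = 5, seed = 12)
  fit <- boost_fit(fx$X, fx$y, n_estimators = 10, seed = 1)
  ev <- evaluate_classifier(fit, fx$X, fx$y)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  # noisy fixture: trapezoid AUC equals the rank-statistic oracle
  set.seed(13)
  Xn <- matrix(rnorm(60 * 4), 60, 4)
  yn <- rep(0:1, 30)
  fitn <- boost_fit(Xn, yn, n_estimators = 5, seed = 2)
  set.seed(14)
  Xt <- matrix(rnorm(40 * 4), 40, 4)
  yt <- rep(0:1, 20)
  evn <- evaluate_classifier(fitn, Xt, yt)
  mg <- boost_predict(fitn, Xt)$margins
  expect_equal(evn$auc, oracle_auc(mg, yt), tolerance = 1e-12)
})

test_that("AUC is calibrated at one half on label-permuted data", {
  set.seed(15)
  aucs <- replicate(12, {
    X <- matrix(rnorm(80 * 5), 80, 5)
    y <- sample(rep(0:1, 40))
    tr <- seq_len(40)
    fit <- boost_fit(X[tr, ], y[tr], n_estimators = 10,
                     seed = sample.int(1e6, 1))
    evaluate_classifier(fit, X[-tr, ], y[-tr])$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), max(3 * se, 0.08))
})

test_that("a single-class test set voids the AUC with a warning", {
  fx <- sep_fixture(seed = 16)
  fit <- boost_fit(fx$X, fx$y, n_estimators = 3, seed = 1)
  expect_warning(ev <- evaluate_classifier(fit, fx$X[fx$y == 1, ],
                                           fx$y[fx$y == 1]),
                 "single-class")
  expect_true(is.na(ev$auc))
})
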