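test_that("the age transform is the printed logistic with its limits", {
  expect_equal(transform_age(50), 0.5)
  expect_equal(transform_age(100), 1 / (1 + exp(-1)))
  expect_equal(transform_age(1e6), 1)
  expect_equal(transform_age(-1e6), 0)
  grid <- transform_age(seq(-20, 130, by = 0.5))
  expect_true(all(diff(grid) > 0))
  expect_true(all(grid > 0 & grid < 1))
  expect_error(transform_age(Inf), "finite")
})

test_that("score adjustment uses the OLS slope only, exactly as stored", {
  scores <- c(0.1, 0.4, 0.5, 0.9)
  ages <- c(30, 55, 60, 85)
  out <- adjust_score(scores, ages)
  ta <- transform_age(ages)
  b_hand <- sum((scores - mean(scores)) * (ta - mean(ta))) /
    sum((scores - mean(scores))^2)
  expect_equal(out$b, b_hand, tolerance = 1e-12)
  expect_equal(out$adjusted, out$b * scores - ta, tolerance = 1e-12)
  # location invariance of the slope
  out2 <- adjust_score(scores + 10, ages)
  expect_equal(out2$b, out$b, tolerance = 1e-12)
  expect_error(adjust_score(rep(0.5, 4), ages), "zero variance")
})

test_that("self-regression of the transform on itself gives slope one", {
  ages <- c(40, 50, 60, 70, 80)
  scores <- transform_age(ages)
  out <- adjust_score(scores, ages)
  expect_equal(out$b, 1, tolerance = 1e-12)
  resid_slope <- coef(lm(out$adjusted ~ ages))[2]
  expect_equal(unname(resid_slope), 0, tolerance = 1e-12)
})

test_that("a constant regression target yields constant scores", {
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- fit_score_regressor(X, rep(1, 20), n_trees = 10, seed = 1)
  expect_equal(predict_score(m, X), rep(1, 20))
})

test_that("scores separate young from old on planted aging data", {
  g <- generate_dataset(n_young = 60, n_old = 60,
                        n_per_disease = c(AD = 10), n_cpg = 60,
                        n_aging_markers = 10, n_disease_markers = 4,
                        missing_frac = 0, batch_sd = 0, seed = 22)
  d <- reference_zscore(g$dataset)
  healthy <- d$meta$group %in% c("young", "control")
  X <- d$values[healthy, g$truth$aging_marker_ids]
  y <- as.integer(d$meta$group[healthy] == "control")
  m <- fit_score_regressor(X, y, n_trees = 50, seed = 2)
  s <- predict_score(m, d$values)
  expect_gt(mean(s[d$meta$group == "control"]),
            mean(s[d$meta$group == "young"]) + 0.3)
})

test_that("out-of-bag scoring removes in-bag optimism for training rows", {
  set.seed(23)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("s%03d", 1:n), paste0("f", 1:5)))
  y <- as.integer(X[, 1] + rnorm(n, sd = 2) > 0)  # noisy target
  m <- fit_score_regressor(X, y, n_trees = 60, seed = 3)
  inb <- predict_score(m, X)
  oob <- predict_score(m, X, oob = TRUE)
  # in-bag residuals are optimistically small relative to out-of-bag
  expect_lt(mean((y - inb)^2), mean((y - oob)^2))
  # out-of-bag averaging changes nothing for unseen rows
  Xnew <- matrix(rnorm(20 * 5), 20, 5,
                 dimnames = list(sprintf("t%03d", 1:20), paste0("f", 1:5)))
  expect_equal(predict_score(m, Xnew, oob = TRUE), predict_score(m, Xnew))
})

test_that("the K-S normality test is calibrated on Gaussian samples and rejects a two-point law", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    ks_normality_test(rnorm(300))$p > 0.05
  }, logical(1))
  expect_gte(sum(hits), 18)
  set.seed(99)
  bimodal <- c(rep(0, 100), rep(1, 100)) + rnorm(200, sd = 1e-3)
  expect_lt(ks_normality_test(bimodal)$p, 1e-6)
  expect_true(ks_normality_test(rnorm(50))$statistic >= 0)
  expect_true(ks_normality_test(rnorm(50))$statistic <= 1)
  expect_identical(ks_normality_test(rep(1, 10))$p, 0)
})

test_that("two-group Kruskal-Wallis matches the squared Mann-Whitney z on tie-free data", {
  set.seed(24)
  score <- c(rnorm(15), rnorm(12, 0.8))
  grp <- c(rep("control", 15), rep("AD", 12))
  age <- rep(70, 27)
  kw <- kruskal_wallis_by_age_group(score, grp, age, thresholds = 50)
  n1 <- 15; n2 <- 12; N <- 27
  W <- sum(rank(score)[grp == "AD"]) - n2 * (n2 + 1) / 2
  z <- (W - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kw$H, z^2, tolerance = 1e-10)
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(25)
  p <- replicate(200, {
    score <- rnorm(60)
    grp <- rep(c("control", "AD"), 30)
    kruskal_wallis_by_age_group(score, grp, rep(70, 60),
                                thresholds = 50)$p
  })
  reject <- mean(p < 0.05)
  expect_lt(abs(reject - 0.05), 0.05)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("empty strata are skipped with a message", {
  score <- rnorm(10)
  grp <- c(rep("control", 5), rep("AD", 5))
  age <- c(rep(60, 5), rep(55, 5))  # no AD above 60
  expect_message(
    kw <- kruskal_wallis_by_age_group(score, grp, age,
                                      thresholds = c(50, 65)),
    "skipped")
  expect_identical(kw$threshold, 50)
})

test_that("the score table carries the adjustment and per-disease scores", {
  g <- generate_dataset(n_young = 30, n_old = 30,
                        n_per_disease = c(AD = 15), n_cpg = 40,
                        n_aging_markers = 6, n_disease_markers = 4,
                        missing_frac = 0, batch_sd = 0, seed = 26)
  d <- reference_zscore(g$dataset)
  healthy <- d$meta$group %in% c("young", "control")
  aging <- fit_score_regressor(d$values[healthy, g$truth$aging_marker_ids],
                               as.integer(d$meta$group[healthy] == "control"),
                               n_trees = 20, seed = 1)
  rows <- d$meta$group %in% c("control", "AD")
  ad <- fit_score_regressor(d$values[rows, g$truth$disease_marker_ids$AD],
                            as.integer(d$meta$group[rows] == "AD"),
                            n_trees = 20, seed = 2)
  tab <- score_table(d, aging, list(AD = ad))
  expect_identical(nrow(tab), nrow(d$meta))
  expect_true(all(c("aging_score", "transformed_age", "adjusted_score",
                    "score_AD") %in% names(tab)))
  b <- attr(tab, "b")
  expect_equal(tab$adjusted_score,
               b * tab$aging_score - tab$transformed_age, tolerance = 1e-12)
})

test_that("median aging score rises with the age threshold on planted data", {
  g <- generate_dataset(n_young = 80, n_old = 120,
                        n_per_disease = c(AD = 20), n_cpg = 60,
                        n_aging_markers = 12, n_disease_markers = 4,
                        missing_frac = 0, batch_sd = 0, seed = 27)
  d <- reference_zscore(g$dataset)
  healthy <- d$meta$group %in% c("young", "control")
  m <- fit_score_regressor(d$values[healthy, g$truth$aging_marker_ids],
                           as.integer(d$meta$group[healthy] == "control"),
                           n_trees = 50, seed = 3)
  s <- predict_score(m, d$values, oob = TRUE)
  thr <- seq(50, 75, by = 5)
  med <- vapply(thr, function(t) {
    median(s[d$meta$age >= t & d$meta$group != "young"])
  }, numeric(1))
  expect_gt(cor(thr, med, method = "spearman"), 0)
})
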