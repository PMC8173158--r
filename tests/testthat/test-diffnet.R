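test_that("pairwise Pearson matches the closed-form sums on a printed fixture", {
  x <- c(1, 2, 4, 5, 7)
  y <- c(2, 1, 5, 4, 8)
  X <- cbind(a = x, b = y, c = -x)
  out <- pairwise_pearson(X)
  n <- 5
  r_hand <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(out$r["a", "b"], r_hand, tolerance = 1e-12)
  expect_equal(out$r["a", "a"], 1)
  expect_equal(out$r["a", "c"], -1)
  expect_equal(out$p["a", "c"], 0)
  tstat <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  expect_equal(out$p["a", "b"], 2 * pt(-abs(tstat), n - 2),
               tolerance = 1e-12)
})

test_that("zero-variance columns yield excluded NA pairs", {
  X <- cbind(a = rnorm(10), b = rep(1, 10))
  out <- pairwise_pearson(X)
  expect_true(is.na(out$r["a", "b"]))
})

test_that("partial correlation equals the residualization oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- 30
    z <- rnorm(n)
    X <- cbind(a = 0.5 * z + rnorm(n), b = -0.3 * z + rnorm(n),
               c = rnorm(n))
    out <- partial_correlation(X, z)
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      ra <- resid(lm(X[, pair[1]] ~ z))
      rb <- resid(lm(X[, pair[2]] ~ z))
      expect_equal(out$pr[pair[1], pair[2]], cor(ra, rb),
                   tolerance = 1e-10)
    }
  }
})

test_that("conditioning removes a shared driver and ignores an irrelevant one", {
  set.seed(32)
  n <- 400
  z <- rnorm(n)
  x <- z + rnorm(n, sd = 0.6)
  y <- z + rnorm(n, sd = 0.6)
  out <- partial_correlation(cbind(x = x, y = y), z)
  expect_gt(cor(x, y), 0.5)
  expect_lt(abs(out$pr["x", "y"]), 0.15)
  w <- rnorm(n)  # independent of x, y
  out2 <- partial_correlation(cbind(x = x, y = y), w)
  expect_lt(abs(out2$pr["x", "y"] - cor(x, y)), 0.05)
})

test_that("BH adjustment equals the hand step-up and preserves order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p_eq <- rep(0.2, 5)
  expect_equal(bh_fdr(p_eq), p_eq)
  set.seed(33)
  for (i in 1:5) {
    p <- runif(50)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)))
})

signflip_fixture <- function(n_per_group = 150, n_pairs = 15, n_noise = 60,
                             rho = 0.8, seed = 1) {
  g <- generate_dataset(n_young = 2, n_old = n_per_group,
                        n_per_disease = c(AD = n_per_group),
                        n_cpg = 2 * n_pairs + n_noise + 10,
                        n_aging_markers = 5, n_disease_markers = 5,
                        batch_sd = 0, missing_frac = 0, aging_effect = 0,
                        disease_effect = 0, seed = seed)
  plant_signflip_pairs(g$dataset, g$truth, n_pairs = n_pairs, rho = rho,
                       seed = seed + 1)
}

test_that("the differential network recovers planted sign-flip pairs", {
  pl <- signflip_fixture(seed = 41)
  d <- pl$dataset
  ctrl <- d$meta$group == "control"
  nd <- d$meta$group == "AD"
  # conditioning variable: the aging axis the score estimates
  f <- scale(d$meta$age)[, 1]
  z_c <- f[ctrl]
  z_n <- f[nd]
  sites <- setdiff(colnames(d$values),
                   c(pl$truth$aging_marker_ids,
                     unlist(pl$truth$disease_marker_ids)))
  ps <- compute_pair_stats(d$values[ctrl, sites], d$values[nd, sites],
                           z_c, z_n)
  net <- build_differential_network(ps, fdr_threshold = 0.1)
  truth_keys <- paste(pmin(pl$truth$signflip_pairs[, 1],
                           pl$truth$signflip_pairs[, 2]),
                      pmax(pl$truth$signflip_pairs[, 1],
                           pl$truth$signflip_pairs[, 2]), sep = "|")
  # every (unflipped, flipped) planted-site pair is a structural flip
  flip <- pl$truth$signflip_flipped
  unflip <- setdiff(as.vector(pl$truth$signflip_pairs), flip)
  structural <- as.vector(outer(unflip, flip, function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = "|")))
  got_keys <- paste(pmin(net$edges$site_a, net$edges$site_b),
                    pmax(net$edges$site_a, net$edges$site_b), sep = "|")
  sens <- mean(truth_keys %in% got_keys)
  fpr <- sum(!(got_keys %in% structural)) /
    (nrow(ps) - length(structural))
  expect_gte(sens, 0.8)
  expect_lte(fpr, 0.05)
})

test_that("edges with same-sign differences are rejected regardless of FDR", {
  ps <- data.frame(site_a = "a", site_b = "b",
                   r_ctrl = 0.5, pr_ctrl = 0.3, r_nd = 0.6, pr_nd = 0.3,
                   q_r_ctrl = 1e-9, q_pr_ctrl = 1e-9, q_r_nd = 1e-9,
                   q_pr_nd = 1e-9, stringsAsFactors = FALSE)
  ps$delta_ctrl <- ps$r_ctrl - ps$pr_ctrl  # +0.2
  ps$delta_nd <- ps$r_nd - ps$pr_nd        # +0.3
  ps$min_q <- 1e-9
  expect_warning(net <- build_differential_network(ps, 0.1), "empty")
  expect_identical(nrow(net$edges), 0L)
})

test_that("label-shuffled null data give few edges at the FDR gate", {
  set.seed(43)
  n <- 120
  X <- matrix(rnorm(2 * n * 40), 2 * n, 40,
              dimnames = list(NULL, sprintf("cg%02d", 1:40)))
  z <- rnorm(2 * n)
  half <- seq_len(n)
  ps <- compute_pair_stats(X[half, ], X[-half, ], z[half], z[-half])
  net <- suppressWarnings(build_differential_network(ps, 0.1))
  expect_lte(nrow(net$edges), 0.05 * nrow(ps))
})

test_that("the FDR gate and differential rule toggles behave as documented", {
  pl <- signflip_fixture(seed = 44, n_pairs = 8)
  d <- pl$dataset
  ctrl <- d$meta$group == "control"
  nd <- d$meta$group == "AD"
  set.seed(45)
  ps <- compute_pair_stats(d$values[ctrl, 1:40], d$values[nd, 1:40],
                           rnorm(sum(ctrl)), rnorm(sum(nd)))
  strict <- build_differential_network(ps, 0.1, gate = "all")
  loose <- suppressWarnings(build_differential_network(ps, 0.1,
                                                       gate = "min"))
  expect_lte(nrow(strict$edges), nrow(loose$edges))
  alt <- suppressWarnings(build_differential_network(ps, 0.1,
                                                     rule = "between"))
  expect_s3_class(alt, "differential_network")
})

test_that("a preferential-attachment graph passes the power-law check; a star does not", {
  set.seed(46)
  ba <- igraph::sample_pa(1000, m = 2, directed = FALSE)
  deg <- igraph::degree(ba)
  fit <- power_law_check(deg)
  expect_lt(fit$slope, -1)
  expect_lt(fit$r, -0.8)
  er <- igraph::sample_gnm(1000, igraph::ecount(ba))
  fit_er <- power_law_check(igraph::degree(er))
  expect_gt(fit_er$r, fit$r)
  expect_warning(out <- power_law_check(c(1, 1, 1, 1, 4)), "not testable")
  expect_false(out$testable)
})

test_that("network similarity is maximal for identical networks and exact on a printed table", {
  net <- random_network(15, 0.3, seed = 47)
  universe <- as.data.frame(t(utils::combn(net$nodes, 2)))
  names(universe) <- c("site_a", "site_b")
  sim <- network_similarity_fisher(net, net, universe)
  expect_lt(sim$p, 1e-6)
  # 2x2 table (10, 2, 3, 985): one-sided p equals the hypergeometric sum
  tab <- matrix(c(10, 3, 2, 985), 2)
  ft <- fisher.test(tab, alternative = "greater")$p.value
  expect_equal(ft, oracle_hyper_upper(10, 12, 13, 1000), tolerance = 1e-10)
  empty <- net
  empty$edges <- net$edges[0, ]
  expect_warning(s2 <- network_similarity_fisher(net, empty, universe),
                 "degenerate")
  expect_identical(s2$p, 1)
})
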