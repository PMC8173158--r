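# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package code.

# Textbook discrete AdaBoost in its exponential-reweighting form, sharing
# only the weak-learner inducer with the implementation under test. Stops on
# a zero-error round (dominant learner); fixtures are chosen so the
# degenerate eps >= 1/2 branch never triggers.
oracle_adaboost <- function(X, y, n_rounds, max_depth = 2, min_leaf = 1) {
  m <- nrow(X)
  ypm <- 2 * as.integer(y) - 1
  w <- rep(1 / m, m)
  trees <- list()
  alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    tree <- epiaccel:::cpp_tree_fit(X, as.integer(y), w, max_depth, min_leaf)
    hpm <- 2 * epiaccel:::cpp_tree_predict(tree, X) - 1
    eps <- sum(w[hpm != ypm])
    if (eps >= 0.5) stop("oracle fixture produced a degenerate round")
    if (eps == 0) {
      trees <- c(trees, list(tree))
      alphas <- c(alphas, 10)
      break
    }
    a <- 0.5 * log((1 - eps) / eps)
    trees <- c(trees, list(tree))
    alphas <- c(alphas, a)
    w <- w * exp(-a * ypm * hpm)
    w <- w / sum(w)
  }
  list(trees = trees, alphas = alphas)
}

oracle_margins_by_round <- function(fit, X) {
  per_tree <- vapply(fit$trees, function(tr) {
    2 * epiaccel:::cpp_tree_predict(tr, X) - 1
  }, numeric(nrow(X)))
  per_tree <- matrix(per_tree, nrow = nrow(X))
  sweep(per_tree, 2, fit$alphas, "*")
}

# Mann-Whitney AUC with half-credit for ties.
oracle_auc <- function(margins, y) {
  pos <- margins[y == 1]
  neg <- margins[y == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# BH step-up computed literally from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Hypergeometric upper tail as a direct sum of exact binomial products
# (linear space; the implementation works with the complementary sum in log
# space).
oracle_hyper_upper <- function(k, M, n, N) {
  j <- k:min(M, n)
  sum(choose(M, j) * choose(N - M, n - j)) / choose(N, n)
}

# Brute-force enumeration over all size-n draws from the universe.
oracle_hyper_enum <- function(k, M, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= k)
}

# Naive ReliefF recomputation with explicit loops.
oracle_relieff <- function(X, y, k) {
  n <- nrow(X)
  p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf
    hits <- order(d + ifelse(y == y[i], 0, Inf))[seq_len(k)]
    miss <- order(d + ifelse(y != y[i], 0, Inf))[seq_len(k)]
    for (f in seq_len(p)) {
      w[f] <- w[f] - sum(abs(X[hits, f] - X[i, f])) / (rng[f] * n * k) +
        sum(abs(X[miss, f] - X[i, f])) / (rng[f] * n * k)
    }
  }
  w
}

# Lexicographically smallest shortest path between two nodes, via igraph
# exhaustive shortest-path enumeration.
oracle_lex_shortest <- function(g, s, t) {
  asp <- igraph::all_shortest_paths(g, from = s, to = t)$res
  if (length(asp) == 0) return(NULL)
  seqs <- lapply(asp, function(p) igraph::V(g)$name[p])
  keys <- vapply(seqs, paste, character(1), collapse = "\r")
  seqs[[order(keys)[1]]]
}

random_network <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(site_a = pairs[keep, 1], site_b = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "differential_network")
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}
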