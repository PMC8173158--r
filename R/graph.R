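adjacency_index <- function(network) {
  nodes <- network$nodes
  idx <- seq_along(nodes)
  names(idx) <- nodes
  adj <- vector("list", length(nodes))
  if (nrow(network$edges) > 0) {
    a <- idx[network$edges$site_a]
    b <- idx[network$edges$site_b]
    for (i in seq_along(a)) {
      adj[[a[i]]] <- c(adj[[a[i]]], b[i])
      adj[[b[i]]] <- c(adj[[b[i]]], a[i])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  list(nodes = nodes, idx = idx, adj = adj)
}

bfs_dist <- function(adj, from, n) {
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

#' Shortest aging-to-disease paths in the differential network
#'
#' For every (source, target) marker pair present and connected in the
#' network, the unique shortest path by hop count is extracted (edges are
#' unweighted, making Dijkstra equivalent to breadth-first search); among
#' equally short paths, the lexicographically smallest node sequence is
#' returned, making the result deterministic. Unreachable or absent pairs
#' yield no path.
#'
#' @param network a `differential_network`.
#' @param sources character vector of source (aging-marker) node IDs.
#' @param targets character vector of target (disease-marker) node IDs.
#' @return A named list of paths (`"source->target"` to node-ID vectors).
#' @export
graph_shortest_paths <- function(network, sources, targets) {
  ai <- adjacency_index(network)
  n <- length(ai$nodes)
  sources <- intersect(sources, ai$nodes)
  targets <- intersect(targets, ai$nodes)
  paths <- list()
  dist_to_target <- lapply(targets, function(t) bfs_dist(ai$adj, ai$idx[[t]], n))
  names(dist_to_target) <- targets
  for (s in sources) {
    ds <- bfs_dist(ai$adj, ai$idx[[s]], n)
    for (t in targets) {
      if (s == t) next
      L <- ds[ai$idx[[t]]]
      if (is.na(L)) next
      dt <- dist_to_target[[t]]
      # greedy reconstruction: at each step take the lexicographically
      # smallest neighbour still on a shortest s->t path
      cur <- ai$idx[[s]]
      path <- cur
      while (cur != ai$idx[[t]]) {
        nbs <- ai$adj[[cur]]
        ok <- nbs[!is.na(ds[nbs]) & ds[nbs] == ds[cur] + 1L &
                    !is.na(dt[nbs]) & dt[nbs] == L - ds[cur] - 1L]
        nxt <- ok[order(ai$nodes[ok])[1]]
        path <- c(path, nxt)
        cur <- nxt
      }
      paths[[paste0(s, "->", t)]] <- ai$nodes[path]
    }
  }
  paths
}

#' Path-restricted betweenness of network nodes
#'
#' Counts, for each node, the number of source-to-target shortest paths on
#' which it lies as an interior node (endpoints excluded).
#'
#' @param paths a path list from [graph_shortest_paths()].
#' @param nodes the node universe to report over.
#' @return A named integer vector.
#' @export
path_betweenness <- function(paths, nodes) {
  bet <- setNames(integer(length(nodes)), nodes)
  for (p in paths) {
    interior <- p[-c(1, length(p))]
    if (length(interior) > 0)
      bet[interior] <- bet[interior] + 1L
  }
  bet
}

#' Permutation test for path-restricted betweenness
#'
#' The observed betweenness counts the aging-to-disease shortest paths
#' through each node. The null redraws the source and target marker labels
#' uniformly (without replacement) among the network nodes `n_perm` times
#' and recomputes the statistic; the p-value is the fraction of
#' permutations whose betweenness reaches the observed value.
#'
#' @param network a `differential_network`.
#' @param sources,targets observed marker node IDs.
#' @param n_perm permutations (at least 100).
#' @param seed integer seed.
#' @return A data.frame `node`, `betweenness`, `p`, sorted by decreasing
#'   betweenness.
#' @export
betweenness_permutation_test <- function(network, sources, targets,
                                         n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 100)
  obs_paths <- graph_shortest_paths(network, sources, targets)
  obs <- path_betweenness(obs_paths, network$nodes)
  n_s <- length(intersect(sources, network$nodes))
  n_t <- length(intersect(targets, network$nodes))
  set.seed(seed)
  ge <- setNames(numeric(length(network$nodes)), network$nodes)
  for (b in seq_len(n_perm)) {
    lab <- sample(network$nodes, n_s + n_t)
    pp <- graph_shortest_paths(network, lab[seq_len(n_s)],
                               lab[n_s + seq_len(n_t)])
    pb <- path_betweenness(pp, network$nodes)
    ge <- ge + (pb >= obs)
  }
  out <- data.frame(node = network$nodes, betweenness = as.integer(obs),
                    p = ge / n_perm, stringsAsFactors = FALSE)
  out[order(-out$betweenness, out$node), , drop = FALSE]
}
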