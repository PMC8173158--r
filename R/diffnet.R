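#' Pairwise Pearson correlations with p-values
#'
#' Standard Pearson r for every column pair; p-values from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Zero-variance columns yield `NA` entries (excluded downstream).
#'
#' @param X numeric matrix, samples x sites, no missing values.
#' @return A list of symmetric matrices `r`, `p`.
#' @export
pairwise_pearson <- function(X) {
  stopifnot(nrow(X) >= 4, !anyNA(X))
  n <- nrow(X)
  sds <- apply(X, 2, sd)
  r <- suppressWarnings(cor(X))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  p <- corr_pvalue(r, n, df = n - 2)
  list(r = r, p = p)
}

corr_pvalue <- function(r, n, df) {
  rc <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- rc * sqrt(df / (1 - rc^2))
  p <- 2 * pt(-abs(tstat), df)
  p[abs(r) >= 1] <- 0
  p[is.na(r)] <- NA
  if (!is.null(dim(p))) diag(p) <- 0
  p
}

#' First-order partial correlations given the aging score
#'
#' For every column pair (x, y) the partial correlation conditioning on the
#' score `z` is `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`;
#' p-values from the t-transform with `n - 3` degrees of freedom. Columns
#' perfectly correlated with `z` yield `NA`.
#'
#' @param X numeric matrix, samples x sites.
#' @param z numeric conditioning vector (the aging score), positive
#'   variance.
#' @return A list of symmetric matrices `pr`, `p`.
#' @export
partial_correlation <- function(X, z) {
  stopifnot(nrow(X) >= 4, length(z) == nrow(X), var(z) > 0, !anyNA(X))
  n <- nrow(X)
  r <- suppressWarnings(cor(X))
  rz <- suppressWarnings(as.vector(cor(X, z)))
  denom <- sqrt(outer(1 - rz^2, 1 - rz^2))
  pr <- (r - outer(rz, rz)) / denom
  pr[abs(rz) >= 1 - 1e-12, ] <- NA
  pr[, abs(rz) >= 1 - 1e-12] <- NA
  diag(pr) <- 1
  p <- corr_pvalue(pr, n, df = n - 3)
  list(pr = pr, p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up BH with monotonicity enforcement; the single shared
#' implementation used by both the network and enrichment stages.
#'
#' @param p_values numeric p-values in `[0, 1]` (`NA` preserved).
#' @return Adjusted q-values.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Per-pair correlation statistics for the differential network
#'
#' Computes, over one candidate site universe, the Pearson correlation and
#' the aging-score-conditioned partial correlation in the control-aged group
#' and in the disease group, BH-adjusts the four p-value families
#' separately across all candidate pairs, and forms the per-group difference
#' `delta_g = r_g - pr_g` whose sign carries the aging-acceleration signal.
#'
#' @param X_ctrl,X_nd numeric matrices (samples x identical site columns).
#' @param z_ctrl,z_nd aging-score vectors for the two groups.
#' @return A data.frame of pairs (`site_a < site_b`) with columns `r_ctrl`,
#'   `pr_ctrl`, `r_nd`, `pr_nd`, their q-values, `delta_ctrl`, `delta_nd`
#'   and `min_q`; pairs with undefined statistics are dropped.
#' @export
compute_pair_stats <- function(X_ctrl, X_nd, z_ctrl, z_nd) {
  stopifnot(identical(colnames(X_ctrl), colnames(X_nd)))
  pc <- pairwise_pearson(X_ctrl)
  pn <- pairwise_pearson(X_nd)
  qc <- partial_correlation(X_ctrl, z_ctrl)
  qn <- partial_correlation(X_nd, z_nd)
  sites <- colnames(X_ctrl)
  up <- which(upper.tri(pc$r), arr.ind = TRUE)
  df <- data.frame(
    site_a = sites[up[, 1]], site_b = sites[up[, 2]],
    r_ctrl = pc$r[up], p_r_ctrl = pc$p[up],
    pr_ctrl = qc$pr[up], p_pr_ctrl = qc$p[up],
    r_nd = pn$r[up], p_r_nd = pn$p[up],
    pr_nd = qn$pr[up], p_pr_nd = qn$p[up],
    stringsAsFactors = FALSE
  )
  ok <- stats::complete.cases(df)
  if (any(!ok)) message(sum(!ok), " pair(s) with undefined statistics dropped")
  df <- df[ok, , drop = FALSE]
  df$q_r_ctrl <- bh_fdr(df$p_r_ctrl)
  df$q_pr_ctrl <- bh_fdr(df$p_pr_ctrl)
  df$q_r_nd <- bh_fdr(df$p_r_nd)
  df$q_pr_nd <- bh_fdr(df$p_pr_nd)
  df$delta_ctrl <- df$r_ctrl - df$pr_ctrl
  df$delta_nd <- df$r_nd - df$pr_nd
  df$min_q <- pmin(df$q_r_ctrl, df$q_pr_ctrl, df$q_r_nd, df$q_pr_nd)
  df
}

#' Build the aging-acceleration differential network
#'
#' An edge is retained when the correlation-minus-partial-correlation
#' difference has opposite signs in the disease and control groups and the
#' FDR gate passes (by default the minimum of the four adjusted p-values is
#' below the threshold). Degree and (global) betweenness are filled per
#' node.
#'
#' @param pair_stats output of [compute_pair_stats()].
#' @param fdr_threshold FDR gate (default 0.1).
#' @param gate `"min"` (default) gates on the minimum of the four q-values;
#'   `"all"` requires all four below the threshold.
#' @param rule `"within"` (default) compares the sign of
#'   `delta_g = r_g - pr_g` between groups; `"between"` compares the signs
#'   of the between-group differences of r and of pr.
#' @param provenance optional label (disease, train/test) stored on the
#'   network.
#' @return An object of class `differential_network`: `nodes`, `edges`,
#'   `degree`, `betweenness`, `graph` (igraph), `provenance`.
#' @export
build_differential_network <- function(pair_stats, fdr_threshold = 0.1,
                                       gate = c("min", "all"),
                                       rule = c("within", "between"),
                                       provenance = NULL) {
  gate <- match.arg(gate)
  rule <- match.arg(rule)
  opposite <- if (rule == "within") {
    sign(pair_stats$delta_nd) * sign(pair_stats$delta_ctrl) < 0
  } else {
    sign(pair_stats$r_nd - pair_stats$r_ctrl) *
      sign(pair_stats$pr_nd - pair_stats$pr_ctrl) < 0
  }
  fdr_ok <- if (gate == "min") {
    pair_stats$min_q < fdr_threshold
  } else {
    pair_stats$q_r_ctrl < fdr_threshold &
      pair_stats$q_pr_ctrl < fdr_threshold &
      pair_stats$q_r_nd < fdr_threshold &
      pair_stats$q_pr_nd < fdr_threshold
  }
  edges <- pair_stats[opposite & fdr_ok, , drop = FALSE]
  nodes <- sort(unique(c(pair_stats$site_a, pair_stats$site_b)))
  if (nrow(edges) == 0) warning("differential network is empty")
  g <- igraph::graph_from_data_frame(
    edges[, c("site_a", "site_b")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  structure(list(
    nodes = nodes,
    edges = edges,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g),
    graph = g,
    provenance = provenance
  ), class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf("<differential_network> %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$provenance)) "" else
                paste0(" [", paste(x$provenance, collapse = "/"), "]")))
  invisible(x)
}

#' Log-log power-law check of the degree distribution
#'
#' Least-squares fit of `log10 P(degree = d)` against `log10 d` over the
#' observed positive degrees; a steep negative slope with strongly negative
#' Pearson r indicates a scale-free degree distribution.
#'
#' @param network a `differential_network`, or a numeric degree vector.
#' @return A list `slope`, `r`, `n_degrees`, `testable`; fewer than three
#'   distinct positive degrees is signalled as not testable.
#' @export
power_law_check <- function(network) {
  deg <- if (inherits(network, "differential_network")) network$degree
         else network
  deg <- deg[deg > 0]
  tab <- table(deg)
  d <- as.numeric(names(tab))
  if (length(d) < 3) {
    warning("fewer than 3 distinct degrees: power-law fit not testable")
    return(list(slope = NA_real_, r = NA_real_, n_degrees = length(d),
                testable = FALSE))
  }
  if (length(d) < 10)
    message("fewer than 10 distinct degrees: power-law fit is coarse")
  pd <- as.numeric(tab) / sum(tab)
  fit <- lm(log10(pd) ~ log10(d))
  list(slope = unname(coef(fit)[2]), r = cor(log10(d), log10(pd)),
       n_degrees = length(d), testable = TRUE)
}

edge_keys <- function(edges) {
  paste(pmin(edges$site_a, edges$site_b), pmax(edges$site_a, edges$site_b),
        sep = "|")
}

#' Fisher exact test of edge overlap between two networks
#'
#' Cross-tabulates the candidate pair universe by edge membership in each
#' network and tests for enrichment of shared edges (one-sided).
#'
#' @param net_a,net_b `differential_network`s over the same node universe.
#' @param universe_pairs data.frame of all candidate pairs (`site_a`,
#'   `site_b`), e.g. the [compute_pair_stats()] table.
#' @return A list `odds_ratio`, `p`, `table`.
#' @export
network_similarity_fisher <- function(net_a, net_b, universe_pairs) {
  u <- edge_keys(universe_pairs)
  a <- u %in% edge_keys(net_a$edges)
  b <- u %in% edge_keys(net_b$edges)
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margins in the similarity table")
    return(list(odds_ratio = NA_real_, p = 1, table = tab))
  }
  ft <- fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
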