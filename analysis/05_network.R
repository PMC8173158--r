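#!/usr/bin/env Rscript
# Stage 5 — aging-acceleration differential network.
# Over a candidate universe (selected markers plus the highest-variance
# sites), Pearson and aging-score-conditioned partial correlations are
# computed separately in the control and pooled-disease arms; the four
# p-value families are BH-adjusted; an edge is kept when the r - pr
# difference flips sign between arms at FDR < 0.1. The training network is
# checked for a scale-free degree law, validated against the test network
# (Fisher), and mined for shortest aging-to-disease paths with a
# permutation test on path betweenness.

source("analysis/00_config.R")
cfg <- analysis_config()
cn <- cfg$network
st <- readRDS(cache("01_cohort"))
data <- readRDS(cache("02_preprocessed"))
mk <- readRDS(cache("03_markers"))
sc <- readRDS(cache("04_scores"))

markers_all <- unique(c(mk$aging$selected_sites,
                        unlist(lapply(mk$disease, `[[`, "selected_sites"))))
train <- subset_dataset(data, data$meta$split == "train")
vars <- apply(train$values, 2, var)
universe <- union(markers_all,
                  head(names(sort(vars, decreasing = TRUE)),
                       cn$universe_top_var))
diseases <- names(mk$disease)

nets <- list()
for (part in c("train", "test")) {
  dd <- subset_dataset(data, data$meta$split == part)
  s <- sc$scores[match(dd$meta$sample_id, sc$scores$sample_id), ]
  ctrl <- dd$meta$group == "control"
  ndr <- dd$meta$group %in% diseases
  ps <- compute_pair_stats(dd$values[ctrl, universe, drop = FALSE],
                           dd$values[ndr, universe, drop = FALSE],
                           s$aging_score[ctrl], s$aging_score[ndr])
  nets[[part]] <- list(ps = ps,
                       net = build_differential_network(
                         ps, fdr_threshold = cn$fdr, gate = cn$gate,
                         rule = cn$rule, provenance = c("ALL", part)))
}
net <- nets$train$net
cat(sprintf("training network: %d nodes, %d edges (of %d candidate pairs)\n",
            sum(net$degree > 0), nrow(net$edges), nrow(nets$train$ps)))

plaw <- power_law_check(net)
if (plaw$testable)
  cat(sprintf("degree distribution: log-log slope %.2f, r = %.2f\n",
              plaw$slope, plaw$r))
sim <- network_similarity_fisher(nets$train$net, nets$test$net,
                                 nets$train$ps)
cat(sprintf("train/test edge overlap: odds ratio %.1f, Fisher p = %.3g\n",
            sim$odds_ratio, sim$p))

# planted sign-flip recovery
tp <- st$gen$truth$signflip_pairs
canon <- paste(pmin(tp[, 1], tp[, 2]), pmax(tp[, 1], tp[, 2]), sep = "|")
got <- paste(pmin(net$edges$site_a, net$edges$site_b),
             pmax(net$edges$site_a, net$edges$site_b), sep = "|")
cat(sprintf("planted sign-flip pairs recovered: %d / %d\n",
            sum(canon %in% got), length(canon)))

paths <- graph_shortest_paths(net, mk$aging$selected_sites,
                              unique(unlist(lapply(mk$disease, `[[`,
                                                   "selected_sites"))))
cat(sprintf("aging->disease shortest paths found: %d\n", length(paths)))
betw <- betweenness_permutation_test(
  net, mk$aging$selected_sites,
  unique(unlist(lapply(mk$disease, `[[`, "selected_sites"))),
  n_perm = cn$n_perm, seed = derive_seed(MASTER_SEED, "betweenness"))
cat("top path-betweenness nodes:\n")
print(head(betw, 5), row.names = FALSE)

table_out(net$edges[, c("site_a", "site_b", "r_ctrl", "pr_ctrl", "r_nd",
                        "pr_nd", "delta_ctrl", "delta_nd", "min_q")],
          "network_edges_train")
table_out(betw, "network_betweenness")
saveRDS(list(nets = nets, paths = paths, betw = betw, universe = universe),
        cache("05_network"))
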