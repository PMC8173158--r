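#!/usr/bin/env Rscript
# Stage 4 — aging and disease risk scores.
# A 100-tree bagged regression ensemble maps the selected aging markers to
# a young(0)/aged(1) score; training samples are scored out of bag. The
# sigmoid age transform and its regression slope give the adjusted score.
# Normality of the score is tested (K-S) and the accelerated-aging pattern
# is compared between disease and control arms per age stratum
# (Kruskal-Wallis, thresholds 50..80).

source("analysis/00_config.R")
cfg <- analysis_config()
data <- readRDS(cache("02_preprocessed"))
mk <- readRDS(cache("03_markers"))
train <- subset_dataset(data, data$meta$split == "train")

healthy_tr <- train$meta$group %in% c("young", "control")
aging_scorer <- fit_score_regressor(
  train$values[healthy_tr, mk$aging$selected_sites, drop = FALSE],
  as.integer(train$meta$group[healthy_tr] == "control"),
  n_trees = cfg$scoring$n_trees,
  seed = derive_seed(MASTER_SEED, "score_aging"))
disease_scorers <- list()
for (d in names(mk$disease)) {
  rows <- train$meta$group %in% c("control", d)
  disease_scorers[[d]] <- fit_score_regressor(
    train$values[rows, mk$disease[[d]]$selected_sites, drop = FALSE],
    as.integer(train$meta$group[rows] == d),
    n_trees = cfg$scoring$n_trees,
    seed = derive_seed(MASTER_SEED, paste0("score_", d)))
}

scores <- score_table(data, aging_scorer, disease_scorers)
ks <- ks_normality_test(scores$aging_score)
kw <- kruskal_wallis_by_age_group(scores$aging_score, scores$group,
                                  scores$age,
                                  thresholds = cfg$scoring$kw_thresholds)
nd <- scores$group %in% names(mk$disease)
cat(sprintf("K-S normality: D = %.3f, p = %.3g (normality %s)\n",
            ks$statistic, ks$p,
            if (ks$p < 0.05) "rejected" else "not rejected"))
cat("median aging score by minimum age (ND vs control):\n")
for (i in seq_len(nrow(kw))) {
  t <- kw$threshold[i]
  cat(sprintf("  age >= %d: %.3f vs %.3f  (KW p = %.3g)\n", t,
              median(scores$aging_score[nd & scores$age >= t]),
              median(scores$aging_score[scores$group == "control" &
                                          scores$age >= t]),
              kw$p[i]))
}

table_out(scores, "score_table")
table_out(kw, "kruskal_wallis_by_age")
saveRDS(list(scores = scores, aging_scorer = aging_scorer,
             disease_scorers = disease_scorers), cache("04_scores"))
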