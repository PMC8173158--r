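#!/usr/bin/env Rscript
# Stage 3 — marker selection.
# ReliefF ranking of all sites, then a 10-fold cross-validated sweep over
# the top 1..50 dimensions with the 100-round boosted tree ensemble; for
# each disease the aged controls are partitioned into the study's 3/9/7/3
# subgroups to balance the classes. Held-out accuracy and AUC evaluate each
# predictor on the test split.

source("analysis/00_config.R")
cfg <- analysis_config()
cm <- cfg$markers
st <- readRDS(cache("01_cohort"))
data <- readRDS(cache("02_preprocessed"))
train <- subset_dataset(data, data$meta$split == "train")
test <- subset_dataset(data, data$meta$split == "test")

healthy_tr <- train$meta$group %in% c("young", "control")
X_tr <- train$values[healthy_tr, , drop = FALSE]
y_tr <- as.integer(train$meta$group[healthy_tr] == "control")
rk <- relieff_rank(X_tr, y_tr, n_neighbors = cm$n_neighbors,
                   seed = derive_seed(MASTER_SEED, "relieff_aging"))
aging_ms <- select_top_k_cv(X_tr, y_tr, rk$site_id, k_max = cm$k_max,
                            folds = cm$folds,
                            n_estimators = cm$n_estimators,
                            seed = derive_seed(MASTER_SEED, "cv_aging"))
healthy_te <- test$meta$group %in% c("young", "control")
ev <- evaluate_classifier(
  aging_ms$final_model,
  test$values[healthy_te, aging_ms$selected_sites, drop = FALSE],
  as.integer(test$meta$group[healthy_te] == "control"))
recov <- mean(st$gen$truth$aging_marker_ids %in% aging_ms$selected_sites)
cat(sprintf(
  "aging predictor: k = %d, test accuracy %.3f, AUC %.3f; %.0f%% of planted markers recovered\n",
  aging_ms$selected_k, ev$accuracy, ev$auc, 100 * recov))

disease_ms <- list()
rows_acc <- list(data.frame(target = "aging", selected_k = aging_ms$selected_k,
                            test_accuracy = ev$accuracy, test_auc = ev$auc))
for (d in names(cfg$synthetic$n_per_disease)) {
  Xc <- train$values[train$meta$group == "control", , drop = FALSE]
  Xd <- train$values[train$meta$group == d, , drop = FALSE]
  ms <- balanced_disease_fit(Xc, Xd,
                             n_subgroups = cm$disease_subgroups[[d]],
                             k_max = cm$k_max, folds = cm$folds,
                             n_estimators = cm$n_estimators,
                             n_neighbors = cm$n_neighbors,
                             seed = derive_seed(MASTER_SEED,
                                                paste0("disease_", d)))
  keep <- test$meta$group %in% c("control", d)
  evd <- evaluate_classifier(
    ms$final_model, test$values[keep, ms$selected_sites, drop = FALSE],
    as.integer(test$meta$group[keep] == d))
  cat(sprintf("%s predictor: k = %d, test accuracy %.3f, AUC %.3f\n",
              d, ms$selected_k, evd$accuracy, evd$auc))
  disease_ms[[d]] <- ms
  rows_acc[[d]] <- data.frame(target = d, selected_k = ms$selected_k,
                              test_accuracy = evd$accuracy,
                              test_auc = evd$auc)
}

table_out(do.call(rbind, rows_acc), "predictor_accuracy")
table_out(data.frame(rank = seq_along(aging_ms$ranked_site_ids),
                     cpg_id = aging_ms$ranked_site_ids,
                     selected = seq_along(aging_ms$ranked_site_ids) <=
                       aging_ms$selected_k),
          "aging_marker_ranking")
saveRDS(list(aging = aging_ms, disease = disease_ms), cache("03_markers"))
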