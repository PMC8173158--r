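#' Default pipeline configuration
#'
#' All thresholds default to the study's printed values: site missingness
#' 0.3, KNN k = 10, three SVD components, 2:1 train/test split, top-50 CV
#' sweep with 10 folds, 100-tree ensembles, control subgrouping 3/9/7/3 for
#' AD/PD/PSP/FTD, network FDR 0.1, enrichment FDR 0.05, and a
#' 20000-draw/5000-burn-in chain. Every stage draws its randomness from a
#' named sub-stream of the single master seed.
#'
#' @param seed master seed.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = seed,
    synthetic = list(
      n_young = 366, n_old = 442,
      n_per_disease = c(AD = 128, PD = 36, PSP = 42, FTD = 123),
      n_cpg = 2000, n_aging_markers = 40, n_disease_markers = 20,
      aging_effect = 0.5, disease_effect = 0.5, accel_factor = 1.5,
      n_cohorts = 4, batch_sd = 1, missing_frac = 0.05,
      signflip_pairs = 20, signflip_rho = 0.8
    ),
    preprocess = list(max_missing = 0.3, knn_k = 10, svd_components = 3,
                      split_ratio = "2:1"),
    markers = list(k_max = 50, folds = 10, n_estimators = 100,
                   n_neighbors = 30,
                   disease_subgroups = c(AD = 3, PD = 9, PSP = 7, FTD = 3)),
    scoring = list(n_trees = 100, kw_thresholds = seq(50, 80, by = 5)),
    network = list(fdr = 0.1, gate = "min", rule = "within",
                   universe_top_var = 500, n_perm = 1000),
    sensitivity = list(n_samples = 20000, burn_in = 5000,
                       proposal_scale = NULL, top_n = 50),
    enrichment = list(fdr = 0.05, n_genes = 500, n_sets = 50,
                      set_size = 25)
  )
}

write_stage_table <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Run the complete analysis pipeline
#'
#' Executes, in order: synthetic-cohort generation, preprocessing, marker
#' selection (aging and per-disease), aging/risk scoring with the
#' age-stratified Kruskal-Wallis comparison, the aging-acceleration
#' differential network on the training and test splits (with scale-free
#' check, Fisher train/test similarity, shortest aging-to-disease paths and
#' permutation betweenness), the MCMC sensitivity scan, and gene-set
#' enrichment of the path genes. Deterministic under the master seed.
#'
#' @param config configuration list, see [default_config()].
#' @param out_dir optional directory; when given, stage tables and a JSON
#'   manifest are written there.
#' @return A list with one element per stage.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cs <- config$synthetic
  master <- config$seed

  # --- synthetic cohort -----------------------------------------------
  gen <- generate_dataset(
    n_young = cs$n_young, n_old = cs$n_old,
    n_per_disease = cs$n_per_disease, n_cpg = cs$n_cpg,
    n_aging_markers = cs$n_aging_markers,
    n_disease_markers = cs$n_disease_markers,
    aging_effect = cs$aging_effect, disease_effect = cs$disease_effect,
    accel_factor = cs$accel_factor, n_cohorts = cs$n_cohorts,
    batch_sd = cs$batch_sd, missing_frac = cs$missing_frac,
    seed = derive_seed(master, "synthetic")
  )
  if (cs$signflip_pairs > 0) {
    gen <- plant_signflip_pairs(gen$dataset, gen$truth,
                                n_pairs = cs$signflip_pairs,
                                rho = cs$signflip_rho,
                                seed = derive_seed(master, "signflip"))
  }
  truth <- gen$truth
  ann <- generate_annotation_and_genesets(
    n_cpg = cs$n_cpg, n_genes = config$enrichment$n_genes,
    n_sets = config$enrichment$n_sets,
    set_size = config$enrichment$set_size, truth = truth,
    seed = derive_seed(master, "annotation")
  )

  # --- preprocessing ---------------------------------------------------
  cp <- config$preprocess
  data <- preprocess_pipeline(
    gen$dataset, max_missing = cp$max_missing, knn_k = cp$knn_k,
    n_components = cp$svd_components, split_ratio = cp$split_ratio,
    seed = derive_seed(master, "split")
  )
  train <- subset_dataset(data, data$meta$split == "train")
  test <- subset_dataset(data, data$meta$split == "test")

  # --- marker selection ------------------------------------------------
  cm <- config$markers
  healthy_tr <- train$meta$group %in% c("young", "control")
  X_tr <- train$values[healthy_tr, , drop = FALSE]
  y_tr <- as.integer(train$meta$group[healthy_tr] == "control")
  rk <- relieff_rank(X_tr, y_tr, n_neighbors = cm$n_neighbors,
                     seed = derive_seed(master, "relieff_aging"))
  aging_ms <- select_top_k_cv(X_tr, y_tr, rk$site_id, k_max = cm$k_max,
                              folds = cm$folds,
                              n_estimators = cm$n_estimators,
                              seed = derive_seed(master, "cv_aging"))
  healthy_te <- test$meta$group %in% c("young", "control")
  aging_eval <- evaluate_classifier(
    aging_ms$final_model,
    test$values[healthy_te, aging_ms$selected_sites, drop = FALSE],
    as.integer(test$meta$group[healthy_te] == "control")
  )

  diseases <- names(cs$n_per_disease)
  disease_ms <- list()
  disease_eval <- list()
  for (d in diseases) {
    Xc <- train$values[train$meta$group == "control", , drop = FALSE]
    Xd <- train$values[train$meta$group == d, , drop = FALSE]
    ms <- balanced_disease_fit(
      Xc, Xd, n_subgroups = cm$disease_subgroups[[d]], k_max = cm$k_max,
      folds = cm$folds, n_estimators = cm$n_estimators,
      n_neighbors = cm$n_neighbors,
      seed = derive_seed(master, paste0("disease_", d))
    )
    keep_te <- test$meta$group %in% c("control", d)
    disease_eval[[d]] <- evaluate_classifier(
      ms$final_model,
      test$values[keep_te, ms$selected_sites, drop = FALSE],
      as.integer(test$meta$group[keep_te] == d)
    )
    disease_ms[[d]] <- ms
  }

  # --- scoring ---------------------------------------------------------
  co <- config$scoring
  aging_scorer <- fit_score_regressor(
    X_tr[, aging_ms$selected_sites, drop = FALSE], y_tr,
    n_trees = co$n_trees, seed = derive_seed(master, "score_aging")
  )
  disease_scorers <- list()
  for (d in diseases) {
    rows <- train$meta$group %in% c("control", d)
    disease_scorers[[d]] <- fit_score_regressor(
      train$values[rows, disease_ms[[d]]$selected_sites, drop = FALSE],
      as.integer(train$meta$group[rows] == d),
      n_trees = co$n_trees, seed = derive_seed(master, paste0("score_", d))
    )
  }
  scores <- score_table(data, aging_scorer, disease_scorers)
  ks_norm <- ks_normality_test(scores$aging_score)
  kw <- kruskal_wallis_by_age_group(scores$aging_score, scores$group,
                                    scores$age,
                                    thresholds = co$kw_thresholds)
  write_stage_table(scores, out_dir, "score_table")
  write_stage_table(kw, out_dir, "kruskal_wallis_by_age")

  # --- differential network -------------------------------------------
  cn <- config$network
  markers_all <- unique(c(aging_ms$selected_sites,
                          unlist(lapply(disease_ms, `[[`,
                                        "selected_sites"))))
  vars <- apply(train$values, 2, var)
  top_var <- names(sort(vars, decreasing = TRUE))
  universe <- union(markers_all,
                    head(top_var, cn$universe_top_var))
  nets <- list()
  for (part in c("train", "test")) {
    dd <- if (part == "train") train else test
    sc <- scores[match(dd$meta$sample_id, scores$sample_id), ]
    ctrl <- dd$meta$group == "control"
    nd <- dd$meta$group %in% diseases
    ps <- compute_pair_stats(
      dd$values[ctrl, universe, drop = FALSE],
      dd$values[nd, universe, drop = FALSE],
      sc$aging_score[ctrl], sc$aging_score[nd]
    )
    nets[[part]] <- list(
      pair_stats = ps,
      network = build_differential_network(ps, fdr_threshold = cn$fdr,
                                           gate = cn$gate, rule = cn$rule,
                                           provenance = c("ALL", part))
    )
  }
  similarity <- network_similarity_fisher(nets$train$network,
                                          nets$test$network,
                                          nets$train$pair_stats)
  plaw <- power_law_check(nets$train$network)
  net_tr <- nets$train$network
  paths <- graph_shortest_paths(
    net_tr, aging_ms$selected_sites,
    unique(unlist(lapply(disease_ms, `[[`, "selected_sites")))
  )
  betw <- if (length(paths) > 0) {
    betweenness_permutation_test(
      net_tr, aging_ms$selected_sites,
      unique(unlist(lapply(disease_ms, `[[`, "selected_sites"))),
      n_perm = cn$n_perm, seed = derive_seed(master, "betweenness")
    )
  } else NULL
  write_stage_table(net_tr$edges, out_dir, "network_edges_train")
  if (!is.null(betw)) write_stage_table(betw, out_dir, "betweenness")

  # --- sensitivity -----------------------------------------------------
  cse <- config$sensitivity
  sens <- run_sensitivity(
    train$values, aging_ms$selected_sites,
    lapply(disease_ms, `[[`, "selected_sites"),
    aging_scorer, disease_scorers,
    n_samples = cse$n_samples, burn_in = cse$burn_in,
    proposal_scale = cse$proposal_scale,
    seed = derive_seed(master, "mcmc")
  )
  ranking <- rank_aging_nd_pairs(sens, aging_ms$selected_sites,
                                 lapply(disease_ms, `[[`,
                                        "selected_sites"),
                                 top_n = cse$top_n)
  write_stage_table(ranking$frequency, out_dir, "shared_marker_frequency")

  # --- enrichment ------------------------------------------------------
  ce <- config$enrichment
  enr <- NULL
  if (length(paths) > 0) {
    path_genes <- map_paths_to_genes(paths, ann$annotation)
    if (length(path_genes) > 0) {
      enr <- enrich(path_genes, ann$genesets, ann$universe,
                    fdr_threshold = ce$fdr)
      write_stage_table(enr, out_dir, "enrichment")
    }
  }
  if (is.null(enr)) message("no network paths: enrichment skipped")

  result <- list(
    truth = truth, annotation = ann, data = data,
    aging_markers = aging_ms, aging_eval = aging_eval,
    disease_markers = disease_ms, disease_eval = disease_eval,
    aging_scorer = aging_scorer, disease_scorers = disease_scorers,
    scores = scores, ks_normality = ks_norm, kruskal_wallis = kw,
    networks = nets, similarity = similarity, power_law = plaw,
    paths = paths, betweenness = betw,
    sensitivity = sens, pair_ranking = ranking, enrichment = enr,
    config = config
  )
  if (!is.null(out_dir)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("epiaccel")),
      seed = master, config = config,
      stages = c("synthetic", "preprocess", "markers", "scoring",
                 "network", "sensitivity", "enrichment")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}
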