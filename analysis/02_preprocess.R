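#!/usr/bin/env Rscript
# Stage 2 — preprocessing.
# Site missingness filter (>= 30% removed), KNN imputation (k = 10),
# sample filtering (no age / early-onset disease), z-scoring against the
# healthy aged reference, removal of the top three reference singular
# directions, a second reference z-scoring, and the stratified 2:1 split.

source("analysis/00_config.R")
cfg <- analysis_config()
st <- readRDS(cache("01_cohort"))

before <- dim(st$gen$dataset$values)
data <- preprocess_pipeline(
  st$gen$dataset,
  max_missing = cfg$preprocess$max_missing,
  knn_k = cfg$preprocess$knn_k,
  n_components = cfg$preprocess$svd_components,
  split_ratio = cfg$preprocess$split_ratio,
  seed = derive_seed(MASTER_SEED, "split")
)
cat(sprintf("samples %d -> %d, sites %d -> %d, missing now %.1f%%\n",
            before[1], nrow(data$values), before[2], ncol(data$values),
            100 * mean(is.na(data$values))))
print(table(data$meta$group, data$meta$split))

table_out(data$meta, "preprocessed_metadata")
saveRDS(data, cache("02_preprocessed"))
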