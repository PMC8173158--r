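#!/usr/bin/env Rscript
# Stage 1 — synthetic methylation cohort.
# Generates the cohort with planted aging markers, per-disease markers, an
# inflated aging slope in disease (the accelerated-aging ground truth),
# cohort batch vectors, missing values, sign-flip pairs for the network
# stage, and the CpG->gene annotation with a planted enriched gene set.

source("analysis/00_config.R")
cfg <- analysis_config()
cs <- cfg$synthetic

gen <- generate_dataset(
  n_young = cs$n_young, n_old = cs$n_old,
  n_per_disease = cs$n_per_disease, n_cpg = cs$n_cpg,
  n_aging_markers = cs$n_aging_markers,
  n_disease_markers = cs$n_disease_markers,
  aging_effect = cs$aging_effect, disease_effect = cs$disease_effect,
  accel_factor = cs$accel_factor, n_cohorts = cs$n_cohorts,
  batch_sd = cs$batch_sd, missing_frac = cs$missing_frac,
  seed = derive_seed(MASTER_SEED, "synthetic")
)
gen <- plant_signflip_pairs(gen$dataset, gen$truth,
                            n_pairs = cs$signflip_pairs,
                            rho = cs$signflip_rho,
                            seed = derive_seed(MASTER_SEED, "signflip"))
ann <- generate_annotation_and_genesets(
  n_cpg = cs$n_cpg, n_genes = cfg$enrichment$n_genes,
  n_sets = cfg$enrichment$n_sets, set_size = cfg$enrichment$set_size,
  truth = gen$truth, seed = derive_seed(MASTER_SEED, "annotation")
)

print(gen$dataset)
cat(sprintf(
  "planted: %d aging markers, %d disease markers/disease, %d sign-flip pairs\n",
  length(gen$truth$aging_marker_ids),
  length(gen$truth$disease_marker_ids[[1]]),
  nrow(gen$truth$signflip_pairs)))

# the full matrix is bulky; it goes to the scratch cache, while the
# small human-readable artifacts land under results/
write_dataset(gen$dataset,
              file.path(cache_dir, "cohort_matrix.tsv"),
              file.path(results_dir, "cohort_metadata.tsv"))
write_annotation(ann$annotation, file.path(results_dir, "annotation.tsv"))
write_gmt(ann$genesets, file.path(results_dir, "genesets.gmt"))
saveRDS(list(gen = gen, ann = ann), cache("01_cohort"))
cat("cohort written to", results_dir, "\n")
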