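# Shared settings for the numbered analysis drivers.
#
# The cohort keeps the study's sample-group structure (366 young / 442 aged
# healthy, 128 AD / 36 PD / 42 PSP / 123 FTD) and the printed method
# constants (30% site-missingness cut, KNN k=10, 3 SVD components, 2:1
# split, top-50 CV sweep with 10 folds, 100-tree ensembles, 3/9/7/3 control
# subgrouping, network FDR 0.1, enrichment FDR 0.05). The site panel,
# permutation count and chain length are sized for a quick single-CPU run;
# see the methods vignette.

library(epiaccel)

MASTER_SEED <- 20260927L

analysis_config <- function() {
  cfg <- default_config(MASTER_SEED)
  cfg$synthetic$n_cpg <- 1000
  cfg$network$universe_top_var <- 300
  cfg$network$n_perm <- 200
  cfg$sensitivity$n_samples <- 10000
  cfg$sensitivity$burn_in <- 2500
  cfg
}

results_dir <- "results"
cache_dir <- "scratch/analysis_cache"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)

cache <- function(name) file.path(cache_dir, paste0(name, ".rds"))
table_out <- function(df, name) {
  write.table(df, file.path(results_dir, paste0(name, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
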