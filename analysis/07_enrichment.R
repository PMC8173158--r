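#!/usr/bin/env Rscript
# Stage 7 — gene-set enrichment of the shortest-path genes.
# CpGs on the aging-to-disease shortest paths are mapped to genes through
# the annotation; each gene set is tested by the hypergeometric upper tail
# against the full gene universe, with BH control at FDR < 0.05.

source("analysis/00_config.R")
cfg <- analysis_config()
st <- readRDS(cache("01_cohort"))
nw <- readRDS(cache("05_network"))

if (length(nw$paths) == 0) {
  cat("no aging->disease paths in the network; nothing to enrich\n")
  quit(save = "no")
}
genes <- map_paths_to_genes(nw$paths, st$ann$annotation)
cat(sprintf("%d genes on %d shortest paths\n", length(genes),
            length(nw$paths)))

res <- enrich(genes, st$ann$genesets, st$ann$universe,
              fdr_threshold = cfg$enrichment$fdr)
n_sig <- sum(res$significant)
cat(sprintf("%d / %d sets significant at FDR < %.2f\n", n_sig, nrow(res),
            cfg$enrichment$fdr))
cat(sprintf("planted enriched set '%s' ranks %d (q = %.3g)\n",
            st$ann$enriched_set_name,
            which(res$set == st$ann$enriched_set_name)[1],
            res$q[res$set == st$ann$enriched_set_name]))
print(head(res[, c("set", "k", "M", "p", "q", "significant")], 5),
      row.names = FALSE)

table_out(res, "enrichment")
cat("enrichment table written\n")
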