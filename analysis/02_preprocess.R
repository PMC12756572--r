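#!/usr/bin/env Rscript
# Preprocess the cohort expression matrix: quantile normalization, removal
# of genes with zero expression status, and selection of the top-15% most
# variable genes as the clustering feature space.

library(endokit)

expr <- read_expression("results/cohort/expression.tsv")
pp <- preprocess_pipeline(expr, top_frac = 0.15)

dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)
write_expression(pp$features, "results/preprocess/features.tsv")
write_expression(pp$genes, "results/preprocess/genes.tsv")
jsonlite::write_json(unclass(pp$report),
                     "results/preprocess/report.json",
                     auto_unbox = TRUE, force = TRUE)

r <- pp$report
message(sprintf("%d genes in -> %d after expression filter -> %d features (top %.0f%%)",
                r$n_probes_in, r$n_genes_out, r$n_features_selected,
                100 * r$variance_quantile))
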