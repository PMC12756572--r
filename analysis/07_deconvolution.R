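#!/usr/bin/env Rscript
# Immune-cell deconvolution of every sample against the signature matrix
# (linear nu-SVR, simplex-projected coefficients) and association of each
# cell type's fraction with BASICq.

library(endokit)

genes <- read_expression("results/preprocess/genes.tsv")
sig_df <- utils::read.delim("results/cohort/signature.tsv", check.names = FALSE)
sig <- as.matrix(sig_df[, -1])
rownames(sig) <- sig_df[[1]]
bq <- utils::read.csv("results/basicq/basicq.csv")
basicq <- setNames(bq$basicq, bq$sample_id)

dc <- deconvolve_cohort(genes, sig)
assoc <- fractions_vs_score(dc$fractions, basicq[rownames(dc$fractions)])

message(sprintf("median reconstruction r: %.3f", median(dc$fit$pearson_r)))
message("fraction ~ BASICq slopes:")
for (i in seq_len(nrow(assoc)))
  message(sprintf("  %-20s slope %+7.3f  R2 %.3f  adj p %.3g",
                  assoc$cell_type[i], assoc$slope[i], assoc$r_squared[i],
                  assoc$adj_p[i]))

dir.create("results/deconv", showWarnings = FALSE, recursive = TRUE)
utils::write.table(data.frame(sample_id = rownames(dc$fractions),
                              dc$fractions, check.names = FALSE),
                   "results/deconv/fractions.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(assoc, "results/deconv/associations.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
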