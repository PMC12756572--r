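#!/usr/bin/env Rscript
# Preranked gene-set enrichment on the moderated-t ranking, against the
# cohort's gene-set collection (planted marker sets plus decoys for the
# synthetic cohort; any GMT for real data).

library(endokit)

seed <- 20251L
de <- utils::read.delim("results/de/de_results.tsv")
sets <- read_gmt("results/cohort/sets.gmt")

ranks <- rank_genes(de)
res <- gsea_preranked(ranks, sets, n_perm = 1000, seed = seed)

top <- res[order(res$adj_p), ][1:min(10, nrow(res)), ]
message("top enriched sets (by adjusted p):")
for (i in seq_len(nrow(top)))
  message(sprintf("  %-16s NES %+6.2f  adj p %.4f", top$set[i], top$NES[i],
                  top$adj_p[i]))

dir.create("results/gsea", showWarnings = FALSE, recursive = TRUE)
out <- res[, c("set", "size_used", "ES", "NES", "p", "adj_p")]
out$leading_edge <- vapply(res$leading_edge, paste, character(1),
                           collapse = ";")
utils::write.table(out, "results/gsea/gsea_results.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
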