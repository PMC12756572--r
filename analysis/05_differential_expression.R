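#!/usr/bin/env Rscript
# Moderated differential expression between endotypes on all filtered genes:
# per-gene two-group fits, empirical-Bayes variance shrinkage, BH
# adjustment, and flagging at |log2FC| >= 1.5, adjusted p < 0.05.

library(endokit)

genes <- read_expression("results/preprocess/genes.tsv")
labels <- utils::read.csv("results/endotype/labels.csv")
lab <- setNames(labels$endotype, labels$sample_id)[colnames(genes)]

de <- ebayes_moderate(fit_gene_models(genes, lab))
tab <- volcano_table(de, fc_threshold = 1.5, alpha = 0.05)

message(sprintf("prior df d0 = %.2f, prior variance s0^2 = %.4f",
                attr(de, "d0"), attr(de, "s0_sq")))
message(sprintf("%d genes tested; %d flagged (|log2FC| >= 1.5 & adj p < 0.05): %d up, %d down in endotype 1",
                nrow(tab), sum(tab$flagged), sum(tab$direction == 1),
                sum(tab$direction == -1)))

dir.create("results/de", showWarnings = FALSE, recursive = TRUE)
utils::write.table(tab[, c("gene", "log2fc", "t_mod", "p", "adj_p", "flagged")],
                   "results/de/de_results.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
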