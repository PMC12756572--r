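#!/usr/bin/env Rscript
# Reduce the differentially expressed gene space to a minimal diagnostic
# panel: FS-PLS selection of up to 10 discriminatory genes, then exhaustive
# search for the best 1-, 2- and 3-gene combinations with Youden-optimal
# thresholds.

library(endokit)

genes <- read_expression("results/preprocess/genes.tsv")
de <- utils::read.delim("results/de/de_results.tsv")
labels <- utils::read.csv("results/endotype/labels.csv")
lab <- setNames(labels$endotype, labels$sample_id)[colnames(genes)]

de_genes <- de$gene[de$flagged]
message(sprintf("%d flagged genes enter FS-PLS", length(de_genes)))
x <- t(unclass(genes)[de_genes, , drop = FALSE])
y <- as.integer(lab == 1)

trace <- fspls_select(x, y, max_k = 10)
message(sprintf("FS-PLS selected %d genes (%s): %s",
                length(trace$selected_genes), trace$stop_reason,
                paste(trace$selected_genes, collapse = ", ")))

panels <- best_combination(x, y, trace$selected_genes,
                           sizes = 1:min(3, length(trace$selected_genes)))
for (sz in names(panels)) {
  p <- panels[[sz]]
  message(sprintf("best %s-gene panel: %s | AUROC %.3f | sens %.1f%% spec %.1f%% at Youden threshold %.3f",
                  sz, paste(p$genes, collapse = "+"), p$auroc,
                  100 * p$sensitivity, 100 * p$specificity, p$threshold))
}

dir.create("results/signature", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(list(selected_genes = trace$selected_genes,
                          step_p = trace$step_p,
                          stop_reason = trace$stop_reason),
                     "results/signature/fspls_trace.json",
                     auto_unbox = TRUE, digits = NA)
ptab <- do.call(rbind, lapply(panels, function(p) data.frame(
  genes = paste(p$genes, collapse = "+"), auroc = p$auroc,
  threshold = p$threshold, sensitivity = p$sensitivity,
  specificity = p$specificity, youden_j = p$youden_j)))
utils::write.table(ptab, "results/signature/panels.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
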