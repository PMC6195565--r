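#!/usr/bin/env Rscript
# Stage 5: differential expression. Exact negative-binomial test with
# tagwise dispersion on the detected miRNAs, Benjamini-Hochberg correction,
# and assignment of features to group signatures (exclusive / shared /
# excluded) using the p < 0.01 and 32 mean-CPM rules.

suppressPackageStartupMessages(library(evsmallrna))

out <- "results/diffexp"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read.delim("results/simulation/samples.tsv")
ev <- meta$type == "EV"
counts <- read.delim("results/quantify/counts_mirna.tsv", row.names = 1)
counts <- as.matrix(counts)[, meta$sample[ev]]
flt <- read.delim("results/quantify/filter_report_mirna.tsv")

detected <- flt$feature[flt$detected]
de <- de_exact(counts[detected, ], meta$group[ev])
write.table(de, file.path(out, "de_mirna.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

groups <- assign_groups(de, flt, flt, cpm_matrix(counts), meta[ev, ])
write.table(groups, file.path(out, "groups_mirna.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Tested", nrow(de), "detected miRNAs; ",
    sum(de$FDR < 0.01), "significant at FDR < 0.01.\n")
cat("Signature groups:\n")
print(table(groups$group))
top <- de[order(de$pValue), ][1:5, c("feature", "log2FC", "log2CPM",
                                     "pValue", "FDR")]
cat("Top differential miRNAs:\n")
print(top, row.names = FALSE, digits = 3)
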