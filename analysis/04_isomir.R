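#!/usr/bin/env Rscript
# Stage 4: isomiR analysis. Summarizes the per-read isomiR calls (made
# during annotation) into per-miRNA dominant types and group-level
# distributions, restricted to miRNAs passing the media filter, and reports
# the fraction of miRNA reads carrying any variation.

suppressPackageStartupMessages(library(evsmallrna))

out <- "results/isomir"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

annotation <- read.delim("results/annotation/annotation.tsv")
meta <- read.delim("results/simulation/samples.tsv")
flt <- read.delim("results/quantify/filter_report_mirna.tsv")
keep <- flt$feature[flt$detected & flt$passed_media]

calls <- annotation[annotation$stage == "MIRNA", ]
calls$mirna <- calls$detail
calls$group <- meta$group[match(calls$sample, meta$sample)]
write.table(calls[, c("read_id", "sample", "mirna", "d5", "d3", "sub_pos",
                      "category")],
            file.path(out, "isomir_calls.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

for (g in unique(meta$group[meta$type == "EV"])) {
  sub <- calls[calls$group == g &
                 calls$sample %in% meta$sample[meta$type == "EV"], ]
  dom <- isomir_dominance(sub, mirnas = keep)
  write.table(dom$per_mirna, file.path(out, paste0("dominance_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%s: %d miRNAs summarized; %.0f%% canonical-dominant, %.0f%% 3'-dominant; %.0f%% of miRNA reads carry variation.\n",
    g, nrow(dom$per_mirna), 100 * dom$distribution[["CANONICAL"]],
    100 * dom$distribution[["THREE_PRIME"]],
    100 * dom$variant_read_fraction))
}
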