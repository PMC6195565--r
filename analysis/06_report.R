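#!/usr/bin/env Rscript
# Stage 6: clustering and final exports. Unsupervised clustering of the EV
# samples on the filtered miRNA table (Euclidean distance on log2(CPM+1),
# average linkage), the media-versus-sample comparison table, and the
# machine-readable artifact bundle with its JSON manifest.

suppressPackageStartupMessages(library(evsmallrna))

out <- "results/report"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read.delim("results/simulation/samples.tsv")
ev <- meta$type == "EV"
counts <- as.matrix(read.delim("results/quantify/counts_mirna.tsv",
                               row.names = 1))
flt <- read.delim("results/quantify/filter_report_mirna.tsv")
norm <- as.matrix(read.delim("results/quantify/normalized_mirna.tsv",
                             row.names = 1))

keep <- flt$feature[flt$detected & flt$passed_media]
tree <- cluster_samples(counts[keep, meta$sample[ev]])
sep <- groups_separate(tree, setNames(meta$group[ev], meta$sample[ev]))
cluster_newick(tree, file.path(out, "cluster_mirna.nwk"))
cat("Clustered", length(keep), "filtered miRNAs across",
    sum(ev), "EV samples; groups in disjoint subtrees:", sep, "\n")

mtab <- media_comparison_table(norm, meta)
write.table(mtab, file.path(out, "media_comparison.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Media comparison covers", nrow(mtab), "feature-group rows.\n")

# assemble the artifact bundle from the staged outputs
cf <- as.matrix(read.delim("results/annotation/class_fractions.tsv",
                           row.names = 1))
run <- list(
  composition = list(class_fractions = cf,
                     length_hist = read.delim(
                       "results/annotation/length_hist.tsv")),
  de = list(mirna = read.delim("results/diffexp/de_mirna.tsv")),
  groups = read.delim("results/diffexp/groups_mirna.tsv"),
  dominance = setNames(lapply(unique(meta$group[ev]), function(g)
    list(per_mirna = read.delim(
      file.path("results/isomir", paste0("dominance_", g, ".tsv"))))),
    unique(meta$group[ev])),
  cluster = list(mirna = tree)
)
paths <- export_reports(run, file.path(out, "bundle"))
cat("Export bundle:", length(paths) - 1L, "artifacts +",
    basename(paths[["manifest"]]), "\n")
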