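#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a two-group EV small-RNA design
# (2 hPSC-like + 3 AT-MSC-like samples, one unconditioned medium per group)
# with reference sets, per-sample FASTQ reads and full ground truth.
# Outputs under results/simulation/: FASTA references, BED class intervals,
# per-sample FASTQ, ground-truth tables.

suppressPackageStartupMessages(library(evsmallrna))

out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- sim_design(seed = 1)
bundle <- make_reference_bundle(design)
stopifnot(length(validate_bundle(bundle)) == 0L)

sim <- simulate_counts(design)
reads <- emit_reads(sim, bundle, design, file.path(out, "fastq"))

write_fasta(bundle$spikeins$sequences, file.path(out, "spikeins.fa"))
write_fasta(bundle$outmap$sequences, file.path(out, "outmap.fa"))
write_fasta(bundle$mirnas$sequences, file.path(out, "mature_mirna.fa"))
write_fasta(bundle$genome$genome, file.path(out, "genome.fa"))
iv <- bundle$genome$intervals
write.table(data.frame(iv$chrom, iv$start, iv$end, iv$class, 0L, iv$strand),
            file.path(out, "classes.bed"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
# BED carries only the class label; keep the interval -> feature-name map so
# downstream truth comparisons can resolve positional interval ids
write.table(data.frame(interval_id = sprintf("%s:%s:%d-%d", iv$class,
                                             iv$chrom, iv$start, iv$end),
                       feature = iv$feature),
            file.path(out, "interval_features.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(feature = rownames(sim$counts), sim$counts),
            file.path(out, "true_counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$meta, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(reads$truth_reads, file.path(out, "truth_reads.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(feature = design$features$feature,
                       class = design$features$class,
                       media_only = design$features$media_only,
                       shared_background = design$features$shared_bg),
            file.path(out, "truth_features.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Simulated", nrow(sim$meta), "libraries (",
    sum(sim$meta$type == "EV"), "EV +", sum(sim$meta$type == "media"),
    "media );", nrow(sim$counts), "features,",
    sum(design$features$media_only), "of them media-only background.\n")
cat("Total reads emitted:",
    sum(sim$meta$depth) + sum(sim$meta$spike_total), "\n")
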