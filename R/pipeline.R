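# End-to-end driver: simulate -> (optionally) emit & annotate reads ->
# count -> filter -> test -> cluster. Count-level runs skip read emission
# and aggregate the simulated counts directly; read-level runs exercise the
# trimming/classification stages and the isomiR summaries as well.

## split simulated counts into the two class tables, mirroring what
## count_features() produces from read annotations
split_count_tables <- function(sim, design) {
  cls <- design$features$class
  spikes <- stats::setNames(as.numeric(sim$meta$spike_total),
                            sim$meta$sample)
  list(
    mirna = ev_counts(sim$counts[cls == "miRNA", , drop = FALSE],
                      sim$meta, spikes),
    ncrna = ev_counts(sim$counts[cls != "miRNA", , drop = FALSE],
                      sim$meta, spikes)
  )
}

#' Run the full analysis pipeline on a synthetic design
#'
#' @param design A [sim_design].
#' @param read_level Emit FASTQ reads and run trimming/classification
#'   (slower); otherwise aggregate the simulated counts directly.
#' @param dir Working directory for FASTQ emission (read-level runs only;
#'   a temporary directory by default).
#' @param alpha,cpm_cutoff Grouping thresholds (defaults 0.01 and 32 CPM).
#' @return List with `design`, `bundle`, `sim`, `tables` (miRNA/ncRNA
#'   [ev_counts]), `detection`, `de`, `normalized`, `media`, `groups`,
#'   `cluster`, `media_table`, and for read-level runs also `annotation`,
#'   `composition`, `dominance`, `truth_reads`, `discarded`, `raw_reads`.
#' @export
run_pipeline <- function(design, read_level = FALSE, dir = tempfile("evrun"),
                         alpha = 0.01, cpm_cutoff = 32) {
  bundle <- make_reference_bundle(design)
  issues <- validate_bundle(bundle)
  if (length(issues) > 0L)
    stop("invalid reference bundle: ", paste(issues, collapse = "; "))
  sim <- simulate_counts(design)
  out <- list(design = design, bundle = bundle, sim = sim)

  if (read_level) {
    em <- emit_reads(sim, bundle, design, dir)
    ann <- list(); disc <- integer(0); raw <- integer(0)
    for (s in names(em$fastq)) {
      a <- annotate_sample(em$fastq[s], bundle, sample = s,
                           min_len = design$min_len)
      ann[[s]] <- a$annotation
      disc[s] <- a$discarded
      raw[s] <- a$raw_reads
    }
    annotation <- do.call(rbind, ann)
    rownames(annotation) <- NULL
    out$annotation <- annotation
    out$discarded <- disc
    out$raw_reads <- raw
    out$composition <- composition_summary(annotation, disc)
    out$truth_reads <- em$truth_reads
    tables <- count_features(annotation, sim$meta)
  } else {
    tables <- split_count_tables(sim, design)
  }
  out$tables <- tables

  ev_cols <- sim$meta$type == "EV"
  ev_meta <- sim$meta[ev_cols, ]
  de <- list(); detection <- list(); media <- list(); normalized <- list()
  for (tb in names(tables)) {
    cm <- tables[[tb]]
    ev_counts_mat <- cm$counts[, ev_cols, drop = FALSE]
    keep_lib <- colSums(ev_counts_mat) > 0
    cpm <- cpm_matrix(ev_counts_mat)
    detection[[tb]] <- detection_filter(cpm, ev_meta)
    det_idx <- which(detection[[tb]]$detected)
    if (length(det_idx) >= 1L) {
      de[[tb]] <- de_exact(ev_counts_mat[det_idx, , drop = FALSE],
                           ev_meta$group)
    } else de[[tb]] <- NULL
    normalized[[tb]] <- spikein_normalize(cm)
    lfc <- de[[tb]]$log2FC[match(rownames(cm$counts), de[[tb]]$feature)]
    media[[tb]] <- media_filter(normalized[[tb]], sim$meta, log2fc = lfc)
  }
  out$detection <- detection
  out$de <- de
  out$normalized <- normalized
  out$media <- media

  mir_cpm <- cpm_matrix(tables$mirna$counts[, ev_cols, drop = FALSE])
  out$groups <- assign_groups(de$mirna, detection$mirna, media$mirna,
                              mir_cpm, ev_meta, alpha = alpha,
                              cpm_cutoff = cpm_cutoff)

  keep <- detection$mirna$feature[detection$mirna$detected &
    media$mirna$passed_media[match(detection$mirna$feature,
                                   media$mirna$feature)]]
  cluster_in <- tables$mirna$counts[intersect(rownames(tables$mirna$counts),
                                              keep), ev_cols, drop = FALSE]
  out$cluster <- list(
    mirna = if (nrow(cluster_in) >= 1L) cluster_samples(cluster_in) else NULL)
  out$media_table <- media_comparison_table(normalized$mirna, sim$meta)

  if (read_level) {
    calls <- out$annotation[out$annotation$stage == "MIRNA", ]
    calls$mirna <- calls$detail
    calls$group <- sim$meta$group[match(calls$sample, sim$meta$sample)]
    dom <- list()
    for (g in unique(ev_meta$group)) {
      sub <- calls[calls$group == g & calls$sample %in%
                     ev_meta$sample[ev_meta$group == g], ]
      keep_g <- intersect(unique(sub$mirna), keep)
      if (length(keep_g) >= 1L && nrow(sub) > 0L)
        dom[[g]] <- isomir_dominance(sub, mirnas = keep_g)
    }
    out$dominance <- dom
  }
  out
}
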