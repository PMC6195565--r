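# Count aggregation and the filtering rules of the EV pipeline: CPM with a
# detection filter (>1 CPM in >=2 samples), spike-in normalization (library
# composition of unconditioned media and EV samples cannot be assumed
# comparable), the two-fold media background filter, and assignment of
# features to group-specific / shared signatures.

#' Count matrix with sample metadata and spike-in totals
#'
#' @param counts Integer matrix, features x samples (non-negative).
#' @param meta `data.frame` with columns `sample`, `group`, `type`
#'   (`"EV"` or `"media"`), one row per column of `counts`.
#' @param spike_totals Named numeric vector of per-sample spike-in read
#'   totals (same samples as `counts`).
#' @return An `ev_counts` object.
#' @export
ev_counts <- function(counts, meta, spike_totals = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  stopifnot(all(c("sample", "group", "type") %in% names(meta)),
            nrow(meta) == ncol(counts))
  if (is.null(colnames(counts))) colnames(counts) <- meta$sample
  stopifnot(identical(colnames(counts), meta$sample))
  if (!is.null(spike_totals)) {
    spike_totals <- spike_totals[meta$sample]
    if (any(is.na(spike_totals)))
      stop("spike totals missing for some samples")
  }
  structure(list(counts = counts, meta = meta, spike_totals = spike_totals,
                 lib_sizes = colSums(counts)),
            class = "ev_counts")
}

#' Aggregate classified reads into per-class count tables
#'
#' Builds one count table for miRNAs (counted by mature miRNA name) and one
#' for the other small-RNA classes (counted by interval feature id; genome
#' reads not assigned to any class interval are dropped from the tables).
#' Spike-in totals are taken from the SPIKE_IN stage.
#'
#' @param annotation Classification `data.frame` with a `sample` column.
#' @param meta Sample metadata (`sample`, `group`, `type`).
#' @return List with `mirna` and `ncrna` [ev_counts] objects.
#' @export
count_features <- function(annotation, meta) {
  stopifnot("sample" %in% names(annotation))
  samples <- meta$sample
  tab_for <- function(sub) {
    if (nrow(sub) == 0L)
      return(matrix(0L, 0L, length(samples),
                    dimnames = list(NULL, samples)))
    t3 <- table(sub$detail, factor(sub$sample, levels = samples))
    m <- matrix(as.integer(t3), nrow(t3), ncol(t3),
                dimnames = dimnames(t3))
    m
  }
  mir <- tab_for(annotation[annotation$stage == "MIRNA", ])
  ncr <- tab_for(annotation[annotation$stage == "GENOME_CLASS" &
                              annotation$detail != "OTHER", ])
  spikes <- annotation[annotation$stage == "SPIKE_IN", ]
  spike_totals <- vapply(samples, function(s) sum(spikes$sample == s),
                         numeric(1))
  list(mirna = ev_counts(mir, meta, spike_totals),
       ncrna = ev_counts(ncr, meta, spike_totals))
}

#' Counts per million
#'
#' `CPM[i, j] = counts[i, j] * 1e6 / library_size[j]`, the library size
#' being the column sum of the same table (each class table is scaled
#' within itself).
#'
#' @param x An [ev_counts] object or a counts matrix.
#' @param lib_sizes Library sizes when `x` is a bare matrix.
#' @return Numeric CPM matrix.
#' @export
cpm_matrix <- function(x, lib_sizes = NULL) {
  if (inherits(x, "ev_counts")) {
    counts <- x$counts
    lib_sizes <- x$lib_sizes
  } else {
    counts <- as.matrix(x)
    if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  }
  if (any(lib_sizes <= 0)) {
    bad <- colnames(counts)[lib_sizes <= 0]
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Detection filter on CPM
#'
#' A feature is detected when its CPM exceeds `min_cpm` in at least
#' `min_samples` samples (any group). Presence within a group additionally
#' requires `min_samples` qualifying samples of that group (for a
#' two-sample group: both).
#'
#' @param cpm CPM matrix (EV samples).
#' @param meta Sample metadata restricted to the same samples.
#' @param min_cpm CPM threshold (exclusive).
#' @param min_samples Number of qualifying samples required.
#' @return `data.frame`: `feature`, `detected`, one `present_<group>`
#'   column per group.
#' @export
detection_filter <- function(cpm, meta, min_cpm = 1, min_samples = 2L) {
  stopifnot(ncol(cpm) >= 2L, nrow(meta) == ncol(cpm))
  hits <- cpm > min_cpm
  out <- data.frame(feature = rownames(cpm),
                    detected = rowSums(hits) >= min_samples,
                    stringsAsFactors = FALSE)
  for (g in unique(meta$group[meta$type == "EV"])) {
    cols <- meta$type == "EV" & meta$group == g
    out[[paste0("present_", g)]] <-
      rowSums(hits[, cols, drop = FALSE]) >= min(min_samples, sum(cols))
  }
  rownames(out) <- NULL
  out
}

#' Spike-in normalization
#'
#' Scales each sample's counts by `reference / spike_total`, the reference
#' being the geometric mean of spike-in totals over all samples and media,
#' so the factor is symmetric and scale-free. Doubling a sample's counts
#' and spike total leaves its normalized values unchanged.
#'
#' @param x An [ev_counts] object with spike totals, or a counts matrix.
#' @param spike_totals Per-sample spike totals when `x` is a bare matrix.
#' @return Numeric matrix of spike-in normalized counts.
#' @export
spikein_normalize <- function(x, spike_totals = NULL) {
  if (inherits(x, "ev_counts")) {
    counts <- x$counts
    spike_totals <- x$spike_totals
  } else counts <- as.matrix(x)
  if (is.null(spike_totals)) stop("spike-in totals required")
  if (any(spike_totals <= 0)) {
    bad <- colnames(counts)[spike_totals <= 0]
    stop("zero spike-in total for sample(s): ", paste(bad, collapse = ", "))
  }
  reference <- exp(mean(log(spike_totals)))
  sweep(counts, 2L, reference / spike_totals, "*")
}

#' Media background filter
#'
#' Excludes features whose signal is attributable to the unconditioned
#' medium, on spike-in normalized counts. Features differentially expressed
#' between the groups (`|FC| > fc_threshold`) must exceed `fold` times their
#' own group's media level in every EV sample; features with similar
#' expression (`|FC| < fc_threshold`) must exceed `fold` times the media
#' level as a group mean, in both groups. The media level of a group is the
#' mean over that medium's replicates.
#'
#' @param normalized Spike-in normalized matrix (EV and media samples).
#' @param meta Sample metadata for the columns of `normalized`.
#' @param log2fc Optional per-feature log2 fold change
#'   (second group over first); computed from normalized group means when
#'   omitted.
#' @param fold Required sample-to-media fold (default 2).
#' @param fc_threshold Fold-change threshold separating the two rules.
#' @param each_sample_shared Apply the per-sample rule also to shared
#'   features (the stricter reading of the shared-feature clause).
#' @return `data.frame`: `feature`, `passed_media`, `log2fc` used.
#' @export
media_filter <- function(normalized, meta, log2fc = NULL, fold = 2,
                         fc_threshold = 2, each_sample_shared = FALSE) {
  groups <- unique(meta$group[meta$type == "EV"])
  stopifnot(length(groups) == 2L)
  media_cols <- lapply(groups, function(g)
    which(meta$type == "media" & meta$group == g))
  names(media_cols) <- groups
  if (any(lengths(media_cols) == 0L))
    stop("missing media sample for group: ",
         paste(groups[lengths(media_cols) == 0L], collapse = ", "))
  ev_cols <- lapply(groups, function(g)
    which(meta$type == "EV" & meta$group == g))
  names(ev_cols) <- groups

  media_level <- vapply(groups, function(g)
    rowMeans(normalized[, media_cols[[g]], drop = FALSE]),
    numeric(nrow(normalized)))
  group_mean <- vapply(groups, function(g)
    rowMeans(normalized[, ev_cols[[g]], drop = FALSE]),
    numeric(nrow(normalized)))
  eps <- 1e-8
  lfc_norm <- log2((group_mean[, 2] + eps) / (group_mean[, 1] + eps))
  if (is.null(log2fc)) log2fc <- lfc_norm
  log2fc[is.na(log2fc)] <- lfc_norm[is.na(log2fc)]  # features without a test
  overexpressed <- abs(log2fc) >= log2(fc_threshold)

  passed <- logical(nrow(normalized))
  for (i in seq_len(nrow(normalized))) {
    if (overexpressed[i] || each_sample_shared) {
      ok <- TRUE
      for (g in groups) {
        need <- fold * media_level[i, g]
        if (any(normalized[i, ev_cols[[g]]] < need)) ok <- FALSE
      }
    } else {
      ok <- all(group_mean[i, ] >= fold * media_level[i, ])
    }
    # a feature with zero signal everywhere carries no evidence of EV origin
    if (all(group_mean[i, ] == 0)) ok <- FALSE
    passed[i] <- ok
  }
  data.frame(feature = rownames(normalized), passed_media = passed,
             log2fc = as.numeric(log2fc), stringsAsFactors = FALSE)
}

#' Assign features to signature groups
#'
#' Combines detection, media filtering and differential expression into the
#' published grouping rule: a feature present in exactly one group with
#' significant differential expression (`p < alpha`) and mean CPM of at
#' least `cpm_cutoff` over the expressing group's samples is exclusive to
#' that group; a feature present in both groups is likewise assigned to the
#' group it is enriched in when `p < alpha`, or called `shared` when
#' `|FC| < fc_threshold` and `p >= alpha`; everything else (including
#' features failing detection, the media filter, or the CPM cutoff) is
#' `excluded`.
#'
#' @param de `data.frame` with columns `feature`, `log2FC`, `pValue`
#'   (log2FC of second group over first).
#' @param detection Output of [detection_filter()].
#' @param media Output of [media_filter()].
#' @param cpm CPM matrix over EV samples.
#' @param meta Metadata for the columns of `cpm`.
#' @param alpha Significance level (default 0.01).
#' @param cpm_cutoff Mean-CPM cutoff (default 32).
#' @param fc_threshold Fold-change bound for `shared` (default 2).
#' @return `data.frame`: `feature`, `group` (one of `<g1>_only`,
#'   `<g2>_only`, `shared`, `excluded`), `mean_cpm`.
#' @export
assign_groups <- function(de, detection, media, cpm, meta, alpha = 0.01,
                          cpm_cutoff = 32, fc_threshold = 2) {
  groups <- unique(meta$group[meta$type == "EV"])
  stopifnot(length(groups) == 2L)
  features <- de$feature
  det <- detection[match(features, detection$feature), ]
  med <- media[match(features, media$feature), ]
  pres <- cbind(det[[paste0("present_", groups[1])]],
                det[[paste0("present_", groups[2])]])
  ev_cols <- lapply(groups, function(g)
    which(meta$type == "EV" & meta$group == g))

  label <- character(length(features))
  mean_cpm <- numeric(length(features))
  for (i in seq_along(features)) {
    f <- features[i]
    ridx <- match(f, rownames(cpm))
    expressed <- which(pres[i, ])
    cols <- if (length(expressed) == 0L) unlist(ev_cols)
            else unlist(ev_cols[expressed])
    mean_cpm[i] <- mean(cpm[ridx, cols])
    if (!isTRUE(det$detected[i]) || !isTRUE(med$passed_media[i]) ||
        mean_cpm[i] < cpm_cutoff) {
      label[i] <- "excluded"
      next
    }
    p <- de$pValue[i]; lfc <- de$log2FC[i]
    if (length(expressed) == 1L) {
      label[i] <- if (p < alpha) paste0(groups[expressed], "_only")
                  else "excluded"
    } else if (p < alpha) {
      label[i] <- paste0(groups[if (lfc > 0) 2L else 1L], "_only")
    } else if (abs(lfc) < log2(fc_threshold)) {
      label[i] <- "shared"
    } else {
      label[i] <- "excluded"
    }
  }
  data.frame(feature = features, group = label, mean_cpm = mean_cpm,
             stringsAsFactors = FALSE)
}
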