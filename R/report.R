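# Figure-level summaries: unsupervised sample clustering (Euclidean
# distance on log2(CPM+1), average linkage), the media-versus-sample
# comparison table, and machine-readable exports.

#' Cluster samples by expression profile
#'
#' Agglomerative clustering of samples with Euclidean distance and average
#' (UPGMA) linkage, on `log2(CPM + 1)` of a pre-filtered count matrix (the
#' transform used for count heatmaps). Deterministic; ties are resolved by
#' smallest leaf index (the behaviour of [stats::hclust()]).
#'
#' @param counts Feature x sample count matrix (pre-filtered).
#' @param transform `"log2cpm"` (default) or `"none"` (cluster the matrix
#'   as supplied).
#' @return An `ev_cluster_tree`: list with the `hclust` object, `merge`,
#'   `height`, `order` and `labels`.
#' @export
cluster_samples <- function(counts, transform = c("log2cpm", "none")) {
  transform <- match.arg(transform)
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("clustering needs at least 2 samples")
  x <- if (transform == "log2cpm") log2(cpm_matrix(counts) + 1) else counts
  hc <- stats::hclust(stats::dist(t(x), method = "euclidean"),
                      method = "average")
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels),
            class = "ev_cluster_tree")
}

#' Serialize a cluster tree as Newick
#'
#' Branch lengths are height differences (ultrametric dendrogram).
#'
#' @param tree An `ev_cluster_tree` from [cluster_samples()].
#' @param path Optional output path; when given the Newick string is also
#'   written there.
#' @return Newick string, invisibly when `path` is given.
#' @export
cluster_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ev_cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Do two sample groups occupy disjoint subtrees?
#'
#' Cuts the dendrogram into two clusters and checks they coincide with the
#' group labels (up to label swapping) -- the qualitative "groups cluster
#' separately" readout.
#'
#' @param tree An `ev_cluster_tree`.
#' @param groups Named vector: group per sample label.
#' @return Logical.
#' @export
groups_separate <- function(tree, groups) {
  stopifnot(inherits(tree, "ev_cluster_tree"))
  ct <- stats::cutree(tree$hclust, k = 2L)
  g <- as.character(groups[names(ct)])
  length(unique(paste(ct, g))) == 2L
}

#' Media versus sample comparison table
#'
#' For each group's medium: the `k` features with the highest spike-in
#' normalized media counts, alongside the mean and min-max range of the
#' normalized counts in that group's EV samples.
#'
#' @param normalized Spike-in normalized matrix (EV and media columns).
#' @param meta Sample metadata for the columns.
#' @param k Number of top media features per group (default 38).
#' @return `data.frame`: `group`, `feature`, `media`, `sample_mean`,
#'   `sample_min`, `sample_max`, ordered by decreasing media signal within
#'   group. Empty (with a warning) for an all-zero medium.
#' @export
media_comparison_table <- function(normalized, meta, k = 38L) {
  groups <- unique(meta$group[meta$type == "EV"])
  out <- list()
  for (g in groups) {
    m_col <- which(meta$type == "media" & meta$group == g)
    e_col <- which(meta$type == "EV" & meta$group == g)
    med <- rowMeans(normalized[, m_col, drop = FALSE])
    if (all(med == 0)) {
      warning("medium for group ", g, " has no normalized signal")
      next
    }
    top <- order(med, decreasing = TRUE)[seq_len(min(k, sum(med > 0)))]
    ev <- normalized[top, e_col, drop = FALSE]
    out[[g]] <- data.frame(
      group = g, feature = rownames(normalized)[top], media = med[top],
      sample_mean = rowMeans(ev), sample_min = apply(ev, 1L, min),
      sample_max = apply(ev, 1L, max), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(group = character(0), feature = character(0),
                      media = numeric(0), sample_mean = numeric(0),
                      sample_min = numeric(0), sample_max = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Export a pipeline run as a TSV/JSON bundle
#'
#' Writes the composition, length-histogram, differential-expression,
#' grouping and isomiR dominance tables plus the sample dendrogram (Newick)
#' and a JSON manifest listing every artifact.
#'
#' @param run Result of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of artifact paths, invisibly.
#' @export
export_reports <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  need <- c("composition", "de", "groups", "cluster")
  missing <- setdiff(need, names(run)[!vapply(run, is.null, logical(1))])
  if (length(missing) > 0L)
    stop("missing upstream stage output(s): ", paste(missing, collapse = ", "))
  paths <- c(
    composition = write_tsv(
      data.frame(sample = rownames(run$composition$class_fractions),
                 run$composition$class_fractions, check.names = FALSE),
      file.path(dir, "composition.tsv")),
    lengths = write_tsv(run$composition$length_hist,
                        file.path(dir, "length_hist.tsv")),
    de = write_tsv(run$de$mirna, file.path(dir, "de_mirna.tsv")),
    groups = write_tsv(run$groups, file.path(dir, "groups.tsv")),
    dominance = if (!is.null(run$dominance)) {
      write_tsv(do.call(rbind, lapply(names(run$dominance), function(g)
        data.frame(group = g, run$dominance[[g]]$per_mirna))),
        file.path(dir, "isomir_dominance.tsv"))
    } else NA_character_,
    cluster = {
      cluster_newick(run$cluster$mirna, file.path(dir, "cluster_mirna.nwk"))
      file.path(dir, "cluster_mirna.nwk")
    }
  )
  paths <- paths[!is.na(paths)]
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(artifacts = as.list(basename(paths))),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = manifest))
}
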