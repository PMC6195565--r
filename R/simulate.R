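# Synthetic-data generator. Emulates a two-group EV small-RNA study:
# a miRNA-poor / tRNA-rich pluripotent-stem-cell (hPSC) group of 2 samples
# and a miRNA-rich mesenchymal (AT-MSC) group of 3 samples, one unconditioned
# medium per group, negative-binomial feature counts, isomiR read variation,
# spike-in reads at known per-sample totals, and medium-derived background
# features that leak into the conditioned samples.

ISOMIR_CATEGORIES <- c("CANONICAL", "FIVE_PRIME", "THREE_PRIME", "BOTH_ENDS",
                       "SUBSTITUTION_SEED", "SUBSTITUTION_NONSEED", "MIXED")

# Default 3' adapter (NEBNext-style small RNA 3' adapter prefix).
DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

#' Default per-miRNA isomiR edit-type profiles
#'
#' Three archetypes of per-miRNA isomiR composition: miRNAs dominated by the
#' canonical sequence, by 3' variants (the commonest biological mode), or by
#' 5' variants (rare, but reported for individual miRNAs). Each row is a
#' probability vector over the isomiR categories.
#'
#' @return Named list of probability vectors.
#' @export
default_isomir_archetypes <- function() {
  list(
    canonical_dominant = c(CANONICAL = 0.40, FIVE_PRIME = 0.07,
                           THREE_PRIME = 0.28, BOTH_ENDS = 0.08,
                           SUBSTITUTION_SEED = 0.03,
                           SUBSTITUTION_NONSEED = 0.07, MIXED = 0.07),
    three_prime_dominant = c(CANONICAL = 0.18, FIVE_PRIME = 0.07,
                             THREE_PRIME = 0.48, BOTH_ENDS = 0.10,
                             SUBSTITUTION_SEED = 0.03,
                             SUBSTITUTION_NONSEED = 0.07, MIXED = 0.07),
    five_prime_dominant = c(CANONICAL = 0.15, FIVE_PRIME = 0.45,
                            THREE_PRIME = 0.18, BOTH_ENDS = 0.08,
                            SUBSTITUTION_SEED = 0.03,
                            SUBSTITUTION_NONSEED = 0.06, MIXED = 0.05)
  )
}

#' Default group-wise mixing over isomiR archetypes
#'
#' Fractions of miRNAs per archetype in each group, emulating a design where
#' most pluripotent-group miRNAs are canonical-dominant while most
#' mesenchymal-group miRNAs are 3'-variant-dominant.
#'
#' @return Named list (one element per group) of archetype fractions.
#' @export
default_archetype_mix <- function() {
  list(
    hPSC = c(canonical_dominant = 0.66, three_prime_dominant = 0.29,
             five_prime_dominant = 0.05),
    ATMSC = c(canonical_dominant = 0.34, three_prime_dominant = 0.53,
              five_prime_dominant = 0.13)
  )
}

default_class_composition <- function() {
  rbind(
    hPSC = c(miRNA = 0.13, tRNA = 0.69, Y_RNA = 0.07, snRNA = 0.04,
             snoRNA = 0.07, piRNA = 0.00),
    ATMSC = c(miRNA = 0.44, tRNA = 0.47, Y_RNA = 0.08, snRNA = 0.005,
              snoRNA = 0.005, piRNA = 0.00)
  )
}

## independent RNG streams per stage: designs with consecutive user seeds
## must never share a stream with each other's downstream stages
derived_seed <- function(seed, k) {
  as.integer((as.double(seed) * 101 + k) %% 2147483647)
}

random_dna <- function(n, len) {
  vapply(len, function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = ""), character(1))
}

#' Simulation design for a two-group EV study
#'
#' Builds the full randomized design: the feature table (classes, per-group
#' abundances, media background structure), sample metadata (depths and
#' expected spike-in totals) and the per-miRNA isomiR archetype assignment.
#' All randomness is drawn from `seed`, so the design is reproducible.
#'
#' Abundances are constructed on a common "absolute" scale on which spike-in
#' normalized counts are comparable across samples and media: genuine
#' features sum to 1 per EV group, each group's medium carries
#' `media_rna_content` of background material, media-only features leak into
#' conditioned samples at `leak_fraction` of their media level, and shared
#' background features are `shared_enrichment`-fold higher in EV samples
#' than in the medium.
#'
#' @param seed Integer RNG seed.
#' @param groups Named integer vector: samples per group (two groups).
#' @param depths Named integer vector: non-spike reads per EV sample, per group.
#' @param media_depths Named integer vector: non-spike reads per medium.
#' @param n_mirna,n_other Number of genuine miRNA / other small-RNA features.
#' @param phi Negative-binomial dispersion (Var = mu + phi * mu^2); scalar or
#'   per-feature vector.
#' @param class_composition Matrix (group x class) of small-RNA class
#'   fractions per group; rows must sum to 1.
#' @param n_media_only,n_shared_bg Number of media-only background features
#'   and of genuine features that also occur in the media.
#' @param leak_fraction Fraction of a media-only feature's media level seen
#'   in conditioned samples (carry-over), in [0, 1).
#' @param shared_enrichment EV-to-media abundance ratio of shared background
#'   features (> 2 so the media filter retains them by design).
#' @param media_rna_content Named vector: total background abundance of each
#'   group's medium relative to the EV samples' total of 1.
#' @param spike_frac Expected spike-in reads as a fraction of non-spike reads
#'   in a library with unit total abundance.
#' @param n_spikein Number of spike-in species.
#' @param mirna_len Length 2 vector: mature miRNA length range (nt).
#' @param isomir_archetypes Named list of isomiR category probability vectors.
#' @param archetype_mix Named list (per group) of archetype fractions.
#' @param min_len Minimum read length (nt) after trimming.
#' @return A `sim_design` object.
#' @export
sim_design <- function(seed = 1L,
                       groups = c(hPSC = 2L, ATMSC = 3L),
                       depths = c(hPSC = 30000L, ATMSC = 12000L),
                       media_depths = c(hPSC = 4000L, ATMSC = 13000L),
                       n_mirna = 40L, n_other = 30L,
                       phi = 0.2,
                       class_composition = default_class_composition(),
                       n_media_only = 10L, n_shared_bg = 6L,
                       leak_fraction = 0.3,
                       shared_enrichment = 8,
                       media_rna_content = c(hPSC = 0.05, ATMSC = 0.4),
                       spike_frac = 0.1,
                       n_spikein = 52L,
                       mirna_len = c(18L, 25L),
                       isomir_archetypes = default_isomir_archetypes(),
                       archetype_mix = default_archetype_mix(),
                       min_len = 15L) {
  stopifnot(length(groups) == 2L, !is.null(names(groups)),
            all(groups >= 1L), n_mirna >= 2L, n_other >= 1L,
            all(depths > 0), all(media_depths > 0), all(phi >= 0),
            leak_fraction >= 0, leak_fraction < 1, shared_enrichment > 2,
            spike_frac > 0)
  gnames <- names(groups)
  if (!identical(sort(rownames(class_composition)), sort(gnames)))
    stop("class_composition rows must match group names")
  if (any(abs(rowSums(class_composition) - 1) > 1e-9))
    stop("class composition must sum to 1 per group")
  for (g in gnames) {
    p <- archetype_mix[[g]]
    if (abs(sum(p) - 1) > 1e-9) stop("archetype mix must sum to 1 for ", g)
    if (!all(names(p) %in% names(isomir_archetypes)))
      stop("unknown archetype in mix for ", g)
  }
  for (a in isomir_archetypes) {
    if (abs(sum(a) - 1) > 1e-9 || !identical(sort(names(a)),
                                             sort(ISOMIR_CATEGORIES)))
      stop("each isomiR archetype must be a probability vector over the ",
           "category set")
  }

  set.seed(derived_seed(seed, 0L))
  classes <- colnames(class_composition)
  other_classes <- setdiff(classes, "miRNA")

  ## --- genuine features ------------------------------------------------
  mirna_names <- sprintf("mir-%03d", seq_len(n_mirna))
  # allocate non-miRNA features to classes proportionally to mean composition
  mean_comp <- colMeans(class_composition[, other_classes, drop = FALSE])
  alloc <- pmax(round(n_other * mean_comp / sum(mean_comp)), 1L)
  while (sum(alloc) > n_other) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_other) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1L
  other_class <- rep(names(alloc), alloc)
  other_names <- unlist(lapply(names(alloc), function(cl)
    sprintf("%s-%03d", cl, seq_len(alloc[cl]))), use.names = FALSE)

  features <- data.frame(
    feature = c(mirna_names, other_names),
    class = c(rep("miRNA", n_mirna), other_class),
    media_only = FALSE, shared_bg = FALSE,
    stringsAsFactors = FALSE
  )

  ## per-group genuine abundances: class budget split by lognormal weights
  A <- matrix(0, nrow(features), length(gnames),
              dimnames = list(features$feature, gnames))
  for (g in gnames) {
    for (cl in classes) {
      idx <- which(features$class == cl)
      if (length(idx) == 0L) next
      budget <- class_composition[g, cl]
      if (budget <= 0) next
      w <- stats::rlnorm(length(idx), 0, 1)
      A[idx, g] <- budget * w / sum(w)
    }
  }

  ## --- media background -------------------------------------------------
  # shared background: genuine features also present in the media
  shared_idx <- integer(0)
  if (n_shared_bg > 0L) {
    sh_mir <- sample(seq_len(n_mirna), min(ceiling(n_shared_bg / 2), n_mirna))
    sh_oth <- sample(n_mirna + seq_along(other_names),
                     n_shared_bg - length(sh_mir))
    shared_idx <- c(sh_mir, sh_oth)
    features$shared_bg[shared_idx] <- TRUE
  }
  # media-only features (e.g. serum-derived RNA): half miRNA, half other
  mo_mir <- ceiling(n_media_only / 2)
  mo_names <- c(sprintf("media-mir-%03d", seq_len(mo_mir)),
                sprintf("media-frag-%03d", seq_len(n_media_only - mo_mir)))
  mo_class <- c(rep("miRNA", mo_mir),
                sample(other_classes[1:2], n_media_only - mo_mir, replace = TRUE))
  if (n_media_only > 0L) {
    features <- rbind(features, data.frame(
      feature = mo_names, class = mo_class,
      media_only = TRUE, shared_bg = FALSE, stringsAsFactors = FALSE))
    A <- rbind(A, matrix(0, n_media_only, length(gnames),
                         dimnames = list(mo_names, gnames)))
  }

  ## media abundance per group
  M <- matrix(0, nrow(features), length(gnames),
              dimnames = list(features$feature, gnames))
  for (g in gnames) {
    if (n_media_only > 0L) {
      v <- stats::rlnorm(n_media_only, 0, 0.7)
      M[mo_names, g] <- media_rna_content[g] * v / sum(v)
    }
    if (length(shared_idx) > 0L)
      M[shared_idx, g] <- A[shared_idx, g] / shared_enrichment
  }
  # leak of media-only features into conditioned samples
  if (n_media_only > 0L) {
    for (g in gnames) A[mo_names, g] <- leak_fraction * M[mo_names, g]
  }

  ## --- samples ----------------------------------------------------------
  meta <- data.frame(
    sample = c(unlist(lapply(gnames, function(g)
      sprintf("%s_%d", g, seq_len(groups[g])))),
      sprintf("media_%s", gnames)),
    group = c(rep(gnames, groups), gnames),
    type = c(rep("EV", sum(groups)), rep("media", length(gnames))),
    stringsAsFactors = FALSE
  )
  meta$depth <- ifelse(meta$type == "EV", depths[meta$group],
                       media_depths[meta$group])
  total_ab <- vapply(seq_len(nrow(meta)), function(i) {
    src <- if (meta$type[i] == "EV") A else M
    sum(src[, meta$group[i]])
  }, numeric(1))
  meta$spike_total <- as.integer(round(meta$depth * spike_frac / total_ab))

  ## --- isomiR archetypes & spike species weights ------------------------
  all_mirna <- features$feature[features$class == "miRNA"]
  arch <- vapply(gnames, function(g)
    sample(names(archetype_mix[[g]]), length(all_mirna), replace = TRUE,
           prob = archetype_mix[[g]]), character(length(all_mirna)))
  dimnames(arch) <- list(all_mirna, gnames)

  spike_names <- sprintf("UniSp%d", 99L + seq_len(n_spikein))
  spike_weights <- stats::rlnorm(n_spikein, 0, 0.5)
  spike_weights <- spike_weights / sum(spike_weights)
  names(spike_weights) <- spike_names

  structure(list(
    seed = seed, groups = groups, meta = meta, features = features,
    abundance = A, media_abundance = M, phi = phi,
    class_composition = class_composition,
    leak_fraction = leak_fraction, shared_enrichment = shared_enrichment,
    spike_frac = spike_frac, spike_weights = spike_weights,
    mirna_len = as.integer(mirna_len), min_len = as.integer(min_len),
    isomir_archetypes = isomir_archetypes, archetype_mix = archetype_mix,
    archetype = arch
  ), class = "sim_design")
}

#' Draw negative-binomial counts
#'
#' Counts with `Var = mu + phi * mu^2` (the dispersion convention of the
#' downstream exact test); `phi = 0` degenerates to Poisson.
#'
#' @param mu Vector of means.
#' @param phi Dispersion, scalar or vector recycled against `mu`.
#' @return Integer vector of counts.
#' @export
rnb_counts <- function(mu, phi = 0) {
  stopifnot(all(mu >= 0), all(phi >= 0))
  phi <- rep_len(phi, length(mu))
  out <- integer(length(mu))
  pois <- phi < 1e-12
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois),
                                               size = 1 / phi[!pois],
                                               mu = mu[!pois])
  as.integer(out)
}

#' Simulate feature counts for a design
#'
#' For each sample, feature counts are drawn negative-binomially with mean
#' `depth * pi_f` (where `pi` is the sample's composition) and dispersion
#' `phi`, then conditioned on the sample's total so that every library sums
#' exactly to its design depth (the sequencer fixes the number of reads, not
#' the number of molecules). Spike-in totals are taken from the design.
#'
#' @param design A [sim_design].
#' @return List with `counts` (features x samples integer matrix over all EV
#'   and media samples), `meta` (sample metadata incl. spike totals) and
#'   `truth` (per-feature ground truth: abundances, media flags, true group
#'   log2 fold changes).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(derived_seed(design$seed, 1L))
  meta <- design$meta
  nf <- nrow(design$features)
  counts <- matrix(0L, nf, nrow(meta),
                   dimnames = list(design$features$feature, meta$sample))
  for (i in seq_len(nrow(meta))) {
    src <- if (meta$type[i] == "EV") design$abundance else design$media_abundance
    ab <- src[, meta$group[i]]
    if (sum(ab) <= 0) next
    pi_j <- ab / sum(ab)
    y <- rnb_counts(meta$depth[i] * pi_j, design$phi)
    if (sum(y) == 0) y <- pi_j  # degenerate library; fall back to expectation
    counts[, i] <- as.integer(stats::rmultinom(1, meta$depth[i], prob = y))
  }
  gnames <- names(design$groups)
  truth <- list(
    abundance = design$abundance,
    media_abundance = design$media_abundance,
    media_only = design$features$media_only,
    shared_bg = design$features$shared_bg,
    class = design$features$class,
    true_log2fc = log2(design$abundance[, gnames[2]] /
                         design$abundance[, gnames[1]])
  )
  list(counts = counts, meta = meta, truth = truth)
}

#' Generate a reference bundle matching a design
#'
#' Random, collision-checked sequences for every feature in the design:
#' spike-ins, an outmap set (adapter, rRNA, phiX and mitochondrial
#' fragments), mature miRNAs (family labels assigned in blocks) and a
#' mini-genome in which every non-miRNA feature is an annotated class
#' interval separated by random spacers. Deterministic given the design seed.
#'
#' @param design A [sim_design].
#' @return A [reference_bundle].
#' @export
make_reference_bundle <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(derived_seed(design$seed, 2L))
  feats <- design$features
  mirna_idx <- which(feats$class == "miRNA")
  other_idx <- which(feats$class != "miRNA")

  lens <- sample(seq(design$mirna_len[1], design$mirna_len[2]),
                 length(mirna_idx), replace = TRUE)
  mir_seq <- random_dna(length(mirna_idx), lens)
  spike_seq <- random_dna(length(design$spike_weights),
                          sample(20:24, length(design$spike_weights), TRUE))
  out_seq <- c(ADAPTER = DEFAULT_ADAPTER,
               rRNA_28S = random_dna(1, 160), rRNA_18S = random_dna(1, 150),
               rRNA_5.8S = random_dna(1, 120), PhiX = random_dna(1, 150),
               MT = random_dna(1, 150))
  out_cat <- c("ADAPTER", "rRNA", "rRNA", "rRNA", "PHIX", "MITO")

  frag_len <- function(cl) switch(cl, tRNA = 72L, Y_RNA = 100L, snRNA = 150L,
                                  snoRNA = 130L, piRNA = 30L, 80L)
  other_seq <- random_dna(length(other_idx),
                          vapply(feats$class[other_idx], frag_len, integer(1)))

  # collision checks: no miRNA may occur inside any other reference, or the
  # staged classifier's ground truth would be ambiguous
  haystack <- c(spike_seq, out_seq, other_seq)
  for (attempt in 1:50) {
    hit <- vapply(mir_seq, function(s)
      any(vapply(haystack, function(h) grepl(s, h, fixed = TRUE), logical(1))),
      logical(1))
    dup <- duplicated(mir_seq) | hit
    if (!any(dup)) break
    mir_seq[dup] <- random_dna(sum(dup), nchar(mir_seq[dup]))
  }
  if (anyDuplicated(c(mir_seq, haystack)))
    stop("could not generate collision-free reference sequences")

  names(mir_seq) <- feats$feature[mirna_idx]
  family <- sprintf("fam-%02d", ceiling(seq_along(mir_seq) / 4))

  # mini-genome: intervals separated by random spacers, one chromosome
  spacers <- random_dna(length(other_idx) + 1L,
                        sample(20:50, length(other_idx) + 1L, TRUE))
  pieces <- character(2 * length(other_idx) + 1L)
  pieces[seq(1, length(pieces), by = 2)] <- spacers
  pieces[seq(2, length(pieces), by = 2)] <- other_seq
  chrom <- paste(pieces, collapse = "")
  starts <- cumsum(nchar(pieces)) - nchar(pieces)  # 0-based piece starts
  iv_start <- starts[seq(2, length(pieces), by = 2)]
  intervals <- data.frame(
    chrom = "chr1", start = iv_start, end = iv_start + nchar(other_seq),
    class = feats$class[other_idx], strand = "+",
    feature = feats$feature[other_idx], stringsAsFactors = FALSE
  )

  names(spike_seq) <- names(design$spike_weights)
  reference_bundle(
    spikeins = spikein_set(spike_seq),
    outmap = outmap_set(out_seq, out_cat),
    mirnas = mature_mirna_set(mir_seq, family = family),
    genome = genome_annotation(c(chr1 = chrom), intervals)
  )
}

## sample one concrete edit of the requested category for a canonical
sample_edit <- function(canonical, category, seed_span, min_len,
                        max5 = 2L, max3 = 4L) {
  L <- nchar(canonical)
  trim5_max <- min(max5, L - min_len)
  trim3_max <- min(max3, L - min_len)
  d5s <- c(if (trim5_max >= 1) -(1:trim5_max), 1:max5)
  d3s <- c(if (trim3_max >= 1) -(1:trim3_max), 1:max3)
  pick <- function(x) x[sample.int(length(x), 1L)]
  d5 <- 0L; d3 <- 0L; sub_pos <- NA_integer_; sub_to <- NA_character_
  if (category == "FIVE_PRIME") d5 <- pick(d5s)
  if (category == "THREE_PRIME") d3 <- pick(d3s)
  if (category == "BOTH_ENDS") {
    repeat {
      d5 <- pick(d5s); d3 <- pick(d3s)
      if (L + d5 + d3 >= min_len) break
    }
  }
  if (category %in% c("SUBSTITUTION_SEED", "SUBSTITUTION_NONSEED", "MIXED")) {
    if (category == "MIXED") {
      repeat {
        if (stats::runif(1) < 0.5) { d5 <- pick(d5s); d3 <- 0L }
        else { d5 <- 0L; d3 <- pick(d3s) }
        if (L + d5 + d3 >= min_len) break
      }
    }
    a <- max(0L, -d5); b <- max(0L, -d3)
    core_pos <- seq.int(a + 1L, L - b)  # canonical positions retained
    cand <- if (category == "SUBSTITUTION_SEED")
      intersect(core_pos, seq.int(seed_span[1], seed_span[2]))
    else if (category == "SUBSTITUTION_NONSEED")
      setdiff(core_pos, seq.int(seed_span[1], seed_span[2]))
    else core_pos
    sub_pos <- pick(cand)
    from <- substr(canonical, sub_pos, sub_pos)
    sub_to <- pick(setdiff(c("A", "C", "G", "T"), from))
  }
  ext5 <- if (d5 > 0) paste(sample(c("A", "C", "G", "T"), d5, TRUE),
                            collapse = "") else ""
  ext3 <- if (d3 > 0) paste(sample(c("A", "T"), d3, TRUE),
                            collapse = "") else ""
  list(d5 = as.integer(d5), d3 = as.integer(d3), sub_pos = sub_pos,
       sub_to = sub_to, ext5 = ext5, ext3 = ext3)
}

#' Emit per-sample FASTQ reads with ground truth
#'
#' Expands simulated counts into reads: each miRNA read is its canonical
#' sequence transformed by an edit drawn from the miRNA's isomiR archetype,
#' non-miRNA reads are random substrings of their reference interval,
#' spike-in reads are exact copies, and media libraries contain only
#' background features. Inserts are emitted as fixed-cycle raw reads
#' (insert + 3' adapter, truncated/padded to `cycles`) with constant
#' quality, so the adapter trimmer is exercised.
#'
#' @param sim Result of [simulate_counts()].
#' @param bundle Matching [make_reference_bundle()] output.
#' @param design The [sim_design].
#' @param dir Output directory for `<sample>.fastq` files.
#' @param cycles Sequencing cycles (raw read length).
#' @return List with `fastq` (named paths) and `truth_reads` (one row per
#'   read: id, sample, feature, class, isomiR category and edit description).
#' @export
emit_reads <- function(sim, bundle, design, dir, cycles = 50L) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(derived_seed(design$seed, 3L))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feats <- design$features
  mirnas <- bundle$mirnas
  seed_span <- mirnas$seed_span
  iv <- bundle$genome$intervals
  iv_seq <- substring(bundle$genome$genome[iv$chrom], iv$start + 1L, iv$end)
  names(iv_seq) <- iv$feature
  adapter <- bundle$outmap$sequences[bundle$outmap$category == "ADAPTER"][1]
  pad <- strrep("G", cycles)

  fastq <- character(0)
  truth <- vector("list", nrow(sim$meta))
  for (i in seq_len(nrow(sim$meta))) {
    smp <- sim$meta$sample[i]
    grp <- sim$meta$group[i]
    cnt <- sim$counts[, i]
    ids <- character(0); seqs <- character(0)
    t_feature <- character(0); t_cat <- character(0)
    t_d5 <- integer(0); t_d3 <- integer(0); t_sub <- integer(0)
    for (f in which(cnt > 0L)) {
      n <- cnt[f]
      feat <- feats$feature[f]
      if (feats$class[f] == "miRNA") {
        canonical <- mirnas$sequences[[feat]]
        if (is.null(canonical)) stop("no reference sequence for ", feat)
        prof <- design$isomir_archetypes[[design$archetype[feat, grp]]]
        cats <- sample(names(prof), n, replace = TRUE, prob = prof)
        rd <- character(n); d5 <- integer(n); d3 <- integer(n); sp <- rep(NA_integer_, n)
        for (k in seq_len(n)) {
          if (cats[k] == "CANONICAL") {
            rd[k] <- canonical
          } else {
            e <- sample_edit(canonical, cats[k], seed_span, design$min_len)
            rd[k] <- apply_isomir_edit(canonical, e$d5, e$d3, e$sub_pos,
                                       e$sub_to, e$ext5, e$ext3)
            d5[k] <- e$d5; d3[k] <- e$d3
            sp[k] <- if (is.na(e$sub_pos)) NA_integer_ else e$sub_pos
          }
        }
        seqs <- c(seqs, rd)
        t_feature <- c(t_feature, rep(feat, n)); t_cat <- c(t_cat, cats)
        t_d5 <- c(t_d5, d5); t_d3 <- c(t_d3, d3); t_sub <- c(t_sub, sp)
      } else {
        ref <- iv_seq[[feat]]
        if (is.null(ref)) stop("no reference sequence for ", feat)
        L <- nchar(ref)
        # keep inserts short enough that >= 8 nt of adapter stay visible
        # within the fixed cycle count, so every read is trimmable
        rl <- sample(25:min(45L, L, cycles - 8L), n, replace = TRUE)
        st <- vapply(rl, function(l) sample.int(L - l + 1L, 1L), integer(1))
        seqs <- c(seqs, substring(ref, st, st + rl - 1L))
        t_feature <- c(t_feature, rep(feat, n))
        t_cat <- c(t_cat, rep(NA_character_, n))
        t_d5 <- c(t_d5, integer(n)); t_d3 <- c(t_d3, integer(n))
        t_sub <- c(t_sub, rep(NA_integer_, n))
      }
    }
    # spike-ins: exact copies at the design total
    s_tot <- sim$meta$spike_total[i]
    s_cnt <- as.integer(stats::rmultinom(1, s_tot, design$spike_weights))
    sp_seqs <- rep(bundle$spikeins$sequences, s_cnt)
    sp_feats <- rep(names(design$spike_weights), s_cnt)
    seqs <- c(seqs, sp_seqs)
    t_feature <- c(t_feature, sp_feats)
    t_cat <- c(t_cat, rep(NA_character_, length(sp_seqs)))
    t_d5 <- c(t_d5, integer(length(sp_seqs)))
    t_d3 <- c(t_d3, integer(length(sp_seqs)))
    t_sub <- c(t_sub, rep(NA_integer_, length(sp_seqs)))

    ids <- sprintf("%s_read%06d", smp, seq_along(seqs))
    raw <- substr(paste0(seqs, adapter, pad), 1L, cycles)
    path <- file.path(dir, paste0(smp, ".fastq"))
    writeLines(paste0("@", ids, "\n", raw, "\n+\n",
                      strrep("I", nchar(raw))), path)
    fastq[smp] <- path
    cls <- feats$class[match(t_feature, feats$feature)]
    cls[is.na(cls)] <- "spikein"
    truth[[i]] <- data.frame(read_id = ids, sample = smp, feature = t_feature,
                             class = cls, category = t_cat, d5 = t_d5,
                             d3 = t_d3, sub_pos = t_sub,
                             stringsAsFactors = FALSE)
  }
  list(fastq = fastq, truth_reads = do.call(rbind, truth))
}
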