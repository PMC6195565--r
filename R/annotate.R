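# Hierarchical read classification, in the strict stage order of the
# annotation pipeline: (1) spike-ins, (2) outmapped nuisance sequences
# (adapter, rRNA, phiX, mitochondrial, poly-A/C homopolymers), (3) mature
# miRNAs with isomiR tolerance, (4) genome with <=1 mismatch and class
# assignment by interval overlap; anything left is UNMAPPED. A read matching
# several stages is assigned to the earliest one. Matching replaces a
# short-read aligner with exact / 1-mismatch substring search, which the
# stage parameters (no penalties allowed in stages 1-2, one mismatch in
# stage 4) make equivalent at this reference scale.

ANNOT_STAGES <- c("SPIKE_IN", "OUTMAPPED", "MIRNA", "GENOME_CLASS", "UNMAPPED")

#' Trim the 3' adapter from raw reads
#'
#' Removes everything from the first occurrence of an adapter prefix of
#' at least 8 nt. Reads shorter than `min_len` after trimming are flagged
#' as discarded (tallied, never silently dropped).
#'
#' @param seqs Character vector of raw read sequences.
#' @param adapter 3' adapter sequence (>= 8 nt).
#' @param min_len Minimum post-trim length.
#' @return `data.frame` with columns `seq` (trimmed sequence) and `kept`.
#' @export
trim_adapter <- function(seqs, adapter = DEFAULT_ADAPTER, min_len = 15L) {
  if (nchar(adapter) < 8L) stop("adapter must be at least 8 nt")
  key <- substr(adapter, 1L, 8L)
  pos <- regexpr(key, seqs, fixed = TRUE)
  trimmed <- ifelse(pos > 0L, substr(seqs, 1L, pos - 1L), seqs)
  data.frame(seq = trimmed, kept = nchar(trimmed) >= min_len,
             stringsAsFactors = FALSE)
}

is_homopolymer <- function(seq, threshold) {
  n <- nchar(seq)
  if (n == 0L) return(FALSE)
  raw <- charToRaw(seq)
  max(sum(raw == charToRaw("A")), sum(raw == charToRaw("C"))) / n >= threshold
}

## best exact-substring hit among a set of references; ties resolved by
## longest reference, then name (logged upstream as stage-internal rule)
substring_hit <- function(read, refs) {
  hit <- vapply(refs, function(r) grepl(read, r, fixed = TRUE), logical(1))
  if (!any(hit)) return(NA_character_)
  cand <- names(refs)[hit]
  lens <- nchar(refs[hit])
  cand <- cand[lens == max(lens)]
  sort(cand)[1]
}

## genome search: exact first (plain substring search), then 1 mismatch via
## Biostrings; returns hit with 0-based half-open coordinates or NULL
genome_hit <- function(read, genome, genome_ds = NULL) {
  chroms <- sort(names(genome))
  for (chrom in chroms) {
    pos <- regexpr(read, genome[[chrom]], fixed = TRUE)
    if (pos > 0L)
      return(list(chrom = chrom, start = pos - 1L,
                  end = pos - 1L + nchar(read), mismatches = 0L))
  }
  if (is.null(genome_ds))
    genome_ds <- lapply(genome, Biostrings::DNAString)
  for (chrom in chroms) {
    m <- Biostrings::matchPattern(read, genome_ds[[chrom]], max.mismatch = 1L)
    if (length(m) > 0L) {
      st <- Biostrings::start(m)[1] - 1L
      return(list(chrom = chrom, start = st, end = st + nchar(read),
                  mismatches = 1L))
    }
  }
  NULL
}

classify_one <- function(read, bundle, max5, max3, min_len, min_overlap,
                         genome_ds = NULL) {
  # stage 1: spike-ins
  hit <- substring_hit(read, bundle$spikeins$sequences)
  if (!is.na(hit))
    return(list(stage = "SPIKE_IN", detail = hit, class = NA_character_,
                mismatches = 0L, call = NULL))
  # stage 2: outmapping (abundant nuisance sequences, homopolymers)
  hit <- substring_hit(read, bundle$outmap$sequences)
  if (!is.na(hit)) {
    cat <- bundle$outmap$category[match(hit, names(bundle$outmap$sequences))]
    return(list(stage = "OUTMAPPED", detail = cat, class = NA_character_,
                mismatches = 0L, call = NULL))
  }
  if (is_homopolymer(read, bundle$outmap$homopolymer_threshold))
    return(list(stage = "OUTMAPPED", detail = "HOMOPOLYMER",
                class = NA_character_, mismatches = 0L, call = NULL))
  # stage 3: mature miRNAs with isomiR tolerance
  call <- isomir_match(read, bundle$mirnas, max5 = max5, max3 = max3,
                       min_len = min_len)
  if (!is.null(call))
    return(list(stage = "MIRNA", detail = call$mirna, class = "miRNA",
                mismatches = if (is.na(call$sub_pos)) 0L else 1L,
                call = call))
  # stage 4: genome, <=1 mismatch, class by >=90%-of-read overlap
  g <- genome_hit(read, bundle$genome$genome, genome_ds)
  if (!is.null(g)) {
    iv <- bundle$genome$intervals
    same <- iv$chrom == g$chrom
    ov <- pmin(iv$end[same], g$end) - pmax(iv$start[same], g$start)
    cls <- "OTHER"; feat <- "OTHER"
    if (any(ov >= min_overlap * nchar(read))) {
      j <- which(same)[which.max(ov)]
      cls <- iv$class[j]; feat <- iv$feature[j]
    }
    return(list(stage = "GENOME_CLASS", detail = feat, class = cls,
                mismatches = g$mismatches, call = NULL))
  }
  list(stage = "UNMAPPED", detail = NA_character_, class = NA_character_,
       mismatches = NA_integer_, call = NULL)
}

#' Classify trimmed reads through the annotation hierarchy
#'
#' @param reads `data.frame` with columns `read_id` and `seq` (post-trim),
#'   or a character vector of sequences.
#' @param bundle A validated [reference_bundle].
#' @param max5,max3 isomiR terminal offset bounds for the miRNA stage.
#' @param min_len Minimum read length.
#' @param min_overlap Fraction of the read that must overlap a class
#'   interval for a genome hit to inherit its class.
#' @return `data.frame`: `read_id`, `seq`, `length`, `stage`, `detail`
#'   (spike-in name, outmap category, miRNA name, or interval feature id),
#'   `class`, `mismatches`, and isomiR columns (`d5`, `d3`, `sub_pos`,
#'   `category`) for MIRNA-stage reads.
#' @export
classify_reads <- function(reads, bundle, max5 = 2L, max3 = 4L,
                           min_len = 15L, min_overlap = 0.9) {
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read%06d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  uniq <- unique(reads$seq)
  genome_ds <- lapply(bundle$genome$genome, Biostrings::DNAString)
  res <- lapply(uniq, classify_one, bundle = bundle, max5 = max5,
                max3 = max3, min_len = min_len, min_overlap = min_overlap,
                genome_ds = genome_ds)
  names(res) <- uniq
  get <- function(field, default) vapply(res, function(r) {
    v <- r[[field]]
    if (is.null(v)) default else v
  }, default)
  getc <- function(field, default) vapply(res, function(r) {
    v <- r$call[[field]]
    if (is.null(v)) default else v
  }, default)
  u <- data.frame(
    seq = uniq,
    stage = get("stage", NA_character_),
    detail = get("detail", NA_character_),
    class = get("class", NA_character_),
    mismatches = get("mismatches", NA_integer_),
    d5 = getc("d5", NA_integer_), d3 = getc("d3", NA_integer_),
    sub_pos = getc("sub_pos", NA_integer_),
    category = getc("category", NA_character_),
    stringsAsFactors = FALSE
  )
  out <- u[match(reads$seq, u$seq), ]
  out$read_id <- reads$read_id
  out$length <- nchar(reads$seq)
  if (!is.null(reads$sample)) out$sample <- reads$sample
  rownames(out) <- NULL
  out[, c("read_id", intersect("sample", names(out)), "seq", "length",
          "stage", "detail", "class", "mismatches", "d5", "d3", "sub_pos",
          "category")]
}

#' Annotate one sample FASTQ end to end
#'
#' Reads a FASTQ, trims the 3' adapter, and classifies the kept reads.
#'
#' @param fastq Path to a FASTQ file.
#' @param bundle A [reference_bundle].
#' @param sample Sample name attached to the result.
#' @param adapter 3' adapter sequence.
#' @param ... Passed to [classify_reads()].
#' @return List with `annotation` (classification `data.frame`),
#'   `discarded` (reads below the length cutoff after trimming) and
#'   `raw_reads` (raw read count).
#' @export
annotate_sample <- function(fastq, bundle, sample = basename(fastq),
                            adapter = DEFAULT_ADAPTER, min_len = 15L, ...) {
  set <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  tr <- trim_adapter(as.character(set), adapter = adapter, min_len = min_len)
  kept <- data.frame(read_id = ids[tr$kept], seq = tr$seq[tr$kept],
                     sample = sample, stringsAsFactors = FALSE)
  ann <- classify_reads(kept, bundle, min_len = min_len, ...)
  list(annotation = ann, discarded = sum(!tr$kept), raw_reads = length(set))
}

#' Per-sample composition and length summaries
#'
#' Small-RNA class fractions are computed over the small-RNA reads of each
#' sample (miRNA-stage reads plus genome-class reads); fractions of total
#' reads are reported separately for each stage. When a sample has no
#' small-RNA reads its class fractions are `NA` (undefined), never 0/0.
#'
#' @param annotation Classification `data.frame` (with a `sample` column)
#'   from [classify_reads()].
#' @param discarded Optional named vector of per-sample discarded-read
#'   counts (from trimming), included in the stage totals.
#' @return List with `class_fractions` (sample x class), `stage_counts`
#'   (sample x stage, plus `discarded` and `total`), and `length_hist`
#'   (long `data.frame`: sample, stage, length, reads).
#' @export
composition_summary <- function(annotation, discarded = NULL) {
  stopifnot("sample" %in% names(annotation))
  samples <- unique(annotation$sample)
  stage_counts <- t(vapply(samples, function(s) {
    tab <- table(factor(annotation$stage[annotation$sample == s],
                        levels = ANNOT_STAGES))
    as.integer(tab)
  }, integer(length(ANNOT_STAGES))))
  colnames(stage_counts) <- ANNOT_STAGES
  disc <- if (is.null(discarded)) rep(0L, length(samples))
          else as.integer(discarded[samples])
  stage_counts <- cbind(stage_counts, discarded = disc,
                        total = rowSums(stage_counts) + disc)
  rownames(stage_counts) <- samples

  classes <- c("miRNA", SMALLRNA_CLASSES)
  class_fractions <- t(vapply(samples, function(s) {
    sub <- annotation[annotation$sample == s &
                        annotation$stage %in% c("MIRNA", "GENOME_CLASS"), ]
    if (nrow(sub) == 0L) return(rep(NA_real_, length(classes)))
    tab <- table(factor(sub$class, levels = classes))
    as.numeric(tab) / nrow(sub)
  }, numeric(length(classes))))
  colnames(class_fractions) <- classes
  rownames(class_fractions) <- samples

  lh <- stats::aggregate(list(reads = annotation$read_id),
                         by = list(sample = annotation$sample,
                                   stage = annotation$stage,
                                   length = annotation$length),
                         FUN = length)
  list(class_fractions = class_fractions,
       stage_counts = stage_counts,
       length_hist = lh[order(lh$sample, lh$stage, lh$length), ])
}
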