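# Reference sets consumed by the annotation hierarchy: spike-ins, outmapped
# nuisance sequences, mature miRNAs, and a genome with small-RNA class
# intervals. All sequences are held in the DNA alphabet (U -> T on input);
# interval coordinates are 0-based half-open throughout.

SMALLRNA_CLASSES <- c("tRNA", "Y_RNA", "snRNA", "snoRNA", "piRNA", "OTHER")
OUTMAP_CATEGORIES <- c("ADAPTER", "rRNA", "PHIX", "MITO")

normalize_seq <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,U,N}: ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  x
}

#' Read a FASTA reference file
#'
#' Loads a FASTA file into a named character vector of uppercase DNA
#' sequences; RNA input is accepted and `U` is converted to `T` so that one
#' alphabet is used for all downstream matching. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param role Short label used in error messages (e.g. `"spikeins"`).
#' @return Named character vector of sequences.
#' @export
load_fasta <- function(path, role = "reference") {
  if (!file.exists(path)) stop("FASTA file for ", role, " not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA for ", role, " (", path, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no records in FASTA for ", role, ": ", path)
  nm <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header in ", role, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- normalize_seq(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA for ", role)
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param rna Write the RNA alphabet (`T` -> `U`) instead of DNA.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  stopifnot(!is.null(names(seqs)))
  out <- if (rna) gsub("T", "U", seqs, fixed = TRUE) else seqs
  set <- Biostrings::BStringSet(out)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Spike-in reference set
#'
#' @param sequences Named character vector of spike-in sequences
#'   (UniSp100-UniSp151 style synthetic RNAs).
#' @return A `spikein_set` object.
#' @export
spikein_set <- function(sequences) {
  sequences <- normalize_seq(sequences)
  if (length(sequences) == 0L) stop("spike-in set must be non-empty")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("spike-in names must be present and unique")
  if (any(nchar(sequences) == 0L)) stop("spike-in sequences must be non-empty")
  structure(list(sequences = sequences), class = "spikein_set")
}

#' Outmap reference set
#'
#' Abundant nuisance sequences discarded before annotation: adapter
#' sequences, ribosomal RNA, the phiX174 genome, mitochondrial RNA, plus a
#' homopolymer rule for poly-A / poly-C reads.
#'
#' @param sequences Named character vector.
#' @param category Category per sequence, one of
#'   `"ADAPTER"`, `"rRNA"`, `"PHIX"`, `"MITO"`.
#' @param homopolymer_threshold Fraction of a single base (A or C) at or
#'   above which a read is called a homopolymer; must lie in (0.5, 1].
#' @return An `outmap_set` object.
#' @export
outmap_set <- function(sequences, category, homopolymer_threshold = 0.9) {
  sequences <- normalize_seq(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("outmap names must be present and unique")
  category <- match.arg(category, OUTMAP_CATEGORIES, several.ok = TRUE)
  if (length(category) != length(sequences))
    stop("one category per outmap sequence required")
  if (!(homopolymer_threshold > 0.5 && homopolymer_threshold <= 1))
    stop("homopolymer threshold must lie in (0.5, 1]")
  structure(list(sequences = sequences, category = category,
                 homopolymer_threshold = homopolymer_threshold),
            class = "outmap_set")
}

#' Mature miRNA reference set
#'
#' @param sequences Named character vector of mature miRNA sequences
#'   (miRBase-style identifiers), each at least 15 nt.
#' @param family Optional family label per miRNA (`NA` allowed).
#' @param seed_span 1-based inclusive positions of the seed region on the
#'   mature sequence; the standard definition is positions 2-8.
#' @return A `mature_mirna_set` object.
#' @export
mature_mirna_set <- function(sequences, family = NULL, seed_span = c(2L, 8L)) {
  sequences <- normalize_seq(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("miRNA names must be present and unique")
  if (any(nchar(sequences) < 15L))
    stop("every mature miRNA sequence must be >= 15 nt")
  if (is.null(family)) family <- rep(NA_character_, length(sequences))
  if (length(family) != length(sequences)) stop("one family label per miRNA")
  seed_span <- as.integer(seed_span)
  if (length(seed_span) != 2L || seed_span[1] < 1L || seed_span[1] > seed_span[2])
    stop("seed_span must be two increasing 1-based positions")
  if (seed_span[2] > min(nchar(sequences)))
    stop("seed_span exceeds the shortest mature sequence")
  structure(list(sequences = sequences, family = family, seed_span = seed_span),
            class = "mature_mirna_set")
}

#' Genome with small-RNA class intervals
#'
#' @param genome Named character vector of chromosome sequences.
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `class` (one of the closed small-RNA class set),
#'   `strand`, and optionally `feature` (a per-interval feature id; a
#'   deterministic id is constructed when absent).
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(genome, intervals) {
  genome <- normalize_seq(genome)
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("chromosome names must be present and unique")
  req <- c("chrom", "start", "end", "class", "strand")
  if (!all(req %in% names(intervals)))
    stop("intervals must have columns: ", paste(req, collapse = ", "))
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  if (any(is.na(intervals$start) | is.na(intervals$end)))
    stop("interval coordinates must be integers")
  if (any(intervals$start < 0L) || any(intervals$start >= intervals$end))
    stop("intervals must satisfy 0 <= start < end")
  if (!all(intervals$chrom %in% names(genome)))
    stop("interval on unknown chromosome")
  clen <- nchar(genome)[intervals$chrom]
  if (any(intervals$end > clen))
    stop("interval end beyond chromosome length")
  unknown <- !(intervals$class %in% SMALLRNA_CLASSES)
  if (any(unknown)) {
    warning("unknown class label(s) ",
            paste(unique(intervals$class[unknown]), collapse = ", "),
            " mapped to OTHER")
    intervals$class[unknown] <- "OTHER"
  }
  if (is.null(intervals$feature)) {
    intervals$feature <- sprintf("%s:%s:%d-%d", intervals$class,
                                 intervals$chrom, intervals$start,
                                 intervals$end)
  }
  rownames(intervals) <- NULL
  structure(list(genome = genome, intervals = intervals),
            class = "genome_annotation")
}

#' Read class intervals from a BED6 file
#'
#' The BED name column carries the small-RNA class label; labels outside the
#' closed class set are mapped to `OTHER` with a warning. Coordinates are
#' kept 0-based half-open (the BED convention).
#'
#' @param path Path to a BED file.
#' @return `data.frame` of intervals (`chrom`, `start`, `end`, `class`,
#'   `strand`, `feature`).
#' @export
load_class_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("invalid BED file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0L) stop("no intervals in BED file: ", path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    class = if (!is.null(gr$name)) as.character(gr$name) else "OTHER",
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(df$start >= df$end)) stop("invalid BED interval: start >= end")
  unknown <- !(df$class %in% SMALLRNA_CLASSES)
  if (any(unknown)) {
    warning("unknown class label(s) ",
            paste(unique(df$class[unknown]), collapse = ", "),
            " mapped to OTHER")
    df$class[unknown] <- "OTHER"
  }
  df$feature <- sprintf("%s:%s:%d-%d", df$class, df$chrom, df$start, df$end)
  df
}

#' Bundle all reference sets
#'
#' @param spikeins A [spikein_set].
#' @param outmap An [outmap_set].
#' @param mirnas A [mature_mirna_set].
#' @param genome A [genome_annotation].
#' @return A `reference_bundle` object.
#' @export
reference_bundle <- function(spikeins, outmap, mirnas, genome) {
  stopifnot(inherits(spikeins, "spikein_set"), inherits(outmap, "outmap_set"),
            inherits(mirnas, "mature_mirna_set"),
            inherits(genome, "genome_annotation"))
  structure(list(spikeins = spikeins, outmap = outmap, mirnas = mirnas,
                 genome = genome), class = "reference_bundle")
}

#' Validate a reference bundle
#'
#' Reports cross-set name collisions, intervals out of genome bounds and
#' empty sets. Only fatal problems (an empty miRNA set or spike-in set)
#' raise an error; everything else is returned as a character vector of
#' issues, empty when the bundle is clean.
#'
#' @param bundle A [reference_bundle].
#' @return Character vector of issues (zero-length if none).
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  if (length(bundle$mirnas$sequences) == 0L) stop("empty miRNA set")
  if (length(bundle$spikeins$sequences) == 0L) stop("empty spike-in set")
  issues <- character(0)
  sets <- list(spikein = names(bundle$spikeins$sequences),
               outmap = names(bundle$outmap$sequences),
               miRNA = names(bundle$mirnas$sequences),
               chromosome = names(bundle$genome$genome))
  all_names <- unlist(sets, use.names = FALSE)
  dup <- unique(all_names[duplicated(all_names)])
  for (d in dup) {
    in_sets <- names(sets)[vapply(sets, function(s) d %in% s, logical(1))]
    issues <- c(issues, sprintf("name '%s' appears in multiple sets (%s)",
                                d, paste(in_sets, collapse = ", ")))
  }
  iv <- bundle$genome$intervals
  clen <- nchar(bundle$genome$genome)[iv$chrom]
  oob <- which(is.na(clen) | iv$end > clen | iv$start < 0L)
  for (i in oob) {
    issues <- c(issues, sprintf("interval %s out of genome bounds", iv$feature[i]))
  }
  if (nrow(iv) == 0L) issues <- c(issues, "genome annotation has no intervals")
  if (length(bundle$outmap$sequences) == 0L) issues <- c(issues, "outmap set is empty")
  issues
}
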