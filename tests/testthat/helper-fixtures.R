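# Shared fixtures (built in code) and independent brute-force oracles.

# let-7a-5p mature sequence, used where a concrete canonical is convenient
LET7A <- "TGAGGTAGTAGGTTGTATAGTT"

## A tiny hand-made reference bundle with known structure.
tiny_bundle <- function(n_mirna = 4L) {
  set.seed(424242)
  mir <- c(LET7A, vapply(seq_len(n_mirna - 1L), function(i)
    paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = ""),
    character(1)))
  names(mir) <- sprintf("mir-t%02d", seq_len(n_mirna))
  spk <- c(UniSp100 = "ACCTGGACTTGGAGTCAGAAGG",
           UniSp101 = "CGGTTCAAGTCCGTTAACCGTA")
  outs <- c(ADAPTER = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
            rRNA_28S = paste(rep("GCTA", 30), collapse = ""),
            MT = paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""))
  trna <- paste(sample(c("A", "C", "G", "T"), 72, TRUE), collapse = "")
  yrna <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  chrom <- paste0(spacer(30), trna, spacer(25), yrna, spacer(30))
  iv <- data.frame(chrom = "chr1",
                   start = c(30L, 30L + 72L + 25L),
                   end = c(30L + 72L, 30L + 72L + 25L + 100L),
                   class = c("tRNA", "Y_RNA"), strand = "+",
                   feature = c("tRNA-t01", "Y_RNA-t01"),
                   stringsAsFactors = FALSE)
  reference_bundle(
    spikeins = spikein_set(spk),
    outmap = outmap_set(outs, c("ADAPTER", "rRNA", "MITO")),
    mirnas = mature_mirna_set(mir),
    genome = genome_annotation(c(chr1 = chrom), iv)
  )
}

## ---- brute-force classification oracle --------------------------------
## Enumerates every (reference, offset, mismatch) alignment of the read
## against every reference of every stage, then applies the stage order.

# all alignments of read against one reference sequence under the isomiR
# edit space; returns the minimal (nsub, |d5|, |d3|) or NULL
brute_isomir_costs <- function(read, canonical, max5 = 2L, max3 = 4L) {
  n <- nchar(read); L <- nchar(canonical)
  best <- NULL
  for (d5 in seq.int(-max5, max5)) {
    d3 <- n - L - d5
    if (abs(d3) > max3) next
    a <- max(0L, -d5); b <- max(0L, -d3)
    e5 <- max(0L, d5)
    core_len <- L - a - b
    if (core_len < 1L) next
    mm <- 0L
    for (k in seq_len(core_len)) {
      if (substr(read, e5 + k, e5 + k) != substr(canonical, a + k, a + k))
        mm <- mm + 1L
    }
    if (mm > 1L) next
    cost <- c(mm, abs(d5), abs(d3))
    if (is.null(best) ||
        (cost[1] < best[1] ||
         (cost[1] == best[1] && (cost[2] < best[2] ||
          (cost[2] == best[2] && cost[3] < best[3])))))
      best <- cost
  }
  best
}

# exhaustive substring check at every offset with <= max_mm mismatches
brute_substring <- function(read, ref, max_mm = 0L) {
  n <- nchar(read); L <- nchar(ref)
  if (n > L) return(NA_integer_)
  best <- NA_integer_
  for (o in 0:(L - n)) {
    mm <- 0L
    for (k in seq_len(n)) {
      if (substr(read, k, k) != substr(ref, o + k, o + k)) mm <- mm + 1L
      if (mm > max_mm) break
    }
    if (mm <= max_mm && (is.na(best) || mm < best)) best <- mm
  }
  best
}

brute_classify <- function(read, bundle) {
  for (s in bundle$spikeins$sequences)
    if (!is.na(brute_substring(read, s, 0L))) return("SPIKE_IN")
  for (s in bundle$outmap$sequences)
    if (!is.na(brute_substring(read, s, 0L))) return("OUTMAPPED")
  n <- nchar(read)
  fr <- strsplit(read, "")[[1]]
  if (max(mean(fr == "A"), mean(fr == "C")) >=
      bundle$outmap$homopolymer_threshold) return("OUTMAPPED")
  for (s in bundle$mirnas$sequences)
    if (!is.null(brute_isomir_costs(read, s))) return("MIRNA")
  for (s in bundle$genome$genome)
    if (!is.na(brute_substring(read, s, 1L))) return("GENOME_CLASS")
  "UNMAPPED"
}

## ---- exact-test oracle -------------------------------------------------
## Conditional law of the first group's total via the negative
## hypergeometric written with lchoose-style gamma terms (independent of
## the dnbinom-based implementation); phi = 0 is the exact binomial.
oracle_exact_p <- function(s_a, s, n_a, n_b, phi) {
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    lp <- lchoose(s, k) + k * log(n_a / (n_a + n_b)) +
      (s - k) * log(n_b / (n_a + n_b))
  } else {
    r_a <- n_a / phi; r_b <- n_b / phi
    lp <- (lgamma(k + r_a) - lgamma(k + 1) - lgamma(r_a)) +
      (lgamma(s - k + r_b) - lgamma(s - k + 1) - lgamma(r_b))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  min(1, 2 * min(sum(p[1:(s_a + 1)]), sum(p[(s_a + 1):(s + 1)])))
}

## ---- brute-force UPGMA oracle -------------------------------------------
## Average-linkage heights computed from the definition: the height of a
## merge is the mean pairwise distance between the two merged clusters.
brute_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}
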