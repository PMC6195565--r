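test_that("adapter trimming removes the 3' adapter and tallies short reads", {
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
  insert <- "ACGTACGTACGTACGTAC"
  tr <- trim_adapter(paste0(insert, adapter), adapter)
  expect_equal(tr$seq, insert)
  expect_true(tr$kept)

  tr2 <- trim_adapter(paste0("ACGTACGTAC", adapter), adapter)  # 10 nt insert
  expect_false(tr2$kept)

  no_ad <- "ACGTACGTACGTACGTACGTACGTAC"
  tr3 <- trim_adapter(no_ad, adapter)
  expect_equal(tr3$seq, no_ad)
  expect_true(tr3$kept)
})

test_that("a read matching both a spike-in and a miRNA is assigned SPIKE_IN", {
  b <- tiny_bundle()
  # make one spike-in carry the let-7a sequence: stage order must win
  b$spikeins$sequences["UniSp100"] <- LET7A
  ann <- classify_reads(LET7A, b)
  expect_equal(ann$stage, "SPIKE_IN")
  expect_equal(ann$detail, "UniSp100")
})

test_that("homopolymer reads are outmapped", {
  b <- tiny_bundle()
  ann <- classify_reads(c(strrep("A", 30), strrep("C", 30)), b)
  expect_equal(ann$stage, c("OUTMAPPED", "OUTMAPPED"))
  expect_equal(ann$detail, c("HOMOPOLYMER", "HOMOPOLYMER"))
  # 80% A with threshold 0.9 is not a homopolymer
  mixed <- paste0(strrep("A", 24), "CGTCGT")
  expect_false(classify_reads(mixed, b)$stage == "OUTMAPPED")
})

test_that("canonical miRNA reads and 1-mismatch genome reads classify correctly", {
  b <- tiny_bundle()
  ann <- classify_reads(LET7A, b)
  expect_equal(ann$stage, "MIRNA")
  expect_equal(ann$detail, "mir-t01")
  expect_equal(ann$category, "CANONICAL")

  # substring of the tRNA interval with one substitution
  g <- b$genome$genome[["chr1"]]
  iv <- b$genome$intervals[1, ]
  read <- substr(g, iv$start + 3, iv$start + 32)  # 30 nt inside tRNA
  substr(read, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                  substr(read, 15, 15))[1]
  ann2 <- classify_reads(read, b)
  expect_equal(ann2$stage, "GENOME_CLASS")
  expect_equal(ann2$class, "tRNA")
  expect_equal(ann2$mismatches, 1L)
})

test_that("genome reads straddling an interval boundary fall back to OTHER", {
  b <- tiny_bundle()
  g <- b$genome$genome[["chr1"]]
  iv <- b$genome$intervals[1, ]
  # 30 nt read with only 10 nt overlapping the tRNA interval (< 90%)
  read <- substr(g, iv$end - 9, iv$end + 20)
  ann <- classify_reads(read, b)
  expect_equal(ann$stage, "GENOME_CLASS")
  expect_equal(ann$class, "OTHER")
})

test_that("classification agrees with the brute-force oracle", {
  b <- tiny_bundle()
  set.seed(77)
  reads <- character(0)
  # edited miRNA reads
  for (m in b$mirnas$sequences)
    reads <- c(reads, enumerate_single_edits(m)$read[c(1, 5, 9, 20, 40)])
  # genome substrings, exact and 1-mismatch
  g <- b$genome$genome[["chr1"]]
  for (i in 1:20) {
    st <- sample(nchar(g) - 30, 1)
    r <- substr(g, st, st + 29)
    if (i %% 2 == 0) {
      p <- sample(30, 1)
      substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
    }
    reads <- c(reads, r)
  }
  # spike-ins, outmap fragments, homopolymers, random reads
  reads <- c(reads, b$spikeins$sequences,
             substr(b$outmap$sequences[["rRNA_28S"]], 5, 34),
             strrep("A", 25), strrep("C", 25),
             vapply(1:20, function(i)
               paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = ""),
               character(1)))
  reads <- reads[!is.na(reads)]
  got <- classify_reads(reads, b)
  want <- vapply(reads, brute_classify, character(1), bundle = b)
  expect_equal(got$stage, unname(want))
})

test_that("stage assignment is stable under reference reordering", {
  b <- tiny_bundle()
  set.seed(78)
  reads <- c(vapply(b$mirnas$sequences, function(m)
    enumerate_single_edits(m)$read[15], character(1)),
    b$spikeins$sequences[2],
    substr(b$genome$genome[["chr1"]], 40, 70))
  b_shuffled <- b
  perm <- rev(seq_along(b$mirnas$sequences))
  b_shuffled$mirnas$sequences <- b$mirnas$sequences[perm]
  b_shuffled$mirnas$family <- b$mirnas$family[perm]
  b_shuffled$spikeins$sequences <- rev(b$spikeins$sequences)
  a1 <- classify_reads(unname(reads), b)
  a2 <- classify_reads(unname(reads), b_shuffled)
  expect_equal(a1$stage, a2$stage)
  expect_equal(a1$detail, a2$detail)
})

test_that("classified reads partition the raw reads of every sample", {
  d <- sim_design(seed = 31, depths = c(hPSC = 800L, ATMSC = 600L),
                  media_depths = c(hPSC = 200L, ATMSC = 400L),
                  n_mirna = 8L, n_other = 6L, n_media_only = 3L,
                  n_shared_bg = 2L)
  run <- run_pipeline(d, read_level = TRUE)
  sc <- run$composition$stage_counts
  expect_equal(unname(sc[, "total"]),
               unname(rowSums(sc[, c(evsmallrna:::ANNOT_STAGES,
                                     "discarded")])))
  expect_equal(unname(sc[names(run$raw_reads), "total"]),
               unname(run$raw_reads))
})

test_that("composition fractions reproduce hand-constructed class counts", {
  ann <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    sample = "s1",
    stage = c(rep("MIRNA", 13), rep("GENOME_CLASS", 87)),
    class = c(rep("miRNA", 13), rep("tRNA", 69), rep("Y_RNA", 7),
              rep("snRNA", 4), rep("snoRNA", 7)),
    length = 22L, stringsAsFactors = FALSE)
  cs <- composition_summary(ann)
  expect_equal(unname(cs$class_fractions["s1", c("miRNA", "tRNA", "Y_RNA",
                                                 "snRNA", "snoRNA")]),
               c(0.13, 0.69, 0.07, 0.04, 0.07))
})

test_that("samples with no small-RNA reads get undefined fractions", {
  ann <- data.frame(read_id = c("r1", "r2"), sample = "s1",
                    stage = "UNMAPPED", class = NA_character_, length = 20L,
                    stringsAsFactors = FALSE)
  cs <- composition_summary(ann)
  expect_true(all(is.na(cs$class_fractions["s1", ])))
})

test_that("class fractions sum to 1 on simulated annotations", {
  set.seed(55)
  stages <- sample(c("MIRNA", "GENOME_CLASS", "UNMAPPED", "SPIKE_IN"), 500,
                   TRUE)
  cls <- ifelse(stages == "MIRNA", "miRNA",
                ifelse(stages == "GENOME_CLASS",
                       sample(c("tRNA", "Y_RNA", "snoRNA", "OTHER"), 500, TRUE),
                       NA))
  ann <- data.frame(read_id = sprintf("r%04d", 1:500),
                    sample = sample(c("a", "b", "c"), 500, TRUE),
                    stage = stages, class = cls, length = 22L,
                    stringsAsFactors = FALSE)
  cs <- composition_summary(ann)
  sums <- rowSums(cs$class_fractions, na.rm = TRUE)
  expect_equal(unname(sums), rep(1, 3), tolerance = 1e-12)
})
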