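tiny_mirnas <- function() tiny_bundle()$mirnas

test_that("canonical reads and simple terminal variants are called exactly", {
  mir <- tiny_mirnas()
  call <- isomir_match(LET7A, mir)
  expect_equal(call$mirna, "mir-t01")
  expect_equal(c(call$d5, call$d3), c(0L, 0L))
  expect_true(is.na(call$sub_pos))
  expect_equal(call$category, "CANONICAL")

  # last base removed: 3' offset -1
  call2 <- isomir_match(substr(LET7A, 1, nchar(LET7A) - 1), mir)
  expect_equal(call2$mirna, "mir-t01")
  expect_equal(c(call2$d5, call2$d3), c(0L, -1L))
  expect_equal(call2$category, "THREE_PRIME")
  expect_equal(substr(LET7A, 1, nchar(LET7A) - 1), "TGAGGTAGTAGGTTGTATAGT")

  # base 4 G->C lies in the seed region (positions 2-8)
  seedsub <- LET7A
  substr(seedsub, 4, 4) <- "C"
  call3 <- isomir_match(seedsub, mir)
  expect_equal(call3$sub_pos, 4L)
  expect_equal(call3$sub_from, "G")
  expect_equal(call3$sub_to, "C")
  expect_true(call3$in_seed)
  expect_equal(call3$category, "SUBSTITUTION_SEED")
})

test_that("every legal single edit is recovered by the matcher", {
  mir <- tiny_mirnas()
  for (nm in names(mir$sequences)) {
    edits <- enumerate_single_edits(mir$sequences[[nm]])
    for (i in seq_len(nrow(edits))) {
      call <- isomir_match(edits$read[i], mir)
      expect_false(is.null(call))
      expect_equal(call$mirna, nm)
      expect_equal(call$category, edits$category[i])
      expect_equal(call$d5, edits$d5[i])
      expect_equal(call$d3, edits$d3[i])
      if (!is.na(edits$sub_pos[i])) {
        expect_equal(call$sub_pos, edits$sub_pos[i])
        expect_equal(call$sub_to, edits$sub_to[i])
      }
    }
  }
})

test_that("reads outside the edit space are not called", {
  mir <- tiny_mirnas()
  # two substitutions
  two_sub <- LET7A
  substr(two_sub, 4, 4) <- "C"
  substr(two_sub, 12, 12) <- "A"
  expect_null(isomir_match(two_sub, mir))
  # 3 nt 5' extension (bound is 2)
  expect_null(isomir_match(paste0("CCC", LET7A), mir))
  # unrelated sequence
  expect_null(isomir_match(strrep("GATC", 6), mir))
})

test_that("categorization follows the closed category set", {
  cat_of <- function(d5, d3, sub_pos = NA_integer_, in_seed = FALSE)
    isomir_categorize(list(d5 = d5, d3 = d3, sub_pos = sub_pos,
                           in_seed = in_seed))
  expect_equal(cat_of(0L, 0L), "CANONICAL")
  expect_equal(cat_of(1L, 0L), "FIVE_PRIME")
  expect_equal(cat_of(0L, -2L), "THREE_PRIME")
  expect_equal(cat_of(1L, -2L), "BOTH_ENDS")
  expect_equal(cat_of(0L, 0L, 4L, TRUE), "SUBSTITUTION_SEED")
  expect_equal(cat_of(0L, 0L, 12L, FALSE), "SUBSTITUTION_NONSEED")
  expect_equal(cat_of(0L, -1L, 12L, FALSE), "MIXED")
})

test_that("matching is independent of miRNA set ordering", {
  mir <- tiny_mirnas()
  mir_rev <- mir
  perm <- rev(seq_along(mir$sequences))
  mir_rev$sequences <- mir$sequences[perm]
  mir_rev$family <- mir$family[perm]
  reads <- unlist(lapply(mir$sequences, function(m)
    enumerate_single_edits(m)$read[c(3, 17, 33)]))
  for (r in reads) {
    a <- isomir_match(r, mir)
    b <- isomir_match(r, mir_rev)
    expect_identical(a, b)
  }
})

test_that("dominance follows read counts with the canonical tie rule", {
  calls <- data.frame(
    mirna = c(rep("m1", 13), rep("m2", 10)),
    category = c(rep("CANONICAL", 10), rep("THREE_PRIME", 3),
                 rep("CANONICAL", 5), rep("THREE_PRIME", 5)),
    stringsAsFactors = FALSE)
  dom <- isomir_dominance(calls)
  expect_equal(dom$per_mirna$dominant[dom$per_mirna$mirna == "m1"],
               "CANONICAL")
  # 5/5 tie resolves to CANONICAL and is flagged
  m2 <- dom$per_mirna[dom$per_mirna$mirna == "m2", ]
  expect_equal(m2$dominant, "CANONICAL")
  expect_true(m2$tie)
  expect_equal(dom$variant_read_fraction, 8 / 23)
  expect_error(isomir_dominance(calls[0, ]), "no isomiR calls")
})

test_that("group dominance distribution recovers the designed mixture", {
  set.seed(202)
  arch <- default_isomir_archetypes()
  n_mir <- 200L
  kind <- sample(c("three_prime_dominant", "canonical_dominant"), n_mir,
                 TRUE, prob = c(0.7, 0.3))
  calls <- do.call(rbind, lapply(seq_len(n_mir), function(i) {
    k <- stats::rmultinom(1, 200, arch[[kind[i]]])[, 1]
    data.frame(mirna = sprintf("m%03d", i),
               category = rep(names(k), k), stringsAsFactors = FALSE)
  }))
  dom <- isomir_dominance(calls)
  expect_equal(unname(dom$distribution["THREE_PRIME"]), 0.7, tolerance = 0.12)
  expect_equal(unname(dom$distribution["CANONICAL"]), 0.3, tolerance = 0.12)
})

test_that("matcher inverts the read generator's edit labels end to end", {
  d <- sim_design(seed = 41, depths = c(hPSC = 1500L, ATMSC = 1000L),
                  media_depths = c(hPSC = 200L, ATMSC = 300L),
                  n_mirna = 10L, n_other = 6L, n_media_only = 2L,
                  n_shared_bg = 2L)
  b <- make_reference_bundle(d)
  sim <- simulate_counts(d)
  em <- emit_reads(sim, b, d, withr::local_tempdir())
  mir <- em$truth_reads[em$truth_reads$class == "miRNA", ]
  adapter <- b$outmap$sequences[["ADAPTER"]]
  set <- Biostrings::readDNAStringSet(em$fastq[1], format = "fastq")
  trimmed <- trim_adapter(as.character(set))
  reads <- setNames(trimmed$seq,
                    vapply(strsplit(names(set), " "), `[`, character(1), 1))
  sub <- mir[mir$sample == sim$meta$sample[1], ]
  for (i in seq_len(nrow(sub))) {
    call <- isomir_match(reads[[sub$read_id[i]]], b$mirnas)
    expect_equal(call$mirna, sub$feature[i])
    expect_equal(call$category, sub$category[i])
  }
})
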