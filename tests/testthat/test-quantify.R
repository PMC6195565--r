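ev_meta5 <- function() {
  data.frame(sample = c("h1", "h2", "a1", "a2", "a3"),
             group = c("hPSC", "hPSC", "ATMSC", "ATMSC", "ATMSC"),
             type = "EV", stringsAsFactors = FALSE)
}

full_meta <- function() {
  rbind(ev_meta5(),
        data.frame(sample = c("mh", "ma"), group = c("hPSC", "ATMSC"),
                   type = "media", stringsAsFactors = FALSE))
}

test_that("CPM scales columns to one million", {
  m <- matrix(c(1, 1), 1, 2, dimnames = list("f1", c("s1", "s2")))
  expect_equal(unname(cpm_matrix(m, lib_sizes = c(2, 2))[1, ]),
               c(5e5, 5e5))
  z <- rbind(f1 = c(10, 20), f2 = c(0, 0), f3 = c(30, 5))
  colnames(z) <- c("s1", "s2")
  cp <- cpm_matrix(z)
  expect_equal(unname(cp["f2", ]), c(0, 0))
  set.seed(91)
  r <- matrix(rpois(60, 50), 10, 6)
  colnames(r) <- sprintf("s%d", 1:6)
  expect_equal(unname(colSums(cpm_matrix(r))), rep(1e6, 6))
  r0 <- r; r0[, 3] <- 0
  expect_error(cpm_matrix(r0), "s3")
})

test_that("detection requires >1 CPM in at least two samples", {
  cpm <- rbind(f1 = c(1.5, 0, 1.2, 0, 0),
               f2 = c(1.5, 0.9, 0, 0, 0),
               f3 = c(50, 50, 0, 0, 0))
  colnames(cpm) <- ev_meta5()$sample
  det <- detection_filter(cpm, ev_meta5())
  expect_equal(det$detected, c(TRUE, FALSE, TRUE))
  # f3 present only in the two-sample hPSC group (both samples qualify)
  expect_equal(det$present_hPSC, c(FALSE, FALSE, TRUE))
  expect_equal(det$present_ATMSC, c(FALSE, FALSE, FALSE))
})

test_that("detection is idempotent and order-independent in samples", {
  set.seed(92)
  cpm <- matrix(rexp(50, 1 / 5), 10, 5,
                dimnames = list(sprintf("f%d", 1:10), ev_meta5()$sample))
  det1 <- detection_filter(cpm, ev_meta5())
  perm <- c(3, 1, 5, 2, 4)
  det2 <- detection_filter(cpm[, perm], ev_meta5()[perm, ])
  expect_equal(det1$detected, det2$detected)
  expect_equal(det1$present_hPSC, det2$present_hPSC)
})

test_that("spike-in normalization uses the geometric-mean reference", {
  m <- rbind(f1 = c(10, 10))
  colnames(m) <- c("s1", "s2")
  expect_equal(spikein_normalize(m, c(s1 = 100, s2 = 100)), m)
  # count 10, spike total 100, reference sqrt(100*400)=200 -> 20
  n <- spikein_normalize(m, c(s1 = 100, s2 = 400))
  expect_equal(unname(n[1, 1]), 20)
  expect_error(spikein_normalize(m, c(s1 = 0, s2 = 100)), "zero spike")
})

test_that("doubling a sample's counts and spike total is a no-op", {
  set.seed(93)
  m <- matrix(rpois(20, 40), 4, 5)
  colnames(m) <- sprintf("s%d", 1:5)
  sp <- c(s1 = 120, s2 = 80, s3 = 200, s4 = 150, s5 = 90)
  n1 <- spikein_normalize(m, sp)
  m2 <- m; m2[, 2] <- 2 * m2[, 2]
  sp2 <- sp; sp2[2] <- 2 * sp2[2]
  n2 <- spikein_normalize(m2, sp2)
  # the shared reference shifts for all samples, but sample 2's normalized
  # profile relative to the others is unchanged
  expect_equal(n2 / n1, matrix((n2 / n1)[1, 1], 4, 5,
                               dimnames = dimnames(n2 / n1)),
               tolerance = 1e-12)
})

test_that("media filter applies the published two-fold rules", {
  meta <- full_meta()
  norm <- rbind(
    over_pass = c(10, 10, 10, 10, 10, 4, 4),    # all samples >= 2 x media
    over_fail = c(10, 7, 10, 10, 10, 4, 4),     # one sample below 8
    media_only = c(0, 0, 0, 0, 0, 30, 30),      # signal only in media
    shared_pass = c(9, 11, 10, 10, 10, 4, 4),   # group means >= 8
    shared_fail = c(9, 11, 5, 8, 5, 4, 4))      # ATMSC mean 6 < 8
  colnames(norm) <- meta$sample
  lfc <- c(over_pass = 3, over_fail = 3, media_only = 0,
           shared_pass = 0.2, shared_fail = 0.2)
  mf <- media_filter(norm, meta, log2fc = lfc)
  expect_equal(setNames(mf$passed_media, mf$feature),
               c(over_pass = TRUE, over_fail = FALSE, media_only = FALSE,
                 shared_pass = TRUE, shared_fail = FALSE))
})

test_that("media filter errors without a medium for each group", {
  meta <- full_meta()[1:6, ]
  norm <- matrix(1, 2, 6, dimnames = list(c("f1", "f2"), meta$sample))
  expect_error(media_filter(norm, meta), "missing media.*ATMSC")
})

test_that("group assignment follows the significance and CPM rules", {
  meta <- ev_meta5()
  cpm <- rbind(h_only = c(120, 130, 0, 0, 0),
               shared = c(40, 44, 38, 41, 36),
               low_a = c(0, 0, 10, 11, 12))
  colnames(cpm) <- meta$sample
  de <- data.frame(feature = rownames(cpm),
                   log2FC = c(-9, 0.4, 8),
                   pValue = c(1e-6, 0.4, 1e-4), stringsAsFactors = FALSE)
  detection <- data.frame(feature = rownames(cpm), detected = TRUE,
                          present_hPSC = c(TRUE, TRUE, FALSE),
                          present_ATMSC = c(FALSE, TRUE, TRUE),
                          stringsAsFactors = FALSE)
  media <- data.frame(feature = rownames(cpm), passed_media = TRUE,
                      stringsAsFactors = FALSE)
  got <- assign_groups(de, detection, media, cpm, meta)
  expect_equal(setNames(got$group, got$feature),
               c(h_only = "hPSC_only", shared = "shared",
                 low_a = "excluded"))  # below the 32 mean-CPM cutoff
  # labels invariant to feature order
  perm <- c(3, 1, 2)
  got2 <- assign_groups(de[perm, ], detection[perm, ], media[perm, ],
                        cpm, meta)
  expect_equal(got2$group[match(got$feature, got2$feature)], got$group)
})

test_that("media-leak features are excluded and genuine features retained", {
  d <- sim_design(seed = 59)
  run <- run_pipeline(d)
  feats <- d$features
  for (tb in c("mirna", "ncrna")) {
    mf <- run$media[[tb]]
    idx <- match(mf$feature, feats$feature)
    expect_true(all(!mf$passed_media[feats$media_only[idx]]))
    genuine <- !feats$media_only[idx]
    expect_gte(mean(mf$passed_media[genuine]), 0.9)
  }
})
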