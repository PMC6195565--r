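test_that("library equalization scales to the geometric mean and rounds half-up", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2)
  eq <- equalize_libraries(m)
  expect_identical(eq$pseudo, m)  # equal libraries unchanged

  m2 <- cbind(a = c(10L, rep(1L, 99)), b = c(40L, rep(4L, 99)))
  eq2 <- equalize_libraries(m2, lib_sizes = c(1e6, 2e6))
  common <- sqrt(1e6 * 2e6)
  expect_equal(unname(eq2$pseudo[1, "a"]),
               as.integer(floor(10 * common / 1e6 + 0.5)))
  expect_equal(unname(eq2$pseudo[1, "b"]),
               as.integer(floor(40 * common / 2e6 + 0.5)))
})

test_that("equalized column sums stay within the rounding bound", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(rpois(400, 30), 100, 4)
    m[, 2] <- m[, 2] * 3L
    eq <- equalize_libraries(m)
    expect_true(all(abs(colSums(eq$pseudo) - eq$common_size) <= 100 / 2))
  }
})

test_that("common dispersion is recovered from simulated counts", {
  set.seed(123)
  mu <- rep(100, 5)
  counts <- t(vapply(1:2000, function(i) rnb_counts(mu, 0.2),
                     integer(5)))
  group <- c("A", "A", "A", "B", "B")
  phi_hat <- estimate_common_dispersion(counts, group)
  expect_gte(phi_hat, 0.16)
  expect_lte(phi_hat, 0.24)

  pois <- t(vapply(1:2000, function(i) rnb_counts(mu, 0), integer(5)))
  expect_lte(estimate_common_dispersion(pois, group), 0.02)
})

test_that("tagwise dispersions shrink toward the common value as the prior grows", {
  set.seed(124)
  counts <- t(vapply(1:200, function(i) rnb_counts(rep(80, 5), 0.3),
                     integer(5)))
  group <- c("A", "A", "A", "B", "B")
  phi_c <- estimate_common_dispersion(counts, group)
  t_small <- estimate_tagwise_dispersion(counts, group, prior_df = 2)
  t_big <- estimate_tagwise_dispersion(counts, group, prior_df = 100)
  d_small <- abs(log(t_small) - log(phi_c))
  d_big <- abs(log(t_big) - log(phi_c))
  expect_lt(mean(d_big), mean(d_small))
  expect_true(all(t_small >= 1e-6 & t_small <= 10))
})

test_that("the exact test is symmetric and handles empty features", {
  r <- nb_exact_test(c(5, 5), c(5, 5), phi = 0.3)
  expect_equal(r$p, 1)
  expect_equal(r$log2FC, 0)
  r0 <- nb_exact_test(c(0, 0, 0), c(0, 0), phi = 0.2)
  expect_equal(r0$p, 1)
  expect_equal(r0$log2FC, 0)
})

test_that("exact-test p-values match brute-force enumeration", {
  # groups (10,10) vs (0,0): all 21 splits of s = 20 under the conditional law
  r <- nb_exact_test(c(10, 10), c(0, 0), phi = 0.1)
  expect_equal(r$p, oracle_exact_p(20, 20, 2, 2, 0.1), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:25) {
    ya <- rpois(3, 40); yb <- rpois(2, 60)
    phi <- sample(c(0, 0.1, 0.5, 1), 1)
    got <- nb_exact_test(ya, yb, phi)$p
    want <- oracle_exact_p(sum(ya), sum(ya) + sum(yb), 3, 2, phi)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("the dispersion-zero limit is the conditional binomial", {
  # equal group sizes: double-tail p of Binomial(s, 1/2)
  ya <- c(14, 9); yb <- c(3, 2)
  s_a <- sum(ya); s <- s_a + sum(yb)
  p_binom <- min(1, 2 * min(pbinom(s_a, s, 0.5),
                            1 - pbinom(s_a - 1, s, 0.5)))
  expect_equal(nb_exact_test(ya, yb, 0)$p, p_binom, tolerance = 1e-12)
  expect_equal(nb_exact_test(ya, yb, 1e-9)$p, p_binom, tolerance = 1e-6)
})

test_that("swapping group labels negates log2FC and keeps p", {
  set.seed(32)
  for (i in 1:10) {
    ya <- rpois(3, 50); yb <- rpois(2, 20)
    a <- nb_exact_test(ya, yb, 0.2)
    b <- nb_exact_test(yb, ya, 0.2)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-12)
  }
})

test_that("the exact test agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(33)
  counts <- matrix(rnbinom(5 * 60, mu = 50, size = 1 / 0.15), 60, 5)
  # equalize to identical library sizes so both routes condition identically
  counts <- counts[, order(colSums(counts))]
  eq <- equalize_libraries(counts)
  group <- factor(c("A", "A", "A", "B", "B"))
  dge <- edgeR::DGEList(counts = eq$pseudo, group = group)
  dge$samples$norm.factors <- rep(1, 5)
  et <- edgeR::exactTest(dge, dispersion = 0.15)
  ours <- vapply(seq_len(nrow(eq$pseudo)), function(i)
    nb_exact_test(eq$pseudo[i, 1:3], eq$pseudo[i, 4:5], 0.15)$p, numeric(1))
  # same conditional law up to edgeR's own pseudo-count equalization
  expect_equal(ours, et$table$PValue, tolerance = 0.02)
  expect_gt(cor(log(ours), log(et$table$PValue)), 0.999)
})

test_that("BH adjustment matches the closed form and the stats oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(34)
  for (i in 1:20) {
    p <- runif(sample(2:200, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("de_exact returns a coherent table", {
  set.seed(35)
  counts <- rbind(
    t(vapply(1:40, function(i) rnb_counts(rep(60, 5), 0.2), integer(5))),
    t(vapply(1:10, function(i) rnb_counts(c(200, 200, 200, 25, 25), 0.2),
             integer(5))))
  rownames(counts) <- sprintf("f%02d", 1:50)
  group <- c("A", "A", "A", "B", "B")
  de <- de_exact(counts, group)
  expect_setequal(names(de), c("feature", "log2FC", "log2CPM", "pValue",
                               "FDR", "dispersion"))
  expect_true(all(de$pValue > 0 & de$pValue <= 1))
  expect_true(all(de$FDR > 0 & de$FDR <= 1))
  o <- order(de$pValue)
  expect_true(all(diff(de$FDR[o]) >= -1e-12))
  # the spiked features are down in B: negative log2FC (B over A)
  expect_true(all(de$log2FC[41:50] < 0))
  expect_lt(median(de$pValue[41:50]), 0.01)
})
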