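test_that("two-SNP EM equals direct counting when no double heterozygotes exist", {
  # genotypes chosen so phase is always determined
  g1 <- c(0, 0, 2, 2, 1, 0)
  g2 <- c(0, 1, 2, 0, 0, 0)
  f <- em_two_snp(g1, g2)
  # count haplotypes by hand: each person contributes two known haplotypes
  # (0,0)->ab,ab ; (0,1)->aB,ab ; (2,2)->AB,AB ; (2,0)->Ab,Ab ;
  # (1,0)->Ab,ab ; (0,0)->ab,ab
  hand <- c(AB = 2, Ab = 3, aB = 1, ab = 6) / 12
  expect_equal(as.numeric(f), as.numeric(hand[names(f)]), tolerance = 1e-9)
})

test_that("two-SNP EM recovers complete LD", {
  set.seed(14)
  pool <- build_haplotype_pool(2, 0.3, ld_level = 1)
  g <- sample_pool_dosages(600, pool_minor_ind(pool), pool$freq)
  f <- em_two_snp(g[, 1], g[, 2])
  q_hat <- sum(g[, 1]) / (2 * nrow(g))
  expect_equal(unname(f["AB"]), q_hat, tolerance = 1e-6)
  ld <- dprime_with_ci(g[, 1], g[, 2])
  expect_equal(ld$d_prime, 1, tolerance = 1e-6)
})

test_that("two-SNP EM attains the grid-search maximum likelihood", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    g1 <- sample(0:2, n, TRUE); g2 <- sample(0:2, n, TRUE)
    if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
    f <- em_two_snp(g1, g2)
    expect_gte(attr(f, "loglik"), two_snp_grid_max(g1, g2) - 1e-6)
  }
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(16)
  for (i in 1:10) {
    g1 <- sample(0:2, 40, TRUE); g2 <- sample(0:2, 40, TRUE)
    if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
    tr <- attr(em_two_snp(g1, g2), "loglik_trace")
    expect_true(all(diff(tr) >= -1e-9))
  }
})

test_that("monomorphic SNPs: EM errors, dprime_with_ci degrades to non-informative", {
  g1 <- rep(0, 20); g2 <- sample(0:2, 20, TRUE)
  expect_error(em_two_snp(g1, g2), "monomorphic")
  ld <- dprime_with_ci(g1, g2)
  expect_equal(ld$classification, "non_informative")
  expect_true(is.na(ld$d_prime))
})

test_that("D' confidence bounds: concentration at 1 for perfect LD, near 0 at equilibrium", {
  set.seed(17)
  pool <- build_haplotype_pool(2, 0.35, ld_level = 1)
  g <- sample_pool_dosages(1000, pool_minor_ind(pool), pool$freq)
  ld <- dprime_with_ci(g[, 1], g[, 2])
  expect_gt(ld$ci_low, 0.9)
  expect_equal(ld$ci_high, 1.0)
  expect_equal(classify_pair(ld$ci_low, ld$ci_high), "strong_ld")

  pool0 <- build_haplotype_pool(2, c(0.3, 0.4), ld_level = 0)
  g0 <- sample_pool_dosages(1000, pool_minor_ind(pool0), pool0$freq)
  ld0 <- dprime_with_ci(g0[, 1], g0[, 2])
  expect_lt(ld0$d_prime, 0.2)
  expect_lt(ld0$ci_low, 0.2)
})

test_that("confidence bounds are ordered on random data", {
  set.seed(18)
  for (i in 1:15) {
    g1 <- sample(0:2, 25, TRUE); g2 <- sample(0:2, 25, TRUE)
    if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
    ld <- dprime_with_ci(g1, g2)
    expect_lte(ld$ci_low, ld$ci_high)
  }
})

test_that("Gabriel classification thresholds", {
  expect_equal(classify_pair(0.75, 0.99), "strong_ld")
  expect_equal(classify_pair(0.0, 0.85), "recombination")
  expect_equal(classify_pair(0.5, 0.95), "non_informative")
  expect_equal(classify_pair(0.7, 0.98), "strong_ld")   # boundary inclusive
})

test_that("D' is invariant under allele relabeling at either SNP", {
  set.seed(19)
  for (i in 1:10) {
    g1 <- sample(0:2, 60, TRUE); g2 <- sample(0:2, 60, TRUE)
    if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
    a <- dprime_with_ci(g1, g2)
    b <- dprime_with_ci(2 - g1, g2)
    c_ <- dprime_with_ci(2 - g1, 2 - g2)
    expect_equal(a$d_prime, b$d_prime, tolerance = 1e-6)
    expect_equal(a$d_prime, c_$d_prime, tolerance = 1e-6)
    expect_equal(a$r2, b$r2, tolerance = 1e-6)
  }
})

test_that("r2 equals the direct-count value on phase-unambiguous data", {
  # no double heterozygotes: haplotypes countable directly
  g1 <- c(0, 0, 2, 2, 1, 0, 2, 1)
  g2 <- c(0, 1, 2, 0, 0, 1, 2, 0)
  # persons: (0,0) ab/ab; (0,1) aB/ab; (2,2) AB/AB; (2,0) Ab/Ab;
  # (1,0) Ab/ab; (0,1) aB/ab; (2,2) AB/AB; (1,0) Ab/ab
  f_hand <- c(AB = 4, Ab = 4, aB = 2, ab = 6) / 16
  pA <- f_hand["AB"] + f_hand["Ab"]; pB <- f_hand["AB"] + f_hand["aB"]
  d <- f_hand["AB"] - pA * pB
  r2_hand <- unname(d^2 / (pA * (1 - pA) * pB * (1 - pB)))
  ld <- dprime_with_ci(g1, g2)
  expect_equal(ld$r2, r2_hand, tolerance = 1e-6)
})

test_that("find_blocks recovers a constructed block and nothing else", {
  set.seed(20)
  # chromosome with a 4-SNP complete-LD region flanked by 2 equilibrium SNPs
  pool <- build_haplotype_pool(4, 0.3, ld_level = 1)
  block_g <- sample_pool_dosages(800, pool_minor_ind(pool), pool$freq)
  noise <- cbind(rbinom(800, 2, 0.25), rbinom(800, 2, 0.4))
  co <- make_cohort(cbind(noise[, 1], block_g, noise[, 2]),
                    status = rep(0:1, 400))
  ld <- pairwise_ld(co)
  bl <- find_blocks(ld, co$snps)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$start_index, 2L)
  expect_equal(bl$end_index, 5L)
  expect_equal(bl$n_snps, 4L)
  expect_gte(bl$frac_strong, 0.95)
})

test_that("no blocks from non-informative pairs, and blocks never span chromosomes", {
  pairs <- data.frame(index_i = c(1L, 1L, 2L), index_j = c(2L, 3L, 3L),
                      classification = "non_informative",
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = c("a", "b", "c"), chromosome = "1",
                     position = c(10, 20, 30), stringsAsFactors = FALSE)
  expect_equal(nrow(find_blocks(pairs, snps)), 0L)

  set.seed(22)
  pool <- build_haplotype_pool(2, 0.3, ld_level = 1)
  g1 <- sample_pool_dosages(500, pool_minor_ind(pool), pool$freq)
  g2 <- sample_pool_dosages(500, pool_minor_ind(pool), pool$freq)
  co <- make_cohort(cbind(g1, g2), status = rep(0:1, 250),
                    chrom = c("1", "1", "2", "2"))
  bl <- find_blocks(pairwise_ld(co), co$snps)
  expect_true(all(vapply(seq_len(nrow(bl)), function(r) {
    span <- bl$start_index[r]:bl$end_index[r]
    length(unique(co$snps$chromosome[span])) == 1
  }, logical(1))))
})
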