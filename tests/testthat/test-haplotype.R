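sim_region_cohort <- function(n_case, n_ctrl, pool, seed, beta_snp = NULL) {
  region <- region_from_pool("BLK", "9", pool)
  eff <- if (is.null(beta_snp)) effect_spec()
         else effect_spec(main_effects = beta_snp)
  simulate_cohort(cohort_spec(n_cases = n_case, n_controls = n_ctrl,
                              missing_rate = 0, seed = seed),
                  list(region), eff)
}

test_that("complete-LD blocks collapse to two haplotypes at the allele frequencies", {
  co <- sim_region_cohort(200, 400, build_haplotype_pool(2, 0.3, 1), seed = 2)
  fr <- em_haplotypes(co, c("BLK_s1", "BLK_s2"))
  expect_equal(length(fr$haplotype), 2L)
  q_hat <- sum(co$geno[, 1]) / (2 * nrow(co$geno))
  i_minor <- which(fr$haplotype == "GG")
  expect_equal(fr$freq_overall[i_minor], q_hat, tolerance = 1e-6)
})

test_that("under equilibrium the haplotype frequencies are products of allele frequencies", {
  co <- sim_region_cohort(400, 800, build_haplotype_pool(2, c(0.3, 0.4), 0),
                          seed = 3)
  fr <- em_haplotypes(co, 1:2, pool_min = 0)
  q1 <- sum(co$geno[, 1]) / (2 * nrow(co$geno))
  q2 <- sum(co$geno[, 2]) / (2 * nrow(co$geno))
  i_gg <- which(fr$haplotype == "GG")
  se <- sqrt(q1 * q2 * (1 - q1 * q2) / (2 * nrow(co$geno)))
  expect_lt(abs(fr$freq_overall[i_gg] - q1 * q2), 3 * se + 0.01)
})

test_that("multi-SNP EM attains the likelihood of exhaustive search on tiny data", {
  set.seed(24)
  for (i in 1:8) {
    n <- sample(8:20, 1)
    G <- cbind(sample(0:2, n, TRUE), sample(0:2, n, TRUE))
    if (any(apply(G, 2, function(x) length(unique(x))) < 2)) next
    co <- make_cohort(G, status = rep_len(0:1, n))
    fr <- em_haplotypes(co, 1:2, pool_min = 0)
    expect_gte(fr$loglik, two_snp_grid_max(G[, 1], G[, 2]) - 1e-6)
    # and the multi-SNP EM agrees with the dedicated two-SNP EM
    f2 <- em_two_snp(G[, 1], G[, 2])
    expect_equal(fr$loglik, attr(f2, "loglik"), tolerance = 1e-5)
  }
})

test_that("three-SNP EM dominates random frequency vectors", {
  set.seed(25)
  G <- cbind(sample(0:2, 15, TRUE), sample(0:2, 15, TRUE),
             sample(0:2, 15, TRUE))
  co <- make_cohort(G, status = rep_len(0:1, 15))
  fr <- em_haplotypes(co, 1:3, pool_min = 0)
  # express the EM solution and candidates over all 8 possible haplotypes
  all_haps <- do.call(paste0, expand.grid(0:1, 0:1, 0:1))
  em_freq <- setNames(numeric(8), all_haps)
  key <- vapply(fr$haplotype, function(h)
    paste(as.integer(strsplit(h, "")[[1]] == "G"), collapse = ""),
    character(1))
  em_freq[key] <- fr$freq_overall
  expect_equal(fr$loglik, multi_hap_loglik_oracle(G, em_freq),
               tolerance = 1e-6)
  for (r in 1:200) {
    cand <- setNames(as.numeric(stats::rgamma(8, 1)), all_haps)
    cand <- cand / sum(cand)
    expect_gte(fr$loglik, multi_hap_loglik_oracle(G, cand) - 1e-6)
  }
})

test_that("haplotype chromosome counts are conserved and order-invariant", {
  co <- sim_region_cohort(150, 350, build_haplotype_pool(3, c(0.2, 0.3, 0.4), 0.9),
                          seed = 6)
  fr <- em_haplotypes(co, 1:3)
  expect_equal(sum(fr$freq_overall), 1, tolerance = 1e-6)
  expect_equal(sum(fr$count_cases), 2 * fr$n_cases, tolerance = 1e-3)
  expect_equal(sum(fr$count_controls), 2 * fr$n_controls, tolerance = 1e-3)
  expect_equal(sum(fr$count_cases + fr$count_controls),
               2 * nrow(co$geno), tolerance = 1e-3)
  # permuting the samples changes nothing
  perm <- sample(nrow(co$geno))
  co2 <- subset_cohort(co, samples = perm)
  fr2 <- em_haplotypes(co2, 1:3)
  ord1 <- order(fr$haplotype); ord2 <- order(fr2$haplotype)
  expect_equal(fr$haplotype[ord1], fr2$haplotype[ord2])
  expect_equal(fr$freq_overall[ord1], fr2$freq_overall[ord2],
               tolerance = 1e-9)
})

test_that("blocks wider than the enumeration bound are refused", {
  co <- make_cohort(matrix(rbinom(20 * 13, 2, 0.3), 20, 13),
                    status = rep_len(0:1, 20))
  expect_error(em_haplotypes(co, 1:13), "12")
  expect_error(em_haplotypes(co, 1), "at least 2")
})

test_that("haplotype-specific chi-square matches a published-scale hand computation", {
  # frequencies shaped like the strongest published haplotype signal:
  # F_A = 0.058, F_U = 0.041 on 5,036 case and 15,042 control chromosomes
  fr <- list(haplotype = c("AT", "OTHER"),
             count_cases = c(0.058, 0.942) * 5036,
             count_controls = c(0.041, 0.959) * 15042,
             n_cases = 2518L, n_controls = 7521L)
  ht <- hap_specific_test(fr, "AT")
  tab <- matrix(c(0.058 * 5036, 0.942 * 5036,
                  0.041 * 15042, 0.959 * 15042), 2, byrow = TRUE)
  expect_equal(ht$chi2, pearson_chi2(tab), tolerance = 1e-9)
  # rounded-frequency approximation of the printed 26.830
  expect_equal(ht$chi2, 25.2, tolerance = 0.02)
  expect_lt(ht$p_value, 1e-5)
})

test_that("haplotype-specific chi-square: null case and scale property", {
  fr <- list(haplotype = c("H1", "H2"),
             count_cases = c(30, 70), count_controls = c(60, 140),
             n_cases = 50L, n_controls = 100L)
  ht <- hap_specific_test(fr, "H1")
  expect_equal(ht$chi2, 0, tolerance = 1e-12)
  expect_equal(ht$p_value, 1)
  fr2 <- list(haplotype = c("H1", "H2"),
              count_cases = c(35, 65), count_controls = c(55, 145),
              n_cases = 50L, n_controls = 100L)
  fr2_doubled <- list(haplotype = fr2$haplotype,
                      count_cases = 2 * fr2$count_cases,
                      count_controls = 2 * fr2$count_controls,
                      n_cases = 100L, n_controls = 200L)
  expect_equal(hap_specific_test(fr2_doubled, "H1")$chi2,
               2 * hap_specific_test(fr2, "H1")$chi2, tolerance = 1e-9)
})

test_that("omnibus test: null gives zero chi-square with df = H - 1", {
  fr <- list(haplotype = c("H1", "H2", "H3"),
             count_cases = c(20, 30, 50), count_controls = c(40, 60, 100),
             n_cases = 50L, n_controls = 100L)
  om <- omnibus_test(fr)
  expect_equal(om$chi2, 0, tolerance = 1e-12)
  expect_equal(om$df, 2L)
  expect_error(omnibus_test(list(haplotype = "H1", count_cases = 1,
                                 count_controls = 1)), "at least 2")
})

test_that("a simulated risk haplotype drives the omnibus test", {
  # staircase pool: the minor allele of s1 rides exclusively on haplotype GG,
  # so a per-allele effect at s1 is a haplotype effect of the same size
  pool <- build_haplotype_pool(2, c(0.15, 0.3), ld_level = 1)
  hits <- 0L
  for (s in 1:10) {
    co <- sim_region_cohort(2518, 7521, pool, seed = 400 + s,
                            beta_snp = c(BLK_s1 = 0.4))
    fr <- em_haplotypes(co, 1:2)
    om <- omnibus_test(fr)
    if (om$p_value < 0.001) hits <- hits + 1L
    # the driven haplotype is the block's most significant row
    per <- do.call(rbind, lapply(fr$haplotype, function(h)
      hap_specific_test(fr, h)))
    expect_equal(per$haplotype[which.min(per$p_value)], "GG")
  }
  expect_gte(hits, 9L)
})

test_that("haplotype scan reproduces the published table layout", {
  co <- sim_region_cohort(150, 450, build_haplotype_pool(2, c(0.2, 0.3), 1),
                          seed = 7)
  hs <- haplotype_scan(co, list(c("BLK_s1", "BLK_s2")))
  expect_identical(names(hs), c("SNPS", "HAPLOTYPE", "F_A", "F_U", "CHISQ", "P"))
  expect_equal(hs$HAPLOTYPE[1], "OMNIBUS")
  expect_true(all(diff(hs$F_A[-1][!is.na(hs$F_A[-1])]) <= 0)
              || nrow(hs) <= 3)  # haplotypes in decreasing frequency
})
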