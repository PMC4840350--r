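test_that("haplotype pools hit target frequencies and LD exactly", {
  # single SNP: two one-letter haplotypes at the allele frequencies
  p1 <- build_haplotype_pool(1, 0.3)
  expect_equal(p1$hap[order(p1$hap)], c("A", "B"))
  expect_equal(p1$freq[order(p1$hap)], c(0.7, 0.3))

  # complete LD with equal frequencies: exactly two haplotypes, D' = 1
  p2 <- build_haplotype_pool(2, 0.3, ld_level = 1)
  expect_equal(nrow(p2), 2L)
  ind <- pool_minor_ind(p2)
  pAB <- sum(p2$freq[ind[, 1] == 1 & ind[, 2] == 1])
  d <- pAB - 0.3 * 0.3
  expect_equal(d / min(0.3 * 0.7, 0.7 * 0.3), 1)

  # linkage equilibrium: frequencies are products, D = 0
  p0 <- build_haplotype_pool(2, c(0.2, 0.4), ld_level = 0)
  ind <- pool_minor_ind(p0)
  pAB <- sum(p0$freq[ind[, 1] == 1 & ind[, 2] == 1])
  expect_lt(abs(pAB - 0.2 * 0.4), 1e-9)
  expect_equal(sort(p0$freq), sort(c(0.48, 0.32, 0.12, 0.08)))

  # intermediate LD: realized adjacent D' equals the requested level
  pm <- build_haplotype_pool(3, c(0.2, 0.3, 0.25), ld_level = 0.6)
  ind <- pool_minor_ind(pm)
  q <- as.vector(crossprod(ind, pm$freq))
  expect_equal(q, c(0.2, 0.3, 0.25), tolerance = 1e-12)
  for (j in 1:2) {
    p11 <- sum(pm$freq[ind[, j] == 1 & ind[, j + 1] == 1])
    d <- p11 - q[j] * q[j + 1]
    dmax <- min(q[j] * (1 - q[j + 1]), (1 - q[j]) * q[j + 1])
    expect_equal(d / dmax, 0.6, tolerance = 1e-9)
  }

  expect_error(build_haplotype_pool(2, 0.03), "target_maf")
  expect_error(build_haplotype_pool(2, 0.6), "target_maf")
})

test_that("region_spec enforces the tag-SNP design constraints", {
  pool <- data.frame(hap = c("AA", "GG"), freq = c(0.95, 0.05))
  expect_error(region_spec("G", "1", c("s1", "s2"), c(1, 2), c("A", "A"),
                           c("G", "G"), pool), "MAF")
  bad_sum <- data.frame(hap = c("AA", "GG"), freq = c(0.6, 0.3))
  expect_error(region_spec("G", "1", c("s1", "s2"), c(1, 2), c("A", "A"),
                           c("G", "G"), bad_sum), "sum to 1")
})

test_that("null cohort: case and control allele frequencies agree within 3 SE", {
  cfg <- default_study_config()
  co <- simulate_cohort(cohort_spec(seed = 21), cfg$regions, cfg$effects)
  expect_equal(sum(co$samples$status), 2518L)
  expect_equal(sum(1 - co$samples$status), 7521L)
  case <- co$samples$status == 1
  for (j in seq_len(ncol(co$geno))) {
    d <- co$geno[, j]
    p1 <- mean(d[case], na.rm = TRUE) / 2
    p0 <- mean(d[!case], na.rm = TRUE) / 2
    se <- sqrt(p1 * (1 - p1) / (2 * sum(case)) +
               p0 * (1 - p0) / (2 * sum(!case)))
    expect_lt(abs(p1 - p0), 3 * se + 1e-12)
  }
  # ages respect the truncation bounds; sexes are near-balanced
  expect_true(all(co$samples$age >= 18 & co$samples$age <= 51))
  expect_gt(mean(co$samples$sex), 0.45)
  expect_lt(mean(co$samples$sex), 0.6)
})

test_that("simulation is reproducible and expected dosage matches the pool", {
  cfg <- default_study_config()
  a <- simulate_cohort(cohort_spec(n_cases = 200, n_controls = 600, seed = 3),
                       cfg$regions, cfg$effects)
  b <- simulate_cohort(cohort_spec(n_cases = 200, n_controls = 600, seed = 3),
                       cfg$regions, cfg$effects)
  expect_identical(a$geno, b$geno)
  expect_identical(a$samples, b$samples)

  big <- simulate_cohort(cohort_spec(seed = 6), cfg$regions, cfg$effects)
  q_design <- unlist(lapply(cfg$regions, `[[`, "maf"))
  for (j in seq_len(ncol(big$geno))) {
    d <- big$geno[, j]
    n2 <- 2 * sum(!is.na(d))
    q_hat <- sum(d, na.rm = TRUE) / n2
    se <- sqrt(q_design[j] * (1 - q_design[j]) / n2)
    expect_lt(abs(q_hat - q_design[j]), 4 * se)
  }
})

test_that("an unreachable case quota raises the intercept advice", {
  cfg <- default_study_config()
  expect_error(
    simulate_cohort(cohort_spec(n_cases = 500, n_controls = 10, seed = 1),
                    cfg$regions,
                    effect_spec(intercept = qlogis(1e-5))),
    "intercept")
})

test_that("missingness injection hits the design rate and is seed-stable", {
  cfg <- default_study_config()
  co <- simulate_cohort(cohort_spec(n_cases = 300, n_controls = 900,
                                    missing_rate = 0, seed = 12),
                        cfg$regions, cfg$effects)
  expect_identical(inject_missingness(co$geno, 0, 5), co$geno)

  m1 <- inject_missingness(co$geno, 0.005, seed = 5)
  m2 <- inject_missingness(co$geno, 0.005, seed = 5)
  expect_identical(m1, m2)
  n_entries <- length(co$geno)
  miss <- sum(is.na(m1))
  expect_lt(abs(miss - 0.005 * n_entries),
            3 * sqrt(n_entries * 0.005 * 0.995))
})

test_that("default study design: 35 SNPs, 4 chromosomes, 432 cross pairs, null effects", {
  cfg <- default_study_config()
  snps <- do.call(rbind, lapply(cfg$regions, function(r)
    data.frame(snp_id = r$snp_ids, chromosome = r$chromosome,
               stringsAsFactors = FALSE)))
  expect_equal(nrow(snps), 35L)
  counts <- table(snps$chromosome)
  expect_setequal(names(counts), c("16", "17", "19", "22"))
  expect_equal(unname(counts[c("17", "19", "16", "22")]),
               c(12L, 12L, 8L, 3L), ignore_attr = TRUE)
  m <- nrow(snps)
  expect_equal(choose(m, 2) - sum(choose(counts, 2)), 432)
  expect_equal(cfg$cohort$n_cases, 2518L)
  expect_equal(cfg$cohort$n_controls, 7521L)
  expect_length(cfg$effects$main_effects, 0)
  expect_equal(nrow(cfg$effects$interaction_effects), 0L)
})

test_that("a simulated per-allele OR is recovered by the unadjusted allelic test", {
  cfg <- default_study_config()
  eff <- effect_spec(main_effects = c(CACNG4_s2 = log(1.5)))
  ors <- vapply(1:5, function(s) {
    co <- simulate_cohort(cohort_spec(seed = 100 + s), cfg$regions, eff)
    d <- co$geno[, "CACNG4_s2"]
    y <- co$samples$status
    cc <- vapply(0:2, function(k) sum(d == k & y == 1, na.rm = TRUE), 0)
    ct <- vapply(0:2, function(k) sum(d == k & y == 0, na.rm = TRUE), 0)
    allelic_test(cc, ct)$or
  }, numeric(1))
  expect_true(all(abs(ors - 1.5) < 0.15))
})

test_that("single-marker P values are uniform under the null design", {
  # 200 independent small null cohorts, one additive Wald P each
  region <- region_from_pool("NUL", "1", build_haplotype_pool(1, 0.3))
  ps <- vapply(1:200, function(s) {
    co <- simulate_cohort(cohort_spec(n_cases = 100, n_controls = 300,
                                      missing_rate = 0, seed = 5000 + s),
                          list(region), effect_spec())
    fit <- fit_logistic(cbind(1, geno = co$geno[, 1]), co$samples$status)
    fit$p_values[["geno"]]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
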