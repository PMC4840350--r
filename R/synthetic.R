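#' Cohort design specification
#'
#' Study-design constants for the synthetic generator. Defaults emulate a
#' large candidate-gene case-control design: 2,518 cases and 7,521 controls,
#' ~0.5% missing genotype calls, ages 18-51 (mean ~37.5, SD ~9.5), and a
#' slight excess of females.
#'
#' @param n_cases,n_controls retained group sizes.
#' @param missing_rate per-entry missing-call probability.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age model (years).
#' @param female_fraction probability that a sample is female (sex code 1).
#' @param seed integer seed governing all generator randomness.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 2518, n_controls = 7521,
                        missing_rate = 0.005,
                        age_mean = 37.5, age_sd = 9.5,
                        age_min = 18, age_max = 51,
                        female_fraction = 0.519, seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0,
            missing_rate >= 0, missing_rate < 1,
            age_min < age_max, female_fraction >= 0, female_fraction <= 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 missing_rate = missing_rate,
                 age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 female_fraction = female_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Effect specification for the generating logistic model
#'
#' Disease status is drawn from
#' `logit P(case) = intercept + sum(main) + sum(interaction) + sex + age`
#' where main effects are per-minor-allele log odds ratios on additive
#' dosages and interaction effects multiply the two additive dosages.
#'
#' @param main_effects named numeric vector: snp_id -> per-allele log OR.
#' @param interaction_effects data.frame with columns `snp1`, `snp2`, `beta`
#'   (log OR on the dosage product), or NULL.
#' @param sex_effect,age_effect log odds per unit (sex code / year of age).
#' @param intercept baseline log odds; the default targets a ~25% case draw
#'   so the 2518/7521 quotas fill at comparable rates.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(main_effects = numeric(0),
                        interaction_effects = NULL,
                        sex_effect = 0, age_effect = 0,
                        intercept = qlogis(0.25)) {
  if (is.null(interaction_effects)) {
    interaction_effects <- data.frame(snp1 = character(0), snp2 = character(0),
                                      beta = numeric(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp1", "snp2", "beta") %in% names(interaction_effects)))
  structure(list(main_effects = main_effects,
                 interaction_effects = interaction_effects,
                 sex_effect = sex_effect, age_effect = age_effect,
                 intercept = intercept),
            class = "effect_spec")
}

#' Gene-region specification
#'
#' A region is a run of SNPs on one chromosome whose two-per-individual
#' haplotypes are drawn from a fixed pool. Pool frequencies imply each SNP's
#' allele frequency; the tag-SNP design constraints (MAF > 0.05,
#' heterozygosity > 0.2 under random mating) are enforced here.
#'
#' @param gene region label.
#' @param chromosome chromosome label.
#' @param snp_ids,positions,major_allele,minor_allele per-SNP panel fields.
#' @param haplotypes data.frame with columns `hap` (allele string over the
#'   region's bases, length = number of SNPs) and `freq` (sums to 1).
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(gene, chromosome, snp_ids, positions,
                        major_allele, minor_allele, haplotypes) {
  k <- length(snp_ids)
  stopifnot(length(positions) == k, length(major_allele) == k,
            length(minor_allele) == k,
            all(c("hap", "freq") %in% names(haplotypes)))
  if (abs(sum(haplotypes$freq) - 1) > 1e-9)
    stop("haplotype frequencies must sum to 1")
  if (any(nchar(haplotypes$hap) != k))
    stop("every haplotype string must have length n_snps")
  if (any(major_allele == minor_allele))
    stop("major and minor alleles must differ")
  hap_mat <- do.call(rbind, strsplit(haplotypes$hap, ""))
  minor_ind <- matrix(0L, nrow(hap_mat), k)
  for (j in seq_len(k)) {
    ok <- hap_mat[, j] %in% c(major_allele[j], minor_allele[j])
    if (!all(ok)) stop("haplotype allele not in {major, minor} at SNP ", snp_ids[j])
    minor_ind[, j] <- as.integer(hap_mat[, j] == minor_allele[j])
  }
  q <- as.vector(crossprod(minor_ind, haplotypes$freq))
  if (any(q <= 0.05 | q > 0.5 + 1e-9))
    stop("implied per-SNP MAF must be in (0.05, 0.5]; got ",
         paste(signif(q, 3), collapse = ", "))
  het <- 2 * q * (1 - q)
  if (any(het <= 0.2))
    stop("implied per-SNP heterozygosity must exceed 0.2")
  structure(list(gene = gene, chromosome = chromosome,
                 snp_ids = snp_ids, positions = positions,
                 major_allele = major_allele, minor_allele = minor_allele,
                 haplotypes = haplotypes, minor_ind = minor_ind,
                 maf = q),
            class = "region_spec")
}

#' Build a region haplotype pool with target allele frequencies and LD
#'
#' Constructs haplotype frequencies by a first-order chain across loci:
#' each SNP's minor-allele frequency equals its target exactly, and each
#' adjacent pair has |D'| equal to `ld_level` exactly (positive association
#' between minor alleles). `ld_level = 1` with equal frequencies collapses
#' the pool to two haplotypes; `ld_level = 0` gives linkage equilibrium
#' (frequencies are products of allele frequencies).
#'
#' @param n_snps number of SNPs in the region.
#' @param target_maf numeric vector (recycled) of per-SNP minor allele
#'   frequencies, each in (0.05, 0.5].
#' @param ld_level target adjacent-pair D' in `[0, 1]`.
#' @param major_allele,minor_allele per-SNP base labels (recycled).
#' @return data.frame with columns `hap` (allele string) and `freq`,
#'   positive frequencies only.
#' @export
build_haplotype_pool <- function(n_snps, target_maf, ld_level = 0.9,
                                 major_allele = "A", minor_allele = "B") {
  stopifnot(n_snps >= 1, ld_level >= 0, ld_level <= 1)
  if (n_snps > 16) stop("haplotype pool enumeration limited to 16 SNPs")
  q <- rep_len(target_maf, n_snps)
  if (any(q <= 0.05 | q > 0.5))
    stop("target_maf must lie in (0.05, 0.5]")
  major_allele <- rep_len(major_allele, n_snps)
  minor_allele <- rep_len(minor_allele, n_snps)

  # chain over loci: minor-allele indicator m_j with P(m_1) = q_1 and
  # adjacent-pair D = ld_level * Dmax (minor-minor association positive)
  states <- as.matrix(expand.grid(rep(list(0:1), n_snps))[, n_snps:1, drop = FALSE])
  logp <- ifelse(states[, 1] == 1, log(q[1]), log(1 - q[1]))
  for (j in seq_len(n_snps - 1)) {
    d_max <- min(q[j] * (1 - q[j + 1]), (1 - q[j]) * q[j + 1])
    d <- ld_level * d_max
    p11 <- q[j] * q[j + 1] + d
    t11 <- p11 / q[j]                       # P(minor at j+1 | minor at j)
    t01 <- (q[j + 1] - p11) / (1 - q[j])    # P(minor at j+1 | major at j)
    if (t11 < -1e-12 || t11 > 1 + 1e-12 || t01 < -1e-12 || t01 > 1 + 1e-12)
      stop("infeasible MAF/LD combination at SNPs ", j, "-", j + 1)
    pr <- ifelse(states[, j] == 1,
                 ifelse(states[, j + 1] == 1, t11, 1 - t11),
                 ifelse(states[, j + 1] == 1, t01, 1 - t01))
    logp <- logp + log(pmax(pr, 0))
  }
  freq <- exp(logp)
  keep <- freq > 1e-12
  states <- states[keep, , drop = FALSE]
  freq <- freq[keep] / sum(freq[keep])
  hap <- vapply(seq_len(nrow(states)), function(i) {
    paste(ifelse(states[i, ] == 1, minor_allele, major_allele), collapse = "")
  }, character(1))
  data.frame(hap = hap, freq = freq, stringsAsFactors = FALSE)
}

# draw ages from a truncated normal by rejection, rounded to whole years
.draw_ages <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Simulate a case-control cohort
#'
#' Individuals are generated prospectively: two haplotypes per region are
#' drawn independently from the region pools, covariates are drawn from the
#' design model, and disease status is Bernoulli with the logistic
#' probability implied by `effects`. Sampling continues until exactly
#' `n_cases` cases and `n_controls` controls are retained (case-control
#' sampling preserves odds ratios). Missing calls are then injected at the
#' design rate. Fully reproducible given `cohort$seed` (status/genotype
#' stream uses `seed`, the missingness mask `seed + 1`).
#'
#' @param cohort a [cohort_spec()].
#' @param regions list of [region_spec()] objects.
#' @param effects an [effect_spec()]; all referenced SNP ids must exist.
#' @return A [new_cohort()] object (dosages count each SNP's designed minor
#'   allele).
#' @export
simulate_cohort <- function(cohort = cohort_spec(),
                            regions = default_study_config()$regions,
                            effects = effect_spec()) {
  snps <- do.call(rbind, lapply(regions, function(r) {
    data.frame(snp_id = r$snp_ids, chromosome = r$chromosome,
               position = r$positions, allele_a = r$major_allele,
               allele_b = r$minor_allele, gene = r$gene,
               stringsAsFactors = FALSE)
  }))
  m <- nrow(snps)
  eff_ids <- c(names(effects$main_effects),
               effects$interaction_effects$snp1,
               effects$interaction_effects$snp2)
  unknown <- setdiff(eff_ids, snps$snp_id)
  if (length(unknown))
    stop("effect references unknown SNP id(s): ", paste(unknown, collapse = ", "))

  beta <- setNames(numeric(m), snps$snp_id)
  beta[names(effects$main_effects)] <- effects$main_effects
  int <- effects$interaction_effects
  int_i <- match(int$snp1, snps$snp_id)
  int_j <- match(int$snp2, snps$snp_id)

  n_need_case <- cohort$n_cases
  n_need_ctrl <- cohort$n_controls
  n_total <- n_need_case + n_need_ctrl
  geno_keep <- matrix(NA_integer_, 0, m)
  status_keep <- sex_keep <- age_keep <- integer(0)
  draws <- 0L
  max_draws <- 500L * n_total

  .with_seed(cohort$seed, {
    while (n_need_case > 0 || n_need_ctrl > 0) {
      B <- min(max(2L * (n_need_case + n_need_ctrl), 1000L), 200000L)
      draws <- draws + B
      if (draws > max_draws)
        stop("case/control quota unreachable after ", draws,
             " draws; adjust the intercept of the generating model")
      g <- matrix(NA_integer_, B, m)
      col0 <- 0L
      for (r in regions) {
        k <- length(r$snp_ids)
        h1 <- sample.int(nrow(r$minor_ind), B, replace = TRUE,
                         prob = r$haplotypes$freq)
        h2 <- sample.int(nrow(r$minor_ind), B, replace = TRUE,
                         prob = r$haplotypes$freq)
        g[, col0 + seq_len(k)] <- r$minor_ind[h1, , drop = FALSE] +
          r$minor_ind[h2, , drop = FALSE]
        col0 <- col0 + k
      }
      sex <- rbinom(B, 1, cohort$female_fraction)
      age <- .draw_ages(B, cohort$age_mean, cohort$age_sd,
                        cohort$age_min, cohort$age_max)
      eta <- effects$intercept + drop(g %*% beta) +
        effects$sex_effect * sex + effects$age_effect * age
      if (nrow(int)) {
        for (r in seq_len(nrow(int)))
          eta <- eta + int$beta[r] * g[, int_i[r]] * g[, int_j[r]]
      }
      y <- rbinom(B, 1, plogis(eta))
      take_case <- which(y == 1)[seq_len(min(n_need_case, sum(y == 1)))]
      take_ctrl <- which(y == 0)[seq_len(min(n_need_ctrl, sum(y == 0)))]
      take <- sort(c(take_case, take_ctrl))
      geno_keep <- rbind(geno_keep, g[take, , drop = FALSE])
      status_keep <- c(status_keep, y[take])
      sex_keep <- c(sex_keep, sex[take])
      age_keep <- c(age_keep, age[take])
      n_need_case <- n_need_case - length(take_case)
      n_need_ctrl <- n_need_ctrl - length(take_ctrl)
    }
  })

  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n_total)),
    status = as.integer(status_keep), sex = as.integer(sex_keep),
    age = as.integer(age_keep), stringsAsFactors = FALSE)
  out <- new_cohort(snps, samples, geno_keep,
                    counted_allele = snps$allele_b)
  if (cohort$missing_rate > 0)
    out <- inject_missingness(out, cohort$missing_rate, cohort$seed + 1L)
  out
}

#' Set genotype entries missing at random
#'
#' Each entry is independently set missing with probability `rate`; already
#' missing entries stay missing. Reproducible given `seed`.
#'
#' @param x a [new_cohort()] object or a dosage matrix.
#' @param rate missing probability in `[0, 1)`.
#' @param seed integer seed.
#' @return Same type as `x`.
#' @export
inject_missingness <- function(x, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  geno <- if (inherits(x, "cohort")) x$geno else x
  if (rate > 0) {
    mask <- .with_seed(seed, matrix(runif(length(geno)) < rate,
                                    nrow(geno), ncol(geno)))
    geno[mask] <- NA_integer_
  }
  if (inherits(x, "cohort")) { x$geno <- geno; x } else geno
}

.default_bases <- list(c("A", "G"), c("C", "T"), c("G", "T"), c("A", "C"))
.default_mafs <- c(0.18, 0.30, 0.42, 0.25, 0.35, 0.15, 0.45, 0.22)

# one region with cycled MAFs/bases and the given LD level; MAFs are sorted
# ascending so that at ld_level = 1 minor alleles nest (staircase pool) and
# every within-region pair has D' = 1, the structure of a real LD block
.make_region <- function(gene, chromosome, n_snps, start_pos,
                         ld_level = 1, spacing = 3000L) {
  q <- sort(rep_len(.default_mafs, n_snps))
  bases <- .default_bases[((seq_len(n_snps) - 1) %% 4) + 1]
  major <- vapply(bases, `[`, character(1), 1)
  minor <- vapply(bases, `[`, character(1), 2)
  pool <- build_haplotype_pool(n_snps, q, ld_level,
                               major_allele = major, minor_allele = minor)
  region_spec(gene = gene, chromosome = chromosome,
              snp_ids = sprintf("%s_s%d", gene, seq_len(n_snps)),
              positions = start_pos + spacing * (seq_len(n_snps) - 1L),
              major_allele = major, minor_allele = minor,
              haplotypes = pool)
}

#' Default synthetic study configuration
#'
#' A 35-SNP panel over 8 gamma-subunit gene regions on 4 chromosomes with
#' per-chromosome SNP counts (12, 12, 8, 3) for chromosomes 17, 19, 16, 22 -
#' a distribution that yields exactly 432 cross-chromosome SNP pairs - with
#' default cohort sizes 2,518 cases / 7,521 controls and zero effects (a
#' null cohort). By default within-region LD is complete (D' = 1 between
#' every pair, few-haplotype staircase pools) so the Gabriel rule can call
#' blocks; lower `ld_level` values weaken the association and, at large n,
#' prevent strong-LD calls entirely (the D' confidence interval then
#' excludes the 0.98 upper bound).
#'
#' @param ld_level adjacent-pair D' within each region.
#' @return list with elements `cohort` ([cohort_spec()]), `regions` (list of
#'   [region_spec()]), `effects` ([effect_spec()]).
#' @export
default_study_config <- function(ld_level = 1) {
  regions <- list(
    .make_region("CACNG1", "17", 4, 65040000L, ld_level),
    .make_region("CACNG4", "17", 4, 65140000L, ld_level),
    .make_region("CACNG5", "17", 4, 65240000L, ld_level),
    .make_region("CACNG6", "19", 4, 54490000L, ld_level),
    .make_region("CACNG7", "19", 4, 54590000L, ld_level),
    .make_region("CACNG8", "19", 4, 54690000L, ld_level),
    .make_region("CACNG3", "16", 8, 24266000L, ld_level),
    .make_region("CACNG2", "22", 3, 36960000L, ld_level))
  list(cohort = cohort_spec(), regions = regions, effects = effect_spec())
}
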