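# ---- fixture builders -------------------------------------------------------

# wrap a dosage matrix into a cohort; SNPs get A (major) / G (minor) alleles
# and dosages are taken as minor-allele counts
make_cohort <- function(geno, status, chrom = NULL, sex = NULL, age = NULL,
                        positions = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  snps <- data.frame(
    snp_id = sprintf("snp%02d", seq_len(m)),
    chromosome = if (is.null(chrom)) rep("1", m) else rep_len(chrom, m),
    position = if (is.null(positions)) 1000L * seq_len(m) else positions,
    allele_a = "A", allele_b = "G", gene = "", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("I%04d", seq_len(n)),
    status = as.integer(status),
    sex = if (is.null(sex)) rep(0L, n) else as.integer(sex),
    age = if (is.null(age)) rep(30L, n) else as.integer(age),
    stringsAsFactors = FALSE)
  new_cohort(snps, samples, geno, counted_allele = snps$allele_b)
}

# sample n diplotypes from a haplotype pool given as minor-indicator matrix
# + frequencies; returns the dosage matrix
sample_pool_dosages <- function(n, minor_ind, freq) {
  h1 <- sample.int(nrow(minor_ind), n, replace = TRUE, prob = freq)
  h2 <- sample.int(nrow(minor_ind), n, replace = TRUE, prob = freq)
  minor_ind[h1, , drop = FALSE] + minor_ind[h2, , drop = FALSE]
}

# minor-indicator matrix of a build_haplotype_pool() result (B = minor)
pool_minor_ind <- function(pool, minor = "B") {
  hm <- do.call(rbind, strsplit(pool$hap, ""))
  matrix(as.integer(hm == minor), nrow(hm), ncol(hm))
}

# small single-region study: k SNPs, one chromosome, given pool
region_from_pool <- function(gene, chrom, pool, start = 1e6) {
  k <- nchar(pool$hap[1])
  region_spec(gene, chrom, sprintf("%s_s%d", gene, 1:k),
              as.integer(start + 3000 * (0:(k - 1))),
              major_allele = rep("A", k), minor_allele = rep("G", k),
              haplotypes = data.frame(
                hap = gsub("B", "G", pool$hap), freq = pool$freq))
}

# ---- independent oracles ----------------------------------------------------

# exact HWE P by direct enumeration with the log-gamma multinomial formula
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (rare == 0) return(1)
  h_vals <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logp <- vapply(h_vals, function(h) {
    n1 <- (rare - h) / 2; n2 <- n - n1 - h
    lgamma(n + 1) - lgamma(n1 + 1) - lgamma(h + 1) - lgamma(n2 + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[match(n_het, h_vals)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Pearson chi-square computed cell by cell
pearson_chi2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# two-SNP genotype log-likelihood at haplotype frequencies (AB, Ab, aB, ab)
two_snp_loglik_oracle <- function(f, g1, g2) {
  pr <- matrix(0, 3, 3)
  pr[1, 1] <- f[4]^2;          pr[1, 2] <- 2 * f[3] * f[4]; pr[1, 3] <- f[3]^2
  pr[2, 1] <- 2 * f[2] * f[4]; pr[2, 2] <- 2 * (f[1] * f[4] + f[2] * f[3])
  pr[2, 3] <- 2 * f[1] * f[3]
  pr[3, 1] <- f[2]^2;          pr[3, 2] <- 2 * f[1] * f[2]; pr[3, 3] <- f[1]^2
  ll <- 0
  for (i in 0:2) for (j in 0:2) {
    ct <- sum(g1 == i & g2 == j)
    if (ct > 0) {
      if (pr[i + 1, j + 1] <= 0) return(-Inf)
      ll <- ll + ct * log(pr[i + 1, j + 1])
    }
  }
  ll
}

# best two-SNP log-likelihood over a fine grid of the free haplotype
# frequency p_AB, margins held at the observed allele frequencies
two_snp_grid_max <- function(g1, g2, step = 0.001) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  pA <- sum(g1) / (2 * n); pB <- sum(g2) / (2 * n)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  best <- -Inf
  for (pAB in seq(lo, hi, by = step)) {
    f <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    if (any(f < 0)) next
    best <- max(best, two_snp_loglik_oracle(f, g1, g2))
  }
  best
}

# log-likelihood of unphased multilocus genotypes at haplotype frequencies
# given as a named vector (names = allele strings of 0/1 minor indicators)
multi_hap_loglik_oracle <- function(G, freq) {
  haps <- names(freq)
  k <- ncol(G)
  ll <- 0
  for (r in seq_len(nrow(G))) {
    g <- G[r, ]
    tot <- 0
    for (a in seq_along(haps)) for (b in a:length(haps)) {
      h1 <- as.integer(strsplit(haps[a], "")[[1]])
      h2 <- as.integer(strsplit(haps[b], "")[[1]])
      if (all(h1 + h2 == g))
        tot <- tot + freq[a] * freq[b] * if (a == b) 1 else 2
    }
    if (tot <= 0) return(-Inf)
    ll <- ll + log(tot)
  }
  unname(as.numeric(ll))
}

# hand inverse-variance pooling (fixed) and DerSimonian-Laird tau2
meta_oracle <- function(log_or, se) {
  w <- 1 / se^2
  mu <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - mu)^2)
  k <- length(log_or)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_r <- 1 / (se^2 + tau2)
  mu_r <- sum(w_r * log_or) / sum(w_r)
  list(fixed = mu, se_fixed = sqrt(1 / sum(w)), q = q, tau2 = tau2,
       random = mu_r, se_random = sqrt(1 / sum(w_r)))
}
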