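#' Enumerate cross-chromosome SNP pairs
#'
#' All unordered pairs of panel SNPs lying on different chromosomes,
#' ordered by (index_i, index_j). Pairs on the same chromosome are removed
#' from the interaction scan.
#'
#' @param snps the cohort's SNP table.
#' @return data.frame: `index_i`, `index_j`, `snp_i`, `snp_j`, `chrom_i`,
#'   `chrom_j` (zero rows if all SNPs share a chromosome).
#' @export
enumerate_cross_chrom_pairs <- function(snps) {
  m <- nrow(snps)
  if (m < 2) {
    idx <- matrix(integer(0), 2, 0)
  } else {
    idx <- combn(m, 2)
    differ <- snps$chromosome[idx[1, ]] != snps$chromosome[idx[2, ]]
    idx <- idx[, differ, drop = FALSE]
  }
  data.frame(index_i = idx[1, ], index_j = idx[2, ],
             snp_i = snps$snp_id[idx[1, ]], snp_j = snps$snp_id[idx[2, ]],
             chrom_i = snps$chromosome[idx[1, ]],
             chrom_j = snps$chromosome[idx[2, ]],
             stringsAsFactors = FALSE)
}

# design matrix and outcome for one pair: columns
# (intercept, g_i, g_j, g_i*g_j [, sex, age]); complete-case rows
.pair_design <- function(cohort, i, j, adjust) {
  g1 <- as.numeric(cohort$geno[, i])
  g2 <- as.numeric(cohort$geno[, j])
  smp <- cohort$samples
  X <- cbind(intercept = 1, g1 = g1, g2 = g2, g1g2 = g1 * g2)
  if (adjust) X <- cbind(X, sex = smp$sex, age = smp$age)
  keep <- complete.cases(X)
  list(X = X[keep, , drop = FALSE], y = smp$status[keep], rows = which(keep))
}

#' Two-locus interaction test
#'
#' Fits `logit P(case) = b0 + b1 g_i + b2 g_j + b3 g_i g_j (+ sex + age)`
#' with additive (0/1/2 minor-allele) coding at both loci and tests the
#' interaction coefficient b3 with a two-sided Wald test;
#' `OR_int = exp(b3)`.
#'
#' @param cohort a [new_cohort()] object.
#' @param snp_i,snp_j SNP ids or panel indices.
#' @param adjust include sex and age covariates.
#' @return One-row data.frame: `snp_i`, `snp_j`, `b1`, `b2`, `b3`, `se_b3`,
#'   `or_interaction`, `ci95_low`, `ci95_high`, `p_nominal`, `n_used`,
#'   `converged`.
#' @export
interaction_test <- function(cohort, snp_i, snp_j, adjust = TRUE) {
  i <- if (is.character(snp_i)) match(snp_i, cohort$snps$snp_id) else snp_i
  j <- if (is.character(snp_j)) match(snp_j, cohort$snps$snp_id) else snp_j
  if (is.na(i) || is.na(j)) stop("unknown SNP id")
  d <- .pair_design(cohort, i, j, adjust)
  fit <- tryCatch(fit_logistic(d$X, d$y), error = function(e) NULL)
  z <- qnorm(0.975)
  if (is.null(fit) || !fit$converged) {
    co <- if (is.null(fit)) rep(NA_real_, 4) else fit$coefficients
    return(data.frame(snp_i = cohort$snps$snp_id[i],
                      snp_j = cohort$snps$snp_id[j],
                      b1 = co[["g1"]] %||% NA_real_, b2 = co[["g2"]] %||% NA_real_,
                      b3 = NA_real_, se_b3 = NA_real_,
                      or_interaction = NA_real_, ci95_low = NA_real_,
                      ci95_high = NA_real_, p_nominal = NA_real_,
                      n_used = length(d$y), converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  b3 <- fit$coefficients[["g1g2"]]; s3 <- fit$se[["g1g2"]]
  data.frame(snp_i = cohort$snps$snp_id[i], snp_j = cohort$snps$snp_id[j],
             b1 = fit$coefficients[["g1"]], b2 = fit$coefficients[["g2"]],
             b3 = b3, se_b3 = s3, or_interaction = exp(b3),
             ci95_low = exp(b3 - z * s3), ci95_high = exp(b3 + z * s3),
             p_nominal = fit$p_values[["g1g2"]],
             n_used = fit$n_used, converged = TRUE, stringsAsFactors = FALSE)
}

#' Exhaustive epistasis scan with max-statistic permutation correction
#'
#' Computes the nominal interaction test for every pair, then builds the
#' family-wise null distribution by shuffling case-control labels against
#' the joint (genotype, sex, age) rows `n_perm` times, re-testing every
#' pair, and recording each replicate's most significant nominal P. The
#' corrected P for a pair is `(1 + #\{replicates with min P <= observed
#' P\}) / (1 + n_perm)` (add-one form, so no corrected P is exactly zero).
#' Non-converged fits contribute no min-P candidate; a replicate in which
#' every fit fails is re-drawn (with a warning after 10 redraws). Bit
#' reproducible given `seed`.
#'
#' @param cohort a [new_cohort()] object.
#' @param pairs an [enumerate_cross_chrom_pairs()] data.frame.
#' @param n_perm permutation count (default 1000); 0 skips correction and
#'   leaves `p_perm` as NA.
#' @param seed integer seed for the label shuffles.
#' @param adjust include sex and age covariates.
#' @return list: `results` (the [interaction_test()] rows plus `p_perm`)
#'   and `null` (list: `n_permutations`, `min_p_values`, `seed`).
#' @export
permutation_scan <- function(cohort, pairs, n_perm = 1000L, seed = 1L,
                             adjust = TRUE) {
  if (!nrow(pairs)) stop("no SNP pairs to test")
  n_perm <- as.integer(n_perm)
  designs <- lapply(seq_len(nrow(pairs)), function(r)
    .pair_design(cohort, pairs$index_i[r], pairs$index_j[r], adjust))
  obs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r)
    interaction_test(cohort, pairs$index_i[r], pairs$index_j[r], adjust)))
  obs <- cbind(pairs[, c("index_i", "index_j")], obs)

  min_p <- numeric(0)
  if (n_perm >= 1) {
    n <- nrow(cohort$samples)
    status <- as.numeric(cohort$samples$status)
    scan_perms <- function(perm_idx) {
      # rows = pairs, cols = replicates; one compiled call per pair
      P <- matrix(NA_real_, length(designs), ncol(perm_idx))
      for (r in seq_along(designs)) {
        d <- designs[[r]]
        Y <- matrix(status[perm_idx[d$rows, , drop = FALSE]],
                    nrow = length(d$rows))
        P[r, ] <- .irls_perm_pvals(d$X, Y, 4L, 1e-8, 25L)
      }
      P
    }
    min_p <- rep(NA_real_, n_perm)
    .with_seed(seed, {
      P <- scan_perms(vapply(seq_len(n_perm), function(b) sample.int(n),
                             integer(n)))
      min_p <- suppressWarnings(apply(P, 2, min, na.rm = TRUE))
      redraws <- 0L
      while (any(!is.finite(min_p))) {  # replicates where every fit failed
        bad <- which(!is.finite(min_p))
        redraws <- redraws + length(bad)
        if (redraws >= 10L)
          warning("10 or more permutation replicates re-drawn (all fits failed)")
        P <- scan_perms(vapply(bad, function(b) sample.int(n), integer(n)))
        min_p[bad] <- suppressWarnings(apply(P, 2, min, na.rm = TRUE))
        if (redraws > 10L * n_perm) stop("permutation replicates keep failing")
      }
    })
    obs$p_perm <- vapply(obs$p_nominal, function(p) {
      if (is.na(p)) return(NA_real_)
      (1 + sum(min_p <= p)) / (1 + n_perm)
    }, numeric(1))
  } else {
    obs$p_perm <- NA_real_
  }
  list(results = obs,
       null = list(n_permutations = n_perm, min_p_values = min_p,
                   seed = seed))
}

#' Case percentage by two-locus genotype combination
#'
#' For each of the nine dosage combinations of two SNPs, the percentage of
#' cases among complete-case samples with that combination, plus the
#' per-locus marginal percentages and the overall case percentage (the
#' dotted-line reference of a combination plot). Empty cells are `NA`,
#' never 0.
#'
#' @param cohort a [new_cohort()] object.
#' @param snp_i,snp_j SNP ids or panel indices.
#' @return list: `table` (3x3 case percentages, rows = dosage of `snp_i`),
#'   `n` (3x3 combination counts), `marginal_i`, `marginal_j`,
#'   `overall_pct`.
#' @export
genotype_combo_summary <- function(cohort, snp_i, snp_j) {
  i <- if (is.character(snp_i)) match(snp_i, cohort$snps$snp_id) else snp_i
  j <- if (is.character(snp_j)) match(snp_j, cohort$snps$snp_id) else snp_j
  g1 <- cohort$geno[, i]; g2 <- cohort$geno[, j]
  y <- cohort$samples$status
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]; y <- y[keep]
  tab <- nn <- matrix(NA_real_, 3, 3,
                      dimnames = list(paste0(cohort$snps$snp_id[i], "=", 0:2),
                                      paste0(cohort$snps$snp_id[j], "=", 0:2)))
  for (a in 0:2) for (b in 0:2) {
    sel <- g1 == a & g2 == b
    nn[a + 1, b + 1] <- sum(sel)
    if (any(sel)) tab[a + 1, b + 1] <- 100 * mean(y[sel])
  }
  marg <- function(g) vapply(0:2, function(a)
    if (any(g == a)) 100 * mean(y[g == a]) else NA_real_, numeric(1))
  list(table = tab, n = nn, marginal_i = marg(g1), marginal_j = marg(g2),
       overall_pct = 100 * mean(y))
}
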