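# genotype-class log-likelihood for a pair of SNPs under random mating,
# given the four haplotype frequencies (AB, Ab, aB, ab); `counts` is the
# 3x3 table of dosage combinations (rows = dosage at SNP 1).
.two_snp_loglik <- function(freqs, counts) {
  pAB <- freqs[1]; pAb <- freqs[2]; paB <- freqs[3]; pab <- freqs[4]
  probs <- matrix(0, 3, 3)
  probs[1, 1] <- pab^2
  probs[1, 2] <- 2 * paB * pab
  probs[1, 3] <- paB^2
  probs[2, 1] <- 2 * pAb * pab
  probs[2, 2] <- 2 * (pAB * pab + pAb * paB)
  probs[2, 3] <- 2 * pAB * paB
  probs[3, 1] <- pAb^2
  probs[3, 2] <- 2 * pAB * pAb
  probs[3, 3] <- pAB^2
  if (any(counts > 0 & probs <= 0)) return(-Inf)
  sum(counts[counts > 0] * log(probs[counts > 0]))
}

#' EM estimation of two-SNP haplotype frequencies from unphased genotypes
#'
#' The only phase-ambiguous class is the double heterozygote; the EM splits
#' it between the coupling (AB/ab) and repulsion (Ab/aB) phases at each
#' step. Initialised at linkage equilibrium, iterated until the largest
#' frequency change falls below `tol`.
#'
#' @param g1,g2 minor-allele dosage columns over the same samples.
#' @param tol convergence tolerance (default 1e-9).
#' @param max_iter iteration cap (default 1000).
#' @return Named numeric `c(AB, Ab, aB, ab)` (A/B = minor alleles) with
#'   attributes `loglik`, `loglik_trace`, `n`, `n_iter`, `counts`.
#' @export
em_two_snp <- function(g1, g2, tol = 1e-9, max_iter = 1000L) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n == 0) stop("no complete genotype pairs")
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    stop("monomorphic SNP: haplotype frequencies (and D') undefined")
  counts <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) counts[i + 1, j + 1] <- sum(g1 == i & g2 == j)

  pA <- sum(g1) / (2 * n); pB <- sum(g2) / (2 * n)
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  n_dh <- counts[2, 2]
  # fixed (phase-unambiguous) haplotype contributions
  base <- c(AB = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3],
            Ab = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
            aB = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
            ab = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1])
  trace <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    w <- if (denom > 0) f["AB"] * f["ab"] / denom else 0.5
    expected <- base + n_dh * c(w, 1 - w, 1 - w, w)
    f_new <- expected / (2 * n)
    trace <- c(trace, .two_snp_loglik(f_new, counts))
    if (max(abs(f_new - f)) < tol || it >= max_iter) { f <- f_new; break }
    f <- f_new
  }
  structure(f, loglik = .two_snp_loglik(f, counts), loglik_trace = trace,
            n = n, n_iter = it, counts = counts)
}

# D, Dmax, D' and r2 from the four haplotype frequencies
.ld_coefficients <- function(f) {
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  d <- f[1] - pA * pB
  d_max <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  list(d = unname(d),
       d_prime = if (d_max > 0) unname(abs(d) / d_max) else NA_real_,
       r2 = unname(d^2 / (pA * (1 - pA) * pB * (1 - pB))),
       pA = unname(pA), pB = unname(pB), d_max = unname(d_max))
}

#' Pairwise D' with likelihood-based 95% confidence bounds
#'
#' Estimates haplotype frequencies by [em_two_snp()], computes D, D' and
#' r2, then evaluates the genotype likelihood on a D' grid over `[0, 1]`
#' (step `grid_step`, allele frequencies held at their MLEs, sign of D
#' fixed at the estimate). The normalised likelihood is accumulated across
#' the grid: `ci_low` is the largest grid value with at most 5% cumulative
#' likelihood below it, `ci_high` the smallest grid value reaching 95%
#' cumulative likelihood. Pairs with a monomorphic member are returned as
#' `non_informative` with missing estimates.
#'
#' @param g1,g2 minor-allele dosage columns over the same samples.
#' @param grid_step D' grid resolution (default 0.01).
#' @return One-row data.frame: `d`, `d_prime`, `r2`, `ci_low`, `ci_high`,
#'   `n`, `classification` (see [classify_pair()]).
#' @export
dprime_with_ci <- function(g1, g2, grid_step = 0.01) {
  f <- tryCatch(em_two_snp(g1, g2), error = function(e) NULL)
  if (is.null(f)) {
    return(data.frame(d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      n = sum(!is.na(g1) & !is.na(g2)),
                      classification = "non_informative",
                      stringsAsFactors = FALSE))
  }
  ld <- .ld_coefficients(f)
  counts <- attr(f, "counts")
  sgn <- if (ld$d >= 0) 1 else -1
  d_max <- if (sgn > 0) min(ld$pA * (1 - ld$pB), (1 - ld$pA) * ld$pB)
           else min(ld$pA * ld$pB, (1 - ld$pA) * (1 - ld$pB))
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, function(dp) {
    dd <- sgn * dp * d_max
    fr <- c(ld$pA * ld$pB + dd, ld$pA * (1 - ld$pB) - dd,
            (1 - ld$pA) * ld$pB - dd, (1 - ld$pA) * (1 - ld$pB) + dd)
    fr[fr < 0 & fr > -1e-12] <- 0
    if (any(fr < 0)) return(-Inf)
    .two_snp_loglik(fr, counts)
  }, numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cum <- cumsum(w)
  cum_below <- c(0, cum[-length(cum)])
  ci_low <- grid[max(which(cum_below <= 0.05))]
  ci_high <- grid[min(which(cum >= 0.95))]
  data.frame(d = ld$d, d_prime = ld$d_prime, r2 = ld$r2,
             ci_low = ci_low, ci_high = ci_high, n = attr(f, "n"),
             classification = classify_pair(ci_low, ci_high),
             stringsAsFactors = FALSE)
}

#' Gabriel classification of a pairwise D' confidence interval
#'
#' "strong LD" when the upper bound is at least 0.98 and the lower bound at
#' least 0.7; "recombination" when the upper bound is below 0.9; otherwise
#' the comparison is non-informative.
#'
#' @param ci_low,ci_high 95% confidence bounds on D' (vectorised).
#' @return Character vector in \{"strong_ld", "recombination",
#'   "non_informative"\}.
#' @export
classify_pair <- function(ci_low, ci_high) {
  out <- rep("non_informative", length(ci_low))
  out[!is.na(ci_high) & ci_high < 0.9] <- "recombination"
  out[!is.na(ci_low) & !is.na(ci_high) & ci_high >= 0.98 & ci_low >= 0.7] <-
    "strong_ld"
  out
}

#' All pairwise LD estimates for a cohort
#'
#' @param cohort a [new_cohort()] object.
#' @param within_chromosome restrict to pairs on the same chromosome
#'   (the input to block construction).
#' @param grid_step passed to [dprime_with_ci()].
#' @return data.frame with one row per pair: `index_i`, `index_j`,
#'   `snp_i`, `snp_j`, `chromosome` (of SNP i), and the [dprime_with_ci()]
#'   columns.
#' @export
pairwise_ld <- function(cohort, within_chromosome = TRUE, grid_step = 0.01) {
  m <- ncol(cohort$geno)
  if (m < 2) stop("need at least two SNPs")
  idx <- combn(m, 2)
  if (within_chromosome) {
    same <- cohort$snps$chromosome[idx[1, ]] == cohort$snps$chromosome[idx[2, ]]
    idx <- idx[, same, drop = FALSE]
  }
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    cbind(data.frame(index_i = i, index_j = j,
                     snp_i = cohort$snps$snp_id[i],
                     snp_j = cohort$snps$snp_id[j],
                     chromosome = cohort$snps$chromosome[i],
                     stringsAsFactors = FALSE),
          dprime_with_ci(cohort$geno[, i], cohort$geno[, j], grid_step))
  })
  do.call(rbind, rows)
}

#' Construct LD blocks from classified pairs (Gabriel rule)
#'
#' Candidate spans are contiguous same-chromosome SNP runs (at least two
#' SNPs) whose outermost pair is "strong LD"; a candidate is accepted when
#' it has at least one informative comparison and the strong-LD fraction of
#' its informative comparisons is at least `min_strong_frac`. Accepted
#' candidates are taken greedily from longest to shortest (ties to the
#' leftmost start), skipping overlaps.
#'
#' @param pairs output of [pairwise_ld()] covering all within-chromosome
#'   pairs of `snps`.
#' @param snps the cohort's SNP table.
#' @param min_strong_frac block acceptance threshold (default 0.95).
#' @return data.frame, one row per block: `chromosome`, `start_index`,
#'   `end_index`, `start_snp`, `end_snp`, `n_snps`, `n_informative`,
#'   `frac_strong`. Zero rows when no block qualifies.
#' @export
find_blocks <- function(pairs, snps, min_strong_frac = 0.95) {
  cls <- matrix(NA_character_, nrow(snps), nrow(snps))
  cls[cbind(pairs$index_i, pairs$index_j)] <- pairs$classification
  cls[cbind(pairs$index_j, pairs$index_i)] <- pairs$classification
  cand <- list()
  members <- list()
  for (chrom in unique(snps$chromosome)) {
    on_chr <- which(snps$chromosome == chrom)
    on_chr <- on_chr[order(snps$position[on_chr])]
    k <- length(on_chr)
    if (k < 2) next
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      i <- on_chr[a]; j <- on_chr[b]
      if (is.na(cls[i, j]) || cls[i, j] != "strong_ld") next
      span <- on_chr[a:b]
      pr <- combn(span, 2)
      cl <- cls[cbind(pr[1, ], pr[2, ])]
      n_strong <- sum(cl == "strong_ld", na.rm = TRUE)
      n_inf <- n_strong + sum(cl == "recombination", na.rm = TRUE)
      if (n_inf >= 1 && n_strong / n_inf >= min_strong_frac) {
        cand[[length(cand) + 1L]] <- data.frame(
          chromosome = chrom, start_index = i, end_index = j,
          start_snp = snps$snp_id[i], end_snp = snps$snp_id[j],
          n_snps = length(span), n_informative = n_inf,
          frac_strong = n_strong / n_inf, stringsAsFactors = FALSE)
        members[[length(members) + 1L]] <- span
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(chromosome = character(0), start_index = integer(0),
                      end_index = integer(0), start_snp = character(0),
                      end_snp = character(0), n_snps = integer(0),
                      n_informative = integer(0), frac_strong = numeric(0),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  ord <- order(-cand$n_snps, cand$start_index)
  taken <- logical(nrow(snps))
  keep <- logical(nrow(cand))
  for (r in ord) {
    span <- members[[r]]
    if (!any(taken[span])) { keep[r] <- TRUE; taken[span] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$start_index), , drop = FALSE]
}
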