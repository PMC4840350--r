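#' Minor allele frequency of a genotype column
#'
#' @param dosages vector of counted-allele dosages in \{0, 1, 2, NA\}.
#' @return `min(p, 1 - p)` with `p = sum(dosages) / (2 * non-missing)`.
#' @export
minor_allele_freq <- function(dosages) {
  nn <- sum(!is.na(dosages))
  if (nn == 0) stop("all genotypes missing: MAF undefined")
  p <- sum(dosages, na.rm = TRUE) / (2 * nn)
  min(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the probability
#' of each compatible heterozygote count is computed under random mating and
#' the P value sums the probabilities of all configurations no more probable
#' than the observed one. Probabilities are built by recurrence from the
#' distribution's mode, so counts in the tens of thousands are handled
#' without overflow.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (either homozygote may carry
#'   the minor allele; the test is symmetric in the labels).
#' @return Exact P value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stop("genotype counts must be >= 0")
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("no genotypes")
  rare <- 2 * min(n_hom1, n_hom2) + n_het   # minor allele copies
  if (rare == 0) return(1)

  # heterozygote counts share the parity of the rare-allele count
  h_obs <- n_het
  h_vals <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  probs <- numeric(length(h_vals))
  # start at (approximately) the mode so relative probabilities stay bounded
  mode <- rare * (2 * n - rare) / (2 * n)
  start <- which.min(abs(h_vals - mode))
  probs[start] <- 1
  # P(h+2)/P(h) = [ (rare-h)(2n-rare-h) ] / [ (h+2)(h+1) ] with
  # hom counts n1 = (rare-h)/2, n2 = n - n1 - h
  if (start < length(h_vals)) {
    for (i in start:(length(h_vals) - 1)) {
      h <- h_vals[i]
      probs[i + 1] <- probs[i] * (rare - h) * (2 * n - rare - h) /
        ((h + 2) * (h + 1))
    }
  }
  if (start > 1) {
    for (i in start:2) {
      h <- h_vals[i]
      probs[i - 1] <- probs[i] * h * (h - 1) /
        ((rare - h + 2) * (2 * n - rare - h + 2))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(h_obs, h_vals)]
  if (is.na(p_obs)) stop("observed heterozygote count incompatible with allele counts")
  # the relative tolerance keeps symmetric ties included regardless of
  # floating-point route
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Per-SNP quality control
#'
#' Computes call rate, minor allele frequency (whole sample) and the exact
#' Hardy-Weinberg P (controls only) for every SNP, then filters the cohort
#' to SNPs passing `maf > maf_min`, `hwe_p >= hwe_min` and
#' `call_rate >= callrate_min`. SNP order is preserved and the summary
#' covers every input SNP.
#'
#' @param cohort a [new_cohort()] object.
#' @param maf_min exclusive lower MAF bound (default 0.05).
#' @param hwe_min inclusive lower bound on the exact HWE P (default 1e-4).
#' @param callrate_min inclusive lower bound on call rate (default 0.97).
#' @return list with `summary` (data.frame: snp_id, call_rate, maf, hwe_p,
#'   pass) and `cohort` (the filtered cohort).
#' @export
apply_qc <- function(cohort, maf_min = 0.05, hwe_min = 1e-4,
                     callrate_min = 0.97) {
  stopifnot(maf_min >= 0, maf_min <= 1, hwe_min >= 0, hwe_min <= 1,
            callrate_min >= 0, callrate_min <= 1)
  is_ctrl <- cohort$samples$status == 0
  if (!any(is_ctrl)) stop("no controls: Hardy-Weinberg QC undefined")
  m <- ncol(cohort$geno)
  call_rate <- maf <- hwe_p <- numeric(m)
  for (j in seq_len(m)) {
    d <- cohort$geno[, j]
    call_rate[j] <- mean(!is.na(d))
    maf[j] <- if (all(is.na(d))) NA_real_ else minor_allele_freq(d)
    dc <- d[is_ctrl]
    dc <- dc[!is.na(dc)]
    hwe_p[j] <- if (length(dc) == 0) NA_real_ else
      hwe_exact_test(sum(dc == 0), sum(dc == 1), sum(dc == 2))
  }
  pass <- !is.na(maf) & !is.na(hwe_p) &
    maf > maf_min & hwe_p >= hwe_min & call_rate >= callrate_min
  summary <- data.frame(snp_id = cohort$snps$snp_id, call_rate = call_rate,
                        maf = maf, hwe_p = hwe_p, pass = pass,
                        stringsAsFactors = FALSE)
  list(summary = summary,
       cohort = subset_cohort(cohort, snps = which(pass)))
}
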