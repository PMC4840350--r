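# enumerate the unordered haplotype pairs compatible with one multilocus
# genotype (dosage vector over k SNPs, bit = minor allele). Returns a
# 2-column integer matrix of haplotype codes (0-based bitmasks).
.compatible_pairs <- function(g) {
  k <- length(g)
  het <- which(g == 1L)
  base <- sum(as.integer(g == 2L) * 2^(seq_len(k) - 1))
  if (!length(het)) return(matrix(c(base, base), ncol = 2))
  h <- length(het)
  bits <- 2^(het - 1)
  # fix the first heterozygous site on haplotype 1 to avoid double-counting
  free <- het[-1]
  n_cfg <- 2^(h - 1)
  out <- matrix(0, n_cfg, 2)
  for (cfg in 0:(n_cfg - 1)) {
    assign1 <- c(TRUE, as.logical(bitwAnd(cfg, 2^(seq_len(h - 1) - 1))))
    h1 <- base + sum(bits[assign1])
    h2 <- base + sum(bits[!assign1])
    out[cfg + 1, ] <- c(h1, h2)
  }
  out
}

#' EM haplotype frequency estimation for a SNP block
#'
#' Expectation-maximisation over all phase assignments consistent with each
#' individual's multilocus genotype, initialised at products of allele
#' frequencies, run on the combined sample (complete-case for the block).
#' Case and control frequencies are posterior-weighted expected counts.
#' Haplotypes rarer than `pool_min` overall are pooled into a `"RARE"`
#' class. When the likelihood is flat (convergence in under 3 iterations),
#' 3 seeded random restarts are tried and the best likelihood kept.
#'
#' @param cohort a [new_cohort()] object.
#' @param snp_ids block member SNP ids (or indices), 2 to 12 SNPs.
#' @param pool_min rare-haplotype pooling threshold (default 0.01).
#' @param tol convergence tolerance on the max frequency change.
#' @param max_iter iteration cap (default 5000).
#' @param seed seed for the random restarts (deterministic).
#' @return list of class `haplotype_freqs`: `snp_ids`, `haplotype` (allele
#'   strings), `freq_overall`, `freq_cases`, `freq_controls`,
#'   `count_cases`, `count_controls` (expected chromosome counts),
#'   `n_cases`, `n_controls`, `loglik`, `n_iter`, `converged`, `n_pooled`.
#' @export
em_haplotypes <- function(cohort, snp_ids, pool_min = 0.01, tol = 1e-6,
                          max_iter = 5000L, seed = 1L) {
  j <- if (is.character(snp_ids)) match(snp_ids, cohort$snps$snp_id)
       else as.integer(snp_ids)
  if (anyNA(j)) stop("unknown snp id(s) in block")
  k <- length(j)
  if (k < 2) stop("a block needs at least 2 SNPs")
  if (k > 12) stop("refusing blocks of more than 12 SNPs (enumeration bound)")
  G <- cohort$geno[, j, drop = FALSE]
  keep <- rowSums(is.na(G)) == 0
  G <- G[keep, , drop = FALSE]
  status <- cohort$samples$status[keep]
  n <- nrow(G)
  if (n == 0) stop("no complete-case samples for the block")

  pat_key <- apply(G, 1, paste, collapse = "")
  pats <- unique(pat_key)
  pat_idx <- match(pat_key, pats)
  cnt_case <- tabulate(pat_idx[status == 1], length(pats))
  cnt_ctrl <- tabulate(pat_idx[status == 0], length(pats))
  cnt_all <- cnt_case + cnt_ctrl
  pairs <- lapply(pats, function(p) .compatible_pairs(as.integer(strsplit(p, "")[[1]])))

  hap_codes <- sort(unique(unlist(pairs)))
  H <- length(hap_codes)
  code_of <- match
  # initial frequencies: products of allele frequencies over possible haps
  q <- colSums(G) / (2 * n)
  hap_bit <- t(vapply(hap_codes, function(h)
    as.integer(bitwAnd(h, 2^(seq_len(k) - 1)) > 0), integer(k)))
  init <- apply(hap_bit, 1, function(b) prod(ifelse(b == 1, q, 1 - q)))
  init <- init / sum(init)

  pair_rows <- lapply(pairs, function(pp)
    cbind(code_of(pp[, 1], hap_codes), code_of(pp[, 2], hap_codes)))

  run_em <- function(f) {
    it <- 0L; converged <- FALSE
    repeat {
      it <- it + 1L
      exp_counts <- numeric(H)
      ll <- 0
      for (p in seq_along(pats)) {
        pr <- pair_rows[[p]]
        w <- f[pr[, 1]] * f[pr[, 2]] * ifelse(pr[, 1] == pr[, 2], 1, 2)
        sw <- sum(w)
        if (sw <= 0) return(list(f = f, loglik = -Inf, n_iter = it,
                                 converged = FALSE))
        ll <- ll + cnt_all[p] * log(sw)
        post <- w / sw
        add <- cnt_all[p] * post
        for (r in seq_len(nrow(pr))) {
          exp_counts[pr[r, 1]] <- exp_counts[pr[r, 1]] + add[r]
          exp_counts[pr[r, 2]] <- exp_counts[pr[r, 2]] + add[r]
        }
      }
      f_new <- exp_counts / (2 * n)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    list(f = f, loglik = ll, n_iter = it, converged = converged)
  }

  best <- run_em(init)
  if (best$n_iter < 3) {  # flat surface: try seeded random restarts
    for (r in 1:3) {
      f0 <- .with_seed(seed + r, { x <- -log(runif(H)); x / sum(x) })
      cand <- run_em(f0)
      if (cand$loglik > best$loglik + 1e-12) best <- cand
    }
  }
  f <- best$f

  # posterior-weighted expected chromosome counts by status
  count_case <- count_ctrl <- numeric(H)
  for (p in seq_along(pats)) {
    pr <- pair_rows[[p]]
    w <- f[pr[, 1]] * f[pr[, 2]] * ifelse(pr[, 1] == pr[, 2], 1, 2)
    post <- w / sum(w)
    for (r in seq_len(nrow(pr))) {
      count_case[pr[r, 1]] <- count_case[pr[r, 1]] + cnt_case[p] * post[r]
      count_case[pr[r, 2]] <- count_case[pr[r, 2]] + cnt_case[p] * post[r]
      count_ctrl[pr[r, 1]] <- count_ctrl[pr[r, 1]] + cnt_ctrl[p] * post[r]
      count_ctrl[pr[r, 2]] <- count_ctrl[pr[r, 2]] + cnt_ctrl[p] * post[r]
    }
  }
  n_case <- sum(status == 1); n_ctrl <- sum(status == 0)

  minor <- cohort$counted_allele[j]
  major <- ifelse(minor == cohort$snps$allele_a[j],
                  cohort$snps$allele_b[j], cohort$snps$allele_a[j])
  hap_str <- apply(hap_bit, 1, function(b)
    paste(ifelse(b == 1, minor, major), collapse = ""))

  # discard classes the EM drove to numerical zero, then pool the rare rest
  nonzero <- f > 1e-8
  f <- f[nonzero]; hap_str <- hap_str[nonzero]
  count_case <- count_case[nonzero]; count_ctrl <- count_ctrl[nonzero]
  keep_hap <- f >= pool_min
  pooled <- any(!keep_hap)
  lab <- c(hap_str[keep_hap], if (pooled) "RARE")
  agg <- function(v) c(v[keep_hap], if (pooled) sum(v[!keep_hap]))
  structure(list(
    snp_ids = cohort$snps$snp_id[j],
    haplotype = lab,
    freq_overall = agg(f),
    freq_cases = if (n_case) agg(count_case) / (2 * n_case) else agg(count_case) * NA,
    freq_controls = if (n_ctrl) agg(count_ctrl) / (2 * n_ctrl) else agg(count_ctrl) * NA,
    count_cases = agg(count_case), count_controls = agg(count_ctrl),
    n_cases = n_case, n_controls = n_ctrl,
    loglik = best$loglik, n_iter = best$n_iter, converged = best$converged,
    n_pooled = sum(!keep_hap)),
    class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat(sprintf("<haplotype_freqs> %s: %d haplotype(s), loglik %.4f (%d iter)\n",
              paste(x$snp_ids, collapse = "-"), length(x$haplotype),
              x$loglik, x$n_iter))
  print(data.frame(haplotype = x$haplotype, freq = x$freq_overall,
                   F_A = x$freq_cases, F_U = x$freq_controls))
  invisible(x)
}

#' Haplotype-specific case-control test
#'
#' 2x2 Pearson chi-square (1 df) comparing the target haplotype's expected
#' chromosome counts against all other haplotypes, cases versus controls.
#' Expected counts from the EM are treated as observed (the standard
#' association-toolchain convention). Cells below 1 flag the result
#' unreliable.
#'
#' @param freqs an [em_haplotypes()] result (or a list with fields
#'   `haplotype`, `count_cases`, `count_controls`, `n_cases`, `n_controls`).
#' @param target haplotype allele string present in `freqs$haplotype`.
#' @return One-row data.frame: `haplotype`, `F_A`, `F_U`, `chi2`, `df`,
#'   `p_value`, `flagged`.
#' @export
hap_specific_test <- function(freqs, target) {
  i <- match(target, freqs$haplotype)
  if (is.na(i)) stop("haplotype not present: ", target)
  a <- freqs$count_cases[i]; b <- 2 * freqs$n_cases - a
  c <- freqs$count_controls[i]; d <- 2 * freqs$n_controls - c
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- if (any(expected == 0)) 0 else sum((tab - expected)^2 / expected)
  data.frame(haplotype = target,
             F_A = a / (2 * freqs$n_cases), F_U = c / (2 * freqs$n_controls),
             chi2 = chi2, df = 1L,
             p_value = pchisq(chi2, 1, lower.tail = FALSE),
             flagged = any(tab < 1), stringsAsFactors = FALSE)
}

#' Omnibus haplotype test
#'
#' Pearson chi-square on the full H x 2 table of expected haplotype
#' chromosome counts (cases vs controls), df = H - 1.
#'
#' @param freqs an [em_haplotypes()] result with at least 2 haplotypes.
#' @return One-row data.frame: `haplotype = "OMNIBUS"`, `chi2`, `df`,
#'   `p_value`.
#' @export
omnibus_test <- function(freqs) {
  H <- length(freqs$haplotype)
  if (H < 2) stop("omnibus test needs at least 2 haplotypes")
  tab <- cbind(cases = freqs$count_cases, controls = freqs$count_controls)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- expected > 0
  chi2 <- sum((tab[ok] - expected[ok])^2 / expected[ok])
  data.frame(haplotype = "OMNIBUS", chi2 = chi2, df = H - 1L,
             p_value = pchisq(chi2, H - 1L, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Haplotype association scan over LD blocks
#'
#' For each block: EM haplotype frequencies, the omnibus test, and every
#' per-haplotype test, tabulated with the omnibus row first and haplotypes
#' in decreasing overall frequency.
#'
#' @param cohort a [new_cohort()] object.
#' @param blocks a [find_blocks()] result (or a data.frame with
#'   `start_index`/`end_index`, or a list of SNP-id character vectors).
#' @param ... passed to [em_haplotypes()].
#' @return data.frame with columns `SNPS`, `HAPLOTYPE`, `F_A`, `F_U`,
#'   `CHISQ`, `P`.
#' @export
haplotype_scan <- function(cohort, blocks, ...) {
  block_members <- if (is.data.frame(blocks)) {
    lapply(seq_len(nrow(blocks)), function(r) {
      chrom <- cohort$snps$chromosome[blocks$start_index[r]]
      on_chr <- which(cohort$snps$chromosome == chrom)
      on_chr <- on_chr[order(cohort$snps$position[on_chr])]
      a <- match(blocks$start_index[r], on_chr)
      b <- match(blocks$end_index[r], on_chr)
      cohort$snps$snp_id[on_chr[a:b]]
    })
  } else {
    blocks
  }
  rows <- lapply(block_members, function(ids) {
    fr <- em_haplotypes(cohort, ids, ...)
    snps_lab <- paste(fr$snp_ids, collapse = "-")
    om <- omnibus_test(fr)
    ord <- order(-fr$freq_overall)
    per <- do.call(rbind, lapply(fr$haplotype[ord], function(h)
      hap_specific_test(fr, h)))
    data.frame(SNPS = snps_lab,
               HAPLOTYPE = c("OMNIBUS", per$haplotype),
               F_A = c(NA_real_, per$F_A),
               F_U = c(NA_real_, per$F_U),
               CHISQ = c(om$chi2, per$chi2),
               P = c(om$p_value, per$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
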