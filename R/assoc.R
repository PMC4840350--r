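#' Code minor-allele dosages under a genetic model
#'
#' Additive: 0/1/2 copies of the minor allele (identity). Dominant: 0 for
#' major-allele homozygotes, 1 for carriers of the minor allele. Recessive:
#' 1 for minor-allele homozygotes, 0 otherwise. Missing propagates.
#'
#' @param dosages minor-allele dosages in \{0, 1, 2, NA\}.
#' @param model one of "additive", "dominant", "recessive".
#' @return Numeric vector of codes with attribute `model`.
#' @export
code_genotypes <- function(dosages, model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  out <- switch(model,
                additive  = as.numeric(dosages),
                dominant  = as.numeric(dosages >= 1),
                recessive = as.numeric(dosages == 2))
  attr(out, "model") <- model
  out
}

#' Maximum-likelihood logistic regression fit
#'
#' Newton/IRLS maximisation of the binomial-logit likelihood with Wald tests
#' (coefficient / SE against the standard normal). Rows with any missing
#' value are dropped (complete-case). Non-convergence and separation
#' (diverging coefficients) are reported via `converged = FALSE`, never
#' silently.
#'
#' @param design numeric matrix of predictors including an intercept column.
#' @param y binary 0/1 outcomes, one per design row.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter iteration cap.
#' @return list of class `logistic_fit`: `coefficients`, `se`, `wald_z`,
#'   `p_values` (all named by design column), `converged`, `n_iter`,
#'   `loglik`, `n_used`.
#' @export
fit_logistic <- function(design, y, tol = 1e-8, max_iter = 25L) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("b", seq_len(ncol(design)) - 1L)
  if (!all(y[!is.na(y)] %in% c(0, 1))) stop("y must be binary 0/1")
  keep <- complete.cases(design) & !is.na(y)
  X <- design[keep, , drop = FALSE]
  yy <- as.numeric(y[keep])
  if (nrow(X) < ncol(X)) stop("fewer complete rows than parameters")
  f <- .irls_logit(X, yy, tol, as.integer(max_iter))
  co <- drop(f$coefficients); se <- drop(f$se)
  names(co) <- names(se) <- colnames(design)
  z <- co / se
  structure(list(coefficients = co, se = se, wald_z = z,
                 p_values = 2 * pnorm(-abs(z)),
                 converged = isTRUE(f$converged),
                 n_iter = f$n_iter, loglik = f$loglik,
                 n_used = nrow(X)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, loglik = %.4f, %s in %d iter\n",
              x$n_used, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$wald_z,
                   p = x$p_values))
  invisible(x)
}

#' Allele-count association test
#'
#' Genotype counts are collapsed to allele counts (each person contributes
#' two alleles) and a 1-df Pearson chi-square without continuity correction
#' is computed on the resulting 2x2 case/control x major/minor table. The
#' odds ratio is the odds of the minor allele in cases over controls; with a
#' zero cell, 0.5 is added to every cell for the OR (flagged).
#'
#' @param case_counts,control_counts length-3 genotype counts
#'   (hom-major, het, hom-minor).
#' @return list: `chi2`, `df`, `p`, `or`, `ci95_low`, `ci95_high`,
#'   `table` (the 2x2 allele counts), `flagged`.
#' @export
allelic_test <- function(case_counts, control_counts) {
  stopifnot(length(case_counts) == 3, length(control_counts) == 3,
            all(case_counts >= 0), all(control_counts >= 0),
            sum(case_counts) > 0, sum(control_counts) > 0)
  minor_case <- case_counts[2] + 2 * case_counts[3]
  major_case <- 2 * case_counts[1] + case_counts[2]
  minor_ctrl <- control_counts[2] + 2 * control_counts[3]
  major_ctrl <- 2 * control_counts[1] + control_counts[2]
  tab <- matrix(c(major_case, minor_case, major_ctrl, minor_ctrl),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("major", "minor")))
  N <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  chi2 <- if (any(expected == 0)) 0 else sum((tab - expected)^2 / expected)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  flagged <- any(tab == 0)
  tt <- if (flagged) tab + 0.5 else tab
  or <- (tt["case", "minor"] * tt["control", "major"]) /
    (tt["case", "major"] * tt["control", "minor"])
  se_log <- sqrt(sum(1 / tt))
  z <- qnorm(0.975)
  list(chi2 = chi2, df = 1L, p = p, or = unname(or),
       ci95_low = unname(or * exp(-z * se_log)),
       ci95_high = unname(or * exp(z * se_log)),
       table = tab, flagged = flagged)
}

#' Single-marker association scan
#'
#' For every SNP: the unadjusted allele-count test, plus a logistic
#' regression of status on the coded genotype under each requested model,
#' optionally adjusted for sex and age. OR = exp(slope) with a 95% Wald CI.
#' Per-SNP fit failures are recorded in the result row and the scan
#' continues.
#'
#' @param cohort a [new_cohort()] object (dosages counting minor alleles;
#'   normally QC-passing SNPs).
#' @param models subset of "additive", "dominant", "recessive".
#' @param adjust include sex and age as covariates in the logistic fits.
#' @param allelic include the unadjusted allele-count test rows.
#' @return data.frame, one row per SNP x model: `snp_id`, `model`,
#'   `odds_ratio`, `ci95_low`, `ci95_high`, `p_value`, `n_used`,
#'   `converged`, plus genotype counts by status.
#' @export
single_marker_scan <- function(cohort,
                               models = c("additive", "dominant", "recessive"),
                               adjust = TRUE, allelic = TRUE) {
  models <- match.arg(models, several.ok = TRUE)
  smp <- cohort$samples
  rows <- list()
  for (j in seq_len(ncol(cohort$geno))) {
    d <- cohort$geno[, j]
    id <- cohort$snps$snp_id[j]
    cc <- vapply(0:2, function(k) sum(d == k & smp$status == 1, na.rm = TRUE), 0)
    ct <- vapply(0:2, function(k) sum(d == k & smp$status == 0, na.rm = TRUE), 0)
    counts <- data.frame(case_hom_major = cc[1], case_het = cc[2],
                         case_hom_minor = cc[3], ctrl_hom_major = ct[1],
                         ctrl_het = ct[2], ctrl_hom_minor = ct[3])
    if (allelic) {
      at <- tryCatch(allelic_test(cc, ct), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(at)) {
        cbind(data.frame(snp_id = id, model = "allelic", odds_ratio = NA_real_,
                         ci95_low = NA_real_, ci95_high = NA_real_,
                         p_value = NA_real_, n_used = sum(!is.na(d)),
                         converged = FALSE, stringsAsFactors = FALSE), counts)
      } else {
        cbind(data.frame(snp_id = id, model = "allelic", odds_ratio = at$or,
                         ci95_low = at$ci95_low, ci95_high = at$ci95_high,
                         p_value = at$p, n_used = sum(!is.na(d)),
                         converged = TRUE, stringsAsFactors = FALSE), counts)
      }
    }
    for (mod in models) {
      g <- code_genotypes(d, mod)
      X <- if (adjust) cbind(intercept = 1, geno = g, sex = smp$sex, age = smp$age)
           else cbind(intercept = 1, geno = g)
      fit <- tryCatch(fit_logistic(X, smp$status), error = function(e) NULL)
      z <- qnorm(0.975)
      rows[[length(rows) + 1L]] <- if (is.null(fit)) {
        cbind(data.frame(snp_id = id, model = mod, odds_ratio = NA_real_,
                         ci95_low = NA_real_, ci95_high = NA_real_,
                         p_value = NA_real_, n_used = NA_integer_,
                         converged = FALSE, stringsAsFactors = FALSE), counts)
      } else {
        b <- fit$coefficients["geno"]; s <- fit$se["geno"]
        cbind(data.frame(snp_id = id, model = mod,
                         odds_ratio = unname(exp(b)),
                         ci95_low = unname(exp(b - z * s)),
                         ci95_high = unname(exp(b + z * s)),
                         p_value = unname(fit$p_values["geno"]),
                         n_used = fit$n_used, converged = fit$converged,
                         stringsAsFactors = FALSE), counts)
      }
    }
  }
  do.call(rbind, rows)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise significance level.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("number of tests must be >= 1")
  alpha / m
}
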