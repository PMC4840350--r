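.z95 <- 1.959964

#' Assemble a study-effects table for meta-analysis
#'
#' @param label study labels.
#' @param or per-study odds ratios.
#' @param ci_low,ci_high 95% CI bounds on the OR (used to recover the
#'   log-OR standard error as `(ln ci_high - ln ci_low) / (2 * 1.959964)`
#'   when `se_log_or` is not given directly).
#' @param se_log_or optional log-OR standard errors.
#' @param n_cases,n_controls optional per-study counts.
#' @return data.frame of class `study_effects` with a `se_log_or` column.
#' @export
study_effects <- function(label, or, ci_low = NULL, ci_high = NULL,
                          se_log_or = NULL, n_cases = NA, n_controls = NA) {
  k <- length(or)
  if (is.null(se_log_or)) {
    if (is.null(ci_low) || is.null(ci_high))
      stop("give either se_log_or or both CI bounds")
    if (any(ci_low <= 0) || any(ci_high < ci_low) ||
        any(or < ci_low) || any(or > ci_high))
      stop("need 0 < ci_low <= or <= ci_high")
    se_log_or <- (log(ci_high) - log(ci_low)) / (2 * .z95)
  }
  if (any(se_log_or <= 0)) stop("log-OR standard errors must be positive")
  out <- data.frame(label = as.character(label), or = or,
                    ci_low = if (is.null(ci_low)) or * exp(-.z95 * se_log_or) else ci_low,
                    ci_high = if (is.null(ci_high)) or * exp(.z95 * se_log_or) else ci_high,
                    se_log_or = se_log_or,
                    n_cases = rep_len(n_cases, k),
                    n_controls = rep_len(n_controls, k),
                    stringsAsFactors = FALSE)
  class(out) <- c("study_effects", "data.frame")
  out
}

.meta_result <- function(res, model, k) {
  or <- exp(as.numeric(res$beta))
  list(model = model, k = k, pooled_or = or,
       ci95_low = exp(res$ci.lb), ci95_high = exp(res$ci.ub),
       se_log_or = res$se, z = as.numeric(res$zval), p = as.numeric(res$pval),
       q_statistic = res$QE, q_df = k - 1, q_p = res$QEp,
       i2 = max(0, res$I2 / 100), tau2 = res$tau2)
}

#' Fixed-effect (inverse-variance) odds-ratio meta-analysis
#'
#' Pooled log OR = sum(w_i y_i) / sum(w_i) with w_i = 1/SE_i^2, Cochran's
#' Q and I^2 = max(0, (Q - (k-1))/Q) for heterogeneity.
#'
#' @param effects a [study_effects()] data.frame (>= 1 study).
#' @return list: `model`, `k`, `pooled_or`, `ci95_low`, `ci95_high`,
#'   `se_log_or`, `z`, `p`, `q_statistic`, `q_df`, `q_p`, `i2`, `tau2` (0).
#' @export
meta_fixed <- function(effects) {
  stopifnot(nrow(effects) >= 1)
  res <- metafor::rma.uni(yi = log(effects$or), sei = effects$se_log_or,
                          method = "FE")
  out <- .meta_result(res, "fixed", nrow(effects))
  out$tau2 <- 0
  out
}

#' DerSimonian-Laird random-effects odds-ratio meta-analysis
#'
#' Between-study variance `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 /
#' sum w))` with fixed-effect weights w; pooling weights `1/(SE^2 + tau2)`.
#' With a single study (or tau2 = 0) the result equals [meta_fixed()].
#'
#' @param effects a [study_effects()] data.frame.
#' @return As [meta_fixed()], with `model = "random"` and the DL `tau2`.
#' @export
meta_random <- function(effects) {
  stopifnot(nrow(effects) >= 1)
  if (nrow(effects) == 1) {
    out <- meta_fixed(effects)
    out$model <- "random"
    return(out)
  }
  res <- metafor::rma.uni(yi = log(effects$or), sei = effects$se_log_or,
                          method = "DL")
  .meta_result(res, "random", nrow(effects))
}

#' Write / read a forest-table TSV of study effects
#'
#' @param effects a [study_effects()] data.frame.
#' @param path TSV path (columns label, or, ci_low, ci_high, n_cases,
#'   n_controls).
#' @return `write_studies_tsv`: the path, invisibly. `read_studies_tsv`:
#'   a [study_effects()] data.frame.
#' @export
write_studies_tsv <- function(effects, path) {
  write.table(effects[, c("label", "or", "ci_low", "ci_high",
                          "n_cases", "n_controls")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_studies_tsv
#' @export
read_studies_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#")
  study_effects(x$label, x$or, x$ci_low, x$ci_high,
                n_cases = x$n_cases, n_controls = x$n_controls)
}

#' Analytic power of the case-control allele-count test
#'
#' The case minor-allele frequency is derived from the control frequency
#' and the per-allele odds ratio; power of the 1-df allele-count test is
#' approximated as `Phi(|p_case - p_ctrl| / SE_diff - z_(1-alpha/2))` with
#' `SE_diff` from the binomial variances at 2N chromosomes per group.
#' `per_allele_or = 1` returns `alpha` (the test's size) by convention.
#'
#' @param n_cases,n_controls group sizes (individuals).
#' @param maf control minor allele frequency in (0, 0.5].
#' @param per_allele_or per-allele odds ratio (> 0).
#' @param alpha two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_case_control <- function(n_cases, n_controls, maf, per_allele_or,
                               alpha = 0.05) {
  stopifnot(n_cases > 0, n_controls > 0, maf > 0, maf <= 0.5,
            per_allele_or > 0, alpha > 0, alpha < 1)
  if (per_allele_or == 1) return(alpha)
  p0 <- maf
  odds1 <- p0 / (1 - p0) * per_allele_or
  p1 <- odds1 / (1 + odds1)
  se_diff <- sqrt(p1 * (1 - p1) / (2 * n_cases) +
                  p0 * (1 - p0) / (2 * n_controls))
  pnorm(abs(p1 - p0) / se_diff - qnorm(1 - alpha / 2))
}

#' Monte-Carlo power of the allele-count test
#'
#' Simulates allele-count 2x2 tables (binomial draws of 2N chromosomes per
#' group at the model frequencies of [power_case_control()]) and returns
#' the rejection fraction of the 1-df Pearson chi-square.
#'
#' @inheritParams power_case_control
#' @param n_sim number of simulated tables.
#' @param seed integer seed.
#' @return Empirical power.
#' @export
power_case_control_mc <- function(n_cases, n_controls, maf, per_allele_or,
                                  alpha = 0.05, n_sim = 5000L, seed = 1L) {
  p0 <- maf
  odds1 <- p0 / (1 - p0) * per_allele_or
  p1 <- odds1 / (1 + odds1)
  .with_seed(seed, {
    a <- rbinom(n_sim, 2 * n_cases, p1)        # case minor alleles
    c_ <- rbinom(n_sim, 2 * n_controls, p0)    # control minor alleles
    b <- 2 * n_cases - a; d <- 2 * n_controls - c_
    N <- 2 * n_cases + 2 * n_controls
    chi2 <- N * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    chi2[!is.finite(chi2)] <- 0
    mean(pchisq(chi2, 1, lower.tail = FALSE) < alpha)
  })
}
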