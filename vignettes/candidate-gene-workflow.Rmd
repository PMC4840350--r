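---
title: "Methods: candidate-gene case-control association with candigene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene case-control association with candigene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(candigene)
```

# Scope and data model

candigene analyses a small panel of biallelic tag SNPs (tens of markers in
a few candidate gene regions) in an unrelated case-control cohort. The
canonical container is the `cohort`: a SNP table (id, chromosome, position,
the two alleles, gene label), a sample table (id, case/control status, sex,
age in years), and an integer dosage matrix counting copies of each SNP's
*counted* allele, with `NA` for missing calls. All analysis functions
assume the counted allele is the minor allele; `recode_to_minor()`
establishes that invariant (whole-sample frequency, cases and controls
combined, with exact-0.5 ties going to the lexicographically smaller base),
and both file readers apply it on ingest. Phase information in VCF input is
discarded: every downstream method (two-SNP and multi-SNP EM, logistic
models) operates on unphased dosages. Chromosome labels are opaque strings
compared by equality; `read_vcf(normalize_chrom = TRUE)` strips a leading
`"chr"`.

Supported formats are VCF v4.x with GT fields plus a phenotype TSV
(`sample_id`, `status`, `sex`, `age`), and whitespace-delimited text
PED/MAP with the usual conventions (phenotype 1 = control / 2 = case, sex
1 = male / 2 = female, `0 0` = missing genotype). PED carries no age, so an
optional covariate TSV fills it; a gene annotation survives a VCF round
trip (as a `GENE=` INFO entry) but not a PED one. Multi-allelic records,
indels, binary PLINK and dosage formats are out of scope.

# Quality control

Three per-SNP statistics drive inclusion, mirroring common practice for
MassARRAY-scale panels:

* **call rate**, default threshold 0.97 (panels of this kind typically
  genotype at > 99%);
* **minor allele frequency**, `min(p, 1-p)` over non-missing dosages,
  default threshold MAF > 0.05 (the tag-SNP selection criterion);
* **exact Hardy-Weinberg P in controls**, default threshold 1e-4.

The Hardy-Weinberg test is the conditional exact test: given the observed
minor-allele count, every compatible heterozygote count has a known
probability under random mating, and the P value sums the probabilities of
all configurations no more probable than the observed one. Probabilities
are built by a two-sided recurrence started at the distribution's mode, so
relative values stay bounded and cohorts of tens of thousands need no
log-space fallback; a relative tolerance of 1e-9 on the inclusion
comparison keeps exactly tied configurations (which arise from the
distribution's symmetry) on a deterministic side regardless of
floating-point route. Computing the test in controls only is a deliberate
choice — disease association itself distorts genotype proportions in cases
— and is the field's default; the alternative (combined sample) is a
one-line change at the call site.

# Single-marker association

Genotypes enter the logistic model under three codings: additive (the
dosage itself), dominant (1 for any minor-allele carrier) and recessive
(1 for minor homozygotes). For each SNP and coding the model

$$\mathrm{logit}\,P(Y=1) = b_0 + b_1\,g \,(+\, b_2\,\text{sex} + b_3\,\text{age})$$

is fitted by iteratively reweighted least squares (IRLS; compiled, see
*Numerical choices*), and the slope is tested with a two-sided Wald test;
`OR = exp(b1)` with a 95% CI at z = 1.959964. Sex is coded 0/1 and age is
used untransformed in years. Missing genotypes are handled complete-case
per SNP, matching the default of the standard association toolchains; at
99.5% call rates the difference from any imputation scheme is negligible.
Alongside the model fits, the unadjusted allele-count test collapses
genotype counts to allele counts (2N chromosomes per group) and applies the
1-df Pearson chi-square without continuity correction; this exact
convention reproduces published allelic P values from printed genotype
counts, which is how the package's acceptance checks anchor it. With a zero
cell the odds ratio falls back to the 0.5-per-cell correction and the
result is flagged. The family-wise threshold is plain Bonferroni, `α/m`
(0.05/35 ≈ 0.001 for the default panel).

# LD blocks

D′ between two SNPs is estimated from unphased data by an EM over the
single phase-ambiguous class (double heterozygotes), initialised at linkage
equilibrium and iterated to a 1e-9 frequency change (cap 1000 iterations).
From the four haplotype frequencies, `D = p_AB − p_A p_B`, the
sign-appropriate `D_max`, `D′ = |D|/D_max` and
`r² = D²/(p_A p_a p_B p_b)`.

The 95% confidence bounds on D′ follow the Haploview-style approximation:
allele frequencies are held at their MLEs, the genotype-class likelihood is
evaluated on a D′ grid over [0, 1] (step 0.01, sign fixed at the
estimate's), and the normalised likelihood is accumulated across the grid;
the lower bound is the largest grid value with at most 5% cumulative
likelihood below it and the upper bound the smallest grid value reaching
95%. Full joint profiling of the three free parameters is deliberately out
of scope. A pair is **strong LD** when the upper bound is ≥ 0.98 and the
lower ≥ 0.7, **recombination** when the upper bound is < 0.9 (the
Gabriel/Haploview convention for the recombination call), otherwise
non-informative.

Blocks are contiguous same-chromosome spans (minimum 2 SNPs, no maximum —
the panel is sparse) whose outermost pair is strong LD and whose
informative comparisons are ≥ 95% strong LD; candidates are accepted
greedily longest-first (ties to the leftmost start), skipping overlaps.
Population-specific spacing rules from the original block definition are
omitted: with ~4 tag SNPs per gene they would never bind.

One structural consequence worth knowing: at cohort sizes in the thousands
the D′ confidence interval is narrow, so a pair whose *true* D′ is 0.95
will be confidently classified as *not* strong LD (its upper bound sits
near 0.96 < 0.98). Block formation at large n therefore requires
essentially complete within-block LD, which is what real tag-SNP blocks
show — and what the default synthetic design provides (see below).

# Haplotype association

Within each block, haplotype frequencies come from an EM over all phase
assignments consistent with each multilocus genotype (complete-case per
block, blocks capped at 12 SNPs by the 2^k enumeration), initialised at
allele-frequency products and run to a 1e-6 frequency change (cap 5000
iterations); when the surface is flat (convergence in under 3 iterations) 3
seeded random restarts are tried and the best likelihood kept. Case (`F_A`)
and control (`F_U`) frequencies are posterior-weighted expected chromosome
counts under the combined-sample estimate. Classes driven to numerical zero
are discarded; haplotypes below 1% overall frequency are pooled into a
`RARE` class.

Tests treat the expected counts as observed — the convention of the
standard toolchain — so the extra EM variance is not propagated; this is a
known, documented approximation that matters only for rare haplotypes
(those rows are flagged when any cell drops below 1). Each haplotype gets a
1-df 2×2 Pearson chi-square (target vs all others, cases vs controls), and
the block gets an omnibus H×2 chi-square with H−1 df. The scan output
mirrors the conventional table layout: `SNPS HAPLOTYPE F_A F_U CHISQ P`,
omnibus row first, haplotypes in decreasing frequency.

# Epistasis

Every cross-chromosome SNP pair (same-chromosome pairs are excluded — their
interaction estimates are confounded by LD) is tested through

$$\mathrm{logit}\,P(Y=1) = b_0 + b_1 g_1 + b_2 g_2 + b_3\,g_1 g_2 + b_4\,\text{sex} + b_5\,\text{age}$$

with additive coding at both loci; the interaction is the two-sided Wald
test on `b3`, `OR_int = exp(b3)`. The default 35-SNP panel, with 12/12/8/3
SNPs on its four chromosomes, yields exactly
`C(35,2) − ΣC(m_c,2) = 595 − 163 = 432` tests.

Family-wise correction uses the max-statistic permutation null: the status
vector is shuffled against the joint (genotype, sex, age) rows — breaking
status-covariate association while preserving genotype-covariate linkage,
the literal reading of "shuffling the case-control labels" — every pair is
refitted, and each replicate contributes its most significant nominal P.
The corrected P uses the add-one estimator
`(1 + #{min P ≤ P_obs})/(1 + n_perm)`, so the smallest reportable value at
1,000 permutations is 1/1001 (reported as "< 0.001" territory, never an
exact zero). Non-converged fits (separation) are flagged and contribute no
min-P candidate; a replicate in which every fit fails is redrawn, with a
warning after 10 redraws. Corrected P values are monotone in nominal P
within a scan, and runs are bit-reproducible given the seed. Main effects
`b1`, `b2` are reported for diagnostics but not permutation-tested.

# Meta-analysis and power

Per-study odds ratios (with 95% CIs, or log-OR standard errors directly)
pool by inverse variance: fixed-effect weights `1/SE²`, Cochran's Q,
`I² = max(0, (Q−(k−1))/Q)`; the random-effects model uses the
DerSimonian-Laird `τ² = max(0, (Q−(k−1))/(Σw − Σw²/Σw))` and weights
`1/(SE²+τ²)`. CI recovery from a 95% CI assumes a symmetric log-scale
interval at z = 1.959964. Both models are always computed side by side
(published pooled estimates rarely say which was used). The arithmetic runs
through `metafor::rma.uni`, cross-checked in the tests against hand
inverse-variance computation at 1e-10.

Power for a per-allele odds ratio uses the allele-count test's normal
approximation: the case allele frequency is the odds-transform of the
control MAF, and
`power = Φ(|p_case − p_ctrl|/SE_diff − z_{1−α/2})` with binomial variances
at 2N chromosomes per group. No prevalence modelling is attempted — for
case-control allelic power in this regime the approximation tracks the
standard genetic power calculator, and the package's Monte-Carlo check
(`power_case_control_mc`, simulated allele-count tables) agrees within
0.02. At the default design (2,518/7,521, MAF 0.3, α = 0.001) analytic
power is 97.1% for OR 1.2 and > 99.9% for OR 1.3; `OR = 1` returns α by
convention.

# The synthetic cohort generator

The generator exists so every stage is testable without external genotype
data; its defaults *are* the emulated study conditions:

* 35 tag SNPs in 8 gene regions on 4 chromosomes (12, 12, 8, 3 per
  chromosome — chosen to reproduce the 432 cross-chromosome pairs; the true
  per-region distribution of the emulated design is not public);
* 2,518 cases / 7,521 controls; 0.5% missing calls; ages truncated-normal
  37.5 ± 9.5 on [18, 51] (between the two groups' reported means); female
  fraction 0.519; all zero effects by default (a null cohort);
* per-SNP MAFs cycling through 0.15–0.45 (all satisfying the tag-SNP
  selection constraints MAF > 0.05 and heterozygosity > 0.2), sorted
  ascending within each region.

Region haplotypes are drawn from pools built by a first-order chain across
loci: each SNP's MAF is hit exactly, and each adjacent pair's D′ equals the
requested `ld_level` exactly (minor-minor association positive). At
`ld_level = 1` with ascending MAFs the minor alleles nest, giving
"staircase" pools of k+1 haplotypes with D′ = 1 between *every* pair — the
default, because (as noted under *LD blocks*) Gabriel calls at large n
require essentially complete LD, and real tag-SNP blocks have it. Lower
`ld_level` values are available for LD-estimation tests but will not form
blocks at the default cohort size.

Disease status is generated prospectively from the logistic model
(configurable intercept, per-allele main effects, dosage-product
interactions, sex/age effects — zero by default, since the emulated design
adjusts for these covariates without reporting their effects) and sampling
continues until the case and control quotas are met exactly. This
quota-retention scheme was chosen over a liability-threshold model because
the downstream analysis is logistic and case-control sampling preserves
odds ratios — so a generating per-allele OR of 0.86 or interaction OR of
0.622 is also the estimand of the corresponding fit, which is what the
recovery checks exploit. The default intercept `logit(0.25)` matches the
sample's case fraction so both quotas fill at comparable rates; a
pathological intercept that cannot reach the quota in 500× the target
draws raises an error suggesting an intercept adjustment.

All randomness flows from one integer seed: the genotype/covariate/status
stream uses `seed`, the missingness mask `seed + 1`, haplotype-EM restarts
their own documented offsets, and the permutation scan takes an explicit
seed — each stage is independently reproducible.

**What the generator does not emulate:** recombination-map realism,
population structure and admixture, relatedness, genotyping batch effects,
differential missingness. Passing tests on synthetic cohorts therefore
validate the statistical machinery under the stated sampling model, not
robustness to the confounding structure of real cohorts (the emulated
design itself could not correct for population stratification — a
limitation the simulator inherits deliberately).

# Numerical choices

* **Logistic fits**: IRLS in compiled code (RcppArmadillo), tolerance 1e-8
  on the max coefficient change, cap 25 iterations, Wald P from the normal
  reference. The permutation scan refits the interaction model hundreds of
  thousands of times (pairs × permutations), which rules out `glm()`'s
  per-call overhead; the engine is validated against `stats::glm`
  coefficients, SEs and log-likelihoods at 1e-6 in the tests, and the same
  engine and tolerances serve the single-marker scan, so permutation
  replicates are exchangeable with the observed pass. Coefficients beyond
  ±15 (or a singular information matrix) are reported as non-converged —
  the separation signature — never silently returned.
* **EM tolerances**: two-SNP 1e-9/1000 iterations; multi-SNP 1e-6/5000.
  Two-SNP EM monotonicity (the observed-data log-likelihood never
  decreases) is asserted per iteration in tests; both EMs are checked
  against exhaustive grid-search oracles on small fixtures at 1e-6.
* **D′ grid**: step 0.01; the cumulative-likelihood quantile construction
  guarantees `ci_low ≤ ci_high`.
* **Ties and degenerate inputs**: minor-allele ties break to the
  lexicographically smaller base; monomorphic SNPs are flagged by
  `recode_to_minor` and classified non-informative in LD (the two-SNP EM
  itself refuses them); all-missing columns error in `minor_allele_freq`;
  empty genotype-combination cells report `NA`, never 0%.
* **Problem sizes in the test-suite**: oracle checks run at n ≤ 30 (where
  enumeration is exact); family-wise error calibration runs 100 null scans
  at n = 600 with 12 SNPs and 200 permutations; effect-recovery checks run
  20 replicates at the full 10,039-sample design. These sizes give the
  binomial checks enough resolution (e.g. a [0.02, 0.10] acceptance band
  for a nominal 0.05 family-wise rate over 100 runs) while keeping the
  default suite under a few minutes.

# Known limitations

* Haplotype tests ignore EM uncertainty (expected counts treated as
  observed); per-haplotype results with any expected cell < 1 are flagged
  unreliable rather than suppressed.
* The block finder implements the confidence-interval D′ rule only — no
  four-gamete or solid-spine definitions.
* Exact logistic regression, genotypic (2-df) models, mixed models and
  genomic control are out of scope; so are X-chromosome conventions,
  multi-allelic variants and imputed-dosage input.
* The power model covers the allelic/trend test only, not dominant or
  recessive designs.
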