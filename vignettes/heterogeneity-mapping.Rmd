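---
title: "Mapping ancestry-related association heterogeneity with hetmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ancestry-related association heterogeneity with hetmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetmap)
```

## The problem and the model

Trans-ancestry meta-analyses of complex-disease GWAS usually find that
risk alleles replicate across populations. The interesting exceptions —
a variant strongly associated in Asian cohorts but null in European
ones, say — can arise because the causal allele itself is
population-specific (common in one ancestry, rare in the other) or
because linkage disequilibrium between a genotyped SNP and the causal
variant differs between populations. `hetmap` implements the scan that
finds such variants from per-cohort summary statistics and the follow-up
analyses that distinguish those two explanations.

The core quantity is a decomposition of Cochran's homogeneity statistic.
For effect estimates $\hat\beta_i$ with standard errors $SE_i$, weights
$w_i = 1/SE_i^2$ and pooled mean $\bar\beta = \sum w_i\hat\beta_i /
\sum w_i$,

$$Q = \sum_i w_i (\hat\beta_i - \bar\beta)^2 .$$

With cohorts partitioned into $G$ ancestry groups the statistic splits
exactly — this is the weighted analysis-of-variance identity — into
within-group and between-group parts:

$$Q_\text{between} \;=\; Q_\text{all} - \sum_g Q_\text{within}(g)
  \;=\; \sum_g W_g\,(\hat\beta_g - \hat\beta_\text{all})^2 ,
  \qquad W_g = \sum_{i \in g} w_i .$$

Under the null hypothesis that all groups share one true effect,
$Q_\text{between} \sim \chi^2_{G-1}$. The package computes the
subtraction form (it is the definition) and enforces the identity with
the direct form as an internal-consistency invariant: a negative
residual larger than $10^{-6}$ aborts with an internal-consistency
error, while negative values within that tolerance — pure floating-point
cancellation — are clamped to zero, as the identity guarantees
nonnegativity analytically.

Assumptions worth stating: effects are fixed within each ancestry group
(fixed-effect pooling throughout; no random-effects variant is offered,
because the between-group contrast *is* the quantity of interest, not a
nuisance to be absorbed); per-cohort estimates are approximately normal
with known variance — the usual large-sample summary-statistics regime;
and cohorts are independent. SNPs carried by cohorts of only one
ancestry group have no between-group contrast and are excluded from the
scan but listed in the result (`single_group_snps`), so nothing is
silently dropped.

## Calibration and thresholding

Because the scan aggregates thousands of tests, `het_scan()` reports a
genomic inflation factor
$\lambda = \mathrm{median}(Q_\text{between}) / 0.4549364$ (the null
$\chi^2_1$ median). When the caller supplies a list of SNPs believed
unrelated to the phenotype, $\lambda$ is computed on those, so true
signal does not inflate it. $\lambda$ is *reported but not applied*: a
well-designed scan has $\lambda \approx 1$ and rescaling by default
would silently change p-values. Passing `gc_correct = TRUE` divides
$Q_\text{between}$ by $\lambda$ before the $\chi^2$ tail when a user
decides the inflation is real.

The significance cutoff is Bonferroni over the number of *independent*
SNPs on the genotyping panel, not the raw SNP count; for Immunochip-
style data the convention is 26,146 independent SNPs, giving
$0.05/26{,}146 \approx 1.9\times 10^{-6}$. Both the family-wise level
and the independent-SNP count are arguments; false-discovery-rate
control is deliberately not offered, keeping the scan's decision rule
identical to the field's.

## Power

The between-ancestry statistic for two groups is
$(\hat\beta_A - \hat\beta_E)^2 / V$ with
$V = V_A + V_E$ the total variance of the difference of pooled
estimates. Under a true difference $\Delta\beta$ it is noncentral
$\chi^2_1$ with noncentrality $\Delta\beta^2/V$, so power is an explicit
tail probability. For one degree of freedom `power_het()` evaluates the
exact two-sided normal form
$1 - \big[\Phi(\sqrt{c}-\sqrt{\text{ncp}}) -
\Phi(-\sqrt{c}-\sqrt{\text{ncp}})\big]$ rather than a series expansion
(exact and fast at this scale); higher df use `pchisq(..., ncp = )`.
`min_detectable_delta()` inverts the power function by monotone
bisection to an absolute tolerance of $10^{-6}$ — power is strictly
increasing in $\Delta\beta$, so the root is unique. A representative
total variance for a well-powered chip-scale discovery analysis is
$V = 0.0030$, the default neighbourhood used in examples; at the
chip-wide level this puts 80% power near $\Delta\beta = 0.31$.

`power_association()` answers the complementary single-population
question: at a given minor allele frequency, odds ratio, sample size and
case fraction, what is the power of an ordinary Wald test? The sampling
variance uses the null (score) form
$SE^2 = [2N\,p(1-p)\,\phi(1-\phi)]^{-1}$; at the effect sizes relevant
here the difference from the alternative-variance form is negligible,
and the null form needs no iterative fitting. No published case fraction
exists for summary-level cohorts, so when the caller omits it the
function assumes 0.25 and says so with a `message()` — an assumption a
user should see, not a silent default.

## Input handling choices

* **Coordinates** are 1-based everywhere (the VCF convention); there is
  no conversion layer.
* **Allele harmonization**: the reference orientation for each SNP is
  taken from the first cohort carrying it after sorting cohort ids, with
  the alphabetically-first allele as effect allele — deterministic and
  stable under cohort reordering. Swapped cohorts get $\beta \to -\beta$
  and $eaf \to 1-eaf$; irreconcilable allele pairs drop that SNP from
  the offending cohort with a log line. Strand-ambiguous (A/T, C/G)
  SNPs are flagged but kept: frequency-based strand resolution is not
  attempted, because a wrong silent flip corrupts the sign of exactly
  the statistic this package exists to compute.
* **Missing p-values** are recomputed as $2\Phi(-|\beta/SE|)$ (Wald
  consistency); the 95% CI multiplier is 1.959964 throughout so standard
  errors derived from published CIs reproduce to four decimals.
* **LD** requires phased, complete haplotypes; `ld_pair()` errors on
  missing alleles rather than imputing, and a monomorphic column yields
  $r^2 = 0$ with a `monomorphic` flag rather than `NaN`, so panel-wide
  reports stay robust. The minor allele is defined within each panel
  separately, since the same allele can be minor in one population and
  major in another.
* **HWE**: the exact test (no mid-p) is the default for QC; the
  $\chi^2$ variant is kept for worked examples. The two agree closely
  where decisions are made (small p) but can differ in the middle of
  the range because the exact distribution is discrete.
* **Post-imputation filter**: keep `info >= 0.5` and folded MAF
  `>= 0.01`, both boundaries inclusive.
* **Logistic association** uses iteratively reweighted least squares
  (via `stats::glm`) with convergence tolerance $10^{-8}$ and at most
  100 iterations; a diverging coefficient ($|\beta| > 20$) is treated
  as separation and reported as an error naming the SNP.
* **Expression normalization** is log base 2 (the array convention; the
  choice only shifts slopes by a constant factor), quantile
  normalization *across the replicates of one individual* followed by
  collapse to the replicate mean, then median centering across
  individuals. Normalize-then-collapse was chosen over
  collapse-then-normalize: it removes replicate-level distributional
  drift before averaging. The eQTL cis-window (default ±300 kb) is
  measured from the SNP to the probe's annotated transcription start —
  the anchor had to be fixed somewhere, and TSS is the common
  convention. The Bonferroni correction counts probes tested, not
  genes.

## What the generators emulate — and what they do not

`sim_config()` describes a multi-cohort two-ancestry case-control
design; its defaults mirror an Immunochip-style study with 4 Asian and
11 European collections at one tenth of their published sizes (Asian
discovery 223 cases / 707 controls, three Asian validation cohorts of
60 / 120, eleven European cohorts of 94 / 323; prevalence 1%). One
tenth keeps individual-level generation fast while preserving the
relative precision structure (the Asian side dominates the total
variance). Tests that need full precision — parameter-recovery checks of
the scan — use half or full published sizes in the summary-statistic
path, where sample size costs nothing.

Two fidelities share the configuration:

* `gen_sumstats()` draws $\hat\beta_{ij} \sim
  N(\beta_{g(i),j}, SE_{ij}^2)$ with $SE_{ij}$ from the cohort's
  case/control counts and group allele frequency via the additive-score
  variance — exactly the sampling model the meta-analysis assumes. This
  is the calibration workhorse (type-I error, λ, null distributions at
  $10^4$ replicates).
* `gen_haplotypes()` / `gen_case_control()` / `gen_expression()`
  produce individual-level data: block-LD haplotypes from a latent
  two-founder mixture (every block SNP tied to a block founder allele at
  correlation $t^{1/4}$, giving all pairs expected $r^2 = t$ while
  preserving marginal frequencies exactly; infeasible frequency/LD
  combinations error with the bound), logistic disease sampling with
  the intercept solved numerically for the target prevalence, and
  dosage-responsive log-normal expression.

Random-number streams are split per cohort and per SNP, so adding a
cohort or SNP to a configuration never perturbs the draws of the
others; every generator is a pure function of (config, seed).

What passing tests on these data do *not* show about real data: the
generators have no realistic LD beyond the block targets (no coalescent
history, no allele-frequency spectrum), no genotyping or imputation
error, no phenotype misclassification, no cryptic relatedness, and
cohort effects are exactly normal around the group truth. They validate
the *statistics* — sizes, power, identities, recovery — not robustness
to real-data pathologies.

## Problem sizes in the shipped tests

The test suite runs at desk scale by design: the null-calibration checks
use 10,000 replicates of a 15-cohort two-ancestry design, the genomic-
control check uses a 1,153-statistic null set, the null-scan check uses
a 5,000-SNP panel, oracle-equivalence loops use 1,000 random instances,
and the Monte-Carlo power oracle uses $10^6$ draws. Parameter-recovery
scans use 120–500 SNP panels with one planted ancestry-specific effect
at half or full published cohort sizes, configurations whose analytic
power (computed by `power_het()` inside the test itself) exceeds 0.9
before any data are drawn.

## Known limitations

* No Bayesian trans-ethnic heterogeneity models (MANTRA-style) and no
  random-effects pooling; the package is faithful to the fixed-effect
  Q-decomposition approach.
* No EM haplotype-frequency estimation from unphased genotypes: LD is
  defined on phased data only.
* Genotype imputation itself is out of scope; only the post-imputation
  filter is implemented.
* The conditional-association machinery reports raw conditional
  p-values; it does not adjudicate "no secondary signal" thresholds.
* `run_followup()` needs the hit SNPs present in the supplied haplotype
  panels; absent SNPs are reported as such rather than imputed.
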