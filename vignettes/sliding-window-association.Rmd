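---
title: "Sliding-window variant-set association: models, calibration and design"
author: "windowscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window variant-set association: models, calibration and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windowscan)
```

## The problem

Resequencing a candidate gene in a small clinical cohort yields hundreds of
SNPs, most of them rare, against a handful of phenotypes — here,
right-censored overall survival and a quantitative expression level for the
gene. Single-marker tests are hopeless for sub-1% variants at n ≈ 60, so
the package tests *sets* of markers: every contiguous window of 10–50
consecutive SNPs (and the region as one entity), slid one marker at a time.
Two set statistics are used, one per phenotype, and both are calibrated by
permutation because asymptotic reference distributions are unreliable at
this sample size.

## Data container

Genotypes live in a `GenotypeExperiment`, a `RangedSummarizedExperiment`
whose rows are biallelic variants (positions, REF/ALT, identifiers) and
whose single `dosage` assay counts ALT alleles per sample (0/1/2, `NA` for
missing calls). All statistics orient dosages to the *minor* allele using
the pooled minor-allele frequency: `f = Σ dosage / (2 · n_called)`,
`MAF = min(f, 1 − f)`. A tie at `f = 0.5` deterministically treats ALT as
minor so statistic signs are reproducible. MAF is computed pooled across
all samples (tumor and normal alike when both are present); a per-cohort
MAF was considered and rejected because the frequency filter and statistic
orientation should not depend on a sample-subset choice.

## Expression: the DMAF scan

Expression probes are averaged per sample and the average dichotomized at
its median; samples exactly at the median join the low group
(deterministic; random assignment was rejected for reproducibility). For a
window W the statistic is

D(W) = Σ_{m ∈ W} ( f₁ₘ − f₀ₘ ),

the signed sum over window markers of the difference in minor-allele
frequency between the two groups, each frequency computed over the
non-missing samples of its group. Inference is two-sided on |D|. A signed
sum captures direction-consistent frequency shifts; an absolute-sum variant
(Σ |f₁ − f₀|, sensitive to direction-mixed shifts) is available via
`statType = "absolute"`. No per-marker variance standardization is applied;
the permutation null absorbs the heteroscedasticity across windows of a
given size.

## Survival: the burden-score Cox scan

For each window the per-sample burden is the integer count of minor alleles
over the window's variants (missing dosages contribute 0 — conservative
toward the null and keeps scores integral; mean imputation was rejected).
The burden enters a single-covariate Cox proportional-hazards model fitted
by maximizing the Breslow-tie partial log-likelihood

ℓ(β) = Σ_{event times t} [ Σ_{events at t} β·xᵢ − d_t · log Σ_{j at risk} exp(β·xⱼ) ]

with safeguarded Newton ascent (the scalar likelihood is concave;
step-halving enforces monotone increase; a log-sum-exp shift keeps risk
sums finite). Breslow tie handling is the simplest standard choice; Efron
weights would be a straightforward extension. When the likelihood is
monotone (risk ordering perfectly concordant with the burden), β is capped
at ±15 — hazard ratios beyond e¹⁵ are numerically indistinguishable — and
the fit is flagged `divergent`; the capped likelihood-ratio statistic
still enters the permutation comparison so observed and null statistics
are computed by the identical rule. The test statistic is
LRT = 2·(ℓ(β̂) − ℓ(0)).

## Permutation calibration and family-wise control

Both scans permute the *phenotype* — the group-label vector for DMAF, the
(time, event) pair vector for survival — holding genotypes fixed, with the
same permutations shared by every window. Per window,

p_unadjusted = (1 + #{b : T_b ≥ T_obs}) / (1 + B),

the add-one estimator that guarantees valid p-values. Per window *size*,
p_adjusted compares each window's observed statistic against the
permutation distribution of the maximum statistic over all windows of that
size, the standard max-statistic construction for family-wise type-I error
control within a size class; the whole-region window forms its own class.
Consequently `p_adjusted ≥ p_unadjusted` always holds. When the number of
distinct relabelings (`choose(n, n₁)` for DMAF, `n!` for survival) is at
most `exhaustiveCap` (default 10,000), exhaustive enumeration replaces
Monte Carlo and p-values are exact fractions. The default B = 50,000 suits
a production run; the examples and tests here use B in the hundreds to
keep runtimes in seconds.

## Candidate prioritization

After both scans, candidate regulatory SNPs are selected by a fixed
cascade: take the SNPs of the top survival window (minimum p, ties broken
by larger statistic then smaller start index — the deterministic ordering
is a package choice, as published analyses rarely state tie-breaks); keep
those inside user-supplied transcription-factor binding intervals (BED,
0-based half-open, converted once at import so a SNP at 1-based `pos`
matches `[start, end)` iff `pos − 1 ∈ [start, end)`); keep those with
genotypic LD R² > 0.8 (strict) against at least one SNP of the top
expression window; report survivors with percent MAF (`"<1%"` below 1%)
and their TF labels. LD is the squared Pearson correlation of unphased
dosages over jointly-called samples (composite r²): the data are unphased
patient genotypes, so a haplotype-EM r² would add a phasing model the
analysis does not need. Undefined LD (a constant dosage column) counts as
non-passing. Only the published direction — survival-window SNPs filtered
against expression-window SNPs — is implemented.

## The synthetic cohort generator

`simulationConfig()` defaults encode the cohort the scans assume: 60
samples, 404 SNPs over a contiguous ~160 kb region, 19% of variants drawn
from a rare spectrum (true frequency Uniform(0.001, 0.01)) and the rest
common (Uniform(0.01, 0.5)), so that at 120 alleles roughly 81% of
variants realize MAF > 1% — matching a 326/404 common/rare split by
construction. Haplotypes are drawn i.i.d. from a population distribution
defined per 20-variant block by thresholding a latent AR(1) Gaussian
process (ρ = 0.9) at `qnorm(f)`: marginals are exactly Bernoulli(f), so
realized allele counts show the Binomial(2n, f) dispersion a real cohort
of this size shows, while adjacent sites are genuinely dependent
(within-block mean r² ≈ 0.13 versus ≈ 0.017 under independence), including
co-carried rare alleles. A copying-pool scheme (grow haplotypes by
template copying with per-site refresh) was tried first and discarded:
site-independent refresh draws produce frequency overdispersion but no
between-site dependence, so it cannot deliver LD and a faithful MAF
spectrum at the same time.

Expression is `baseline + effect · burden(causal window) + N(0, noise_sd)`
with three probe columns adding independent N(0, 0.5) probe noise, echoing
multiple array probe sets measuring one transcript. Survival is
exponential with rate `h₀ · exp(log_hr · burden)` (h₀ = log 2 / 20 per
month, i.e. a 20-month median at burden 0 — a realistic resected-cohort
scale); censoring is an independent exponential calibrated to a target
censored fraction, 0.3 by default (the real-world fraction is rarely
printed; 0.3 is an assumption, stated here). Censoring independent of
genotype matches the Cox model assumption being tested. What the generator
does *not* emulate: tumor/normal pairing (samples are independent),
somatic/germline distinction, population stratification, genotyping error,
and base-pair-scaled LD decay. Passing calibration tests on these cohorts
therefore shows correct *statistical mechanics* — valid permutation
p-values, nominal family-wise control, faithful likelihood maximization —
not robustness to those real-data complications.

## Numerical and testing choices

Newton iterations stop when the score falls below 1e-11 (relative);
agreement with an independent golden-section maximizer of the same
likelihood and with `survival::coxph` (Breslow) is checked to 1e-6.
Degenerate inputs are handled deterministically: constant covariates give
LRT = 0; markers uncallable within one phenotype group contribute 0 to
DMAF with a warning; samples with missing survival fields are dropped with
a message; an all-identical expression vector is an error. Calibration
tests run 200 null cohorts at n = 60, M = 100, B = 500 with window sizes
{10, 25} and check the per-size family-wise rejection rate at α = 0.05
against the exact binomial 95% band, plus a Kolmogorov–Smirnov check that
single-window unadjusted p-values are uniform; planted-signal recovery
(per-allele log hazard ratio log 2 on a 25-SNP window) is compared against
a frozen 300-replicate `coxph` oracle envelope. These problem sizes keep
the full suite in minutes while leaving the binomial bands tight enough to
detect miscalibration.

## Limitations

Permutation p-values have resolution 1/(B+1); paired tumor/normal samples
are treated as independent (as the cohort design caveat notes); the DMAF
weighting is the unstandardized signed sum described above, and analyses
that standardize per-marker variances will differ window-by-window;
multivariable adjustment (age, stage) is out of scope.
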