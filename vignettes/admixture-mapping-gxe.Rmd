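---
title: "Admixture mapping with a local-ancestry-by-BMI interaction: models and design"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture mapping with a local-ancestry-by-BMI interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

# The scientific problem

In recently admixed populations such as African Americans, chromosomes are
mosaics of segments inherited from the two ancestral populations. At any
locus an individual carries 0, 1 or 2 copies of (say) European ancestry --
the *local ancestry* -- and the genome-wide average of these copies is the
*global ancestry* proportion $\theta$. Admixture mapping scans local
ancestry, rather than genotype, for association with disease: a locus where
cases systematically carry less European ancestry than controls points to
risk variation that differs in frequency between the ancestral populations.

`admixscan` implements this scan for binary (case-control) outcomes with a
*gene-environment* twist: the association between local ancestry $a_m$ at
marker $m$ and disease is allowed to depend on body mass index. The
per-marker working model is the multiple logistic regression

$$\mathrm{logit}\,P(Y=1) = \beta_0 + \beta_{la} a_m + \beta_{bmi}\,BMI +
\beta_{int}\, a_m \times BMI + \beta_{age}\,age + \sum_{j=1}^{10}\gamma_j PC_j,$$

and the scan statistic is the Wald test of $\beta_{int}$, the
log-odds-ratio of the ancestry effect per kg/m^2 of BMI. Per-study scans
are combined across cohorts by inverse-variance-weighted fixed-effects
meta-analysis, and genome-wide significance is calibrated empirically by a
paired min-p permutation procedure. Follow-up models include BMI-stratified
ancestry effects, a 3-df likelihood-ratio test of group-by-BMI-category
interaction, four SNP-by-BMI interaction parameterizations, and conditional
adjustment of a SNP signal for local ancestry at a named marker.

Because the individual-level cohorts this methodology targets are held
under restricted access, the package ships a first-class simulator that
generates admixed cohorts with known ancestry truth; every downstream stage
is exercised and tested against that truth.

# The cohort simulator

## Ancestry tract model

Each haplotype is a two-state Markov chain (African/European) along each
chromosome. The first marker of a chromosome is European with probability
$\lambda$; between adjacent markers separated by $d$ bp the chain re-draws
its state from the stationary distribution $\{\lambda, 1-\lambda\}$ with
probability $1 - \exp(-G r d)$, where $G$ is the number of generations
since admixture and $r$ the per-bp per-generation recombination rate.
Defaults are $\lambda = 0.2$, $G = 7$, $r = 10^{-8}$ -- the canonical
African American admixture configuration.

This "re-draw from stationary" kernel is the Li-Stephens/LAMP-style
approximation to pedigree recombination: re-draw events form a Poisson
process of rate $G$ per Morgan, so ancestry switch points have exponential
spacing. A useful identity for testing: a re-draw changes the *visible*
label only with probability $2\lambda(1-\lambda)$, so observable
same-ancestry segments have mean length $1/(2 G \lambda (1-\lambda))$
Morgans ($\approx 0.45$ M at the defaults), while the re-draw events
themselves have mean spacing $1/G$. The property tests assert the
closed form for the observable segments.

Individual admixture proportions vary in real cohorts (reported SDs around
10 percentage points in African American studies). The simulator therefore
draws a per-individual proportion $\lambda_i \sim
\mathrm{Beta}$ with mean `lambdaEur` and SD `lambdaSd` (default 0.1), shared by
the individual's two haplotypes; `lambdaSd = 0` recovers the fixed-$\lambda$
model. Without this between-individual variance, global ancestry is almost
constant ($\mathrm{SD}(\theta) \approx 0.02$ from tract noise alone) and no
principal component can recover it; with it, PC1 and $\theta$ correlate at
0.98-0.99, as observed on real admixed genotype data.

## Genotypes, covariates, outcome

Given a haplotype's ancestry at a marker, its allele is alternate with
probability `freq_eur` (European) or `freq_afr` (African) from the
ancestral panel; the genotype is the sum over the two haplotypes and the
true local ancestry is the number of European haplotype labels. The default
synthetic panel draws marker positions with exponential spacing averaging
150 kb -- the density of a 20,000-marker genome-wide AIM set on the human
autosomes -- and uniform ancestral frequencies, optionally rejected until
the frequency difference exceeds a delta floor.

Covariates are independent truncated normals: BMI
$\sim N(32.5, 8.7^2)$ kg/m^2 truncated at 15, age $\sim N(41, 13^2)$ years
truncated at 18, matching an obesity-enriched adult case-control
population. The joint BMI-age distribution of the motivating cohorts is not
published beyond per-group moments, so independence is a modelling choice,
not an asserted fact about any real cohort.

Outcomes are Bernoulli draws from

$$\mathrm{logit}\,P(case) = \beta_0 + \beta_{la} a + \beta_{bmi} BMI +
\beta_{int}\, a (BMI - 25) + \beta_{age}\, age,$$

with $a$ the true European copy count at a designated causal marker. BMI is
centered at 25 kg/m^2 *inside the product term only*: the main ancestry
effect $\beta_{la}$ is then interpretable at the normal-weight boundary and
the baseline case fraction does not drift as $\beta_{int}$ moves. Fitted
models are invariant to this centering up to reparameterization (a property
test asserts the exact Jacobian rescaling under affine BMI re-encoding).
Default effect sizes plant an interaction odds ratio of 0.95 per kg/m^2 per
European copy and a main ancestry odds ratio of 0.74, the magnitudes this
study design is meant to detect.

## What the simulator does not emulate

No genotyping error, no phasing, no sex chromosomes, no three-way
admixture, no linkage disequilibrium within ancestral populations beyond
what admixture itself induces, and independent covariates. Passing tests
demonstrate that the statistical machinery is correct under the stated
generative model; they do not certify performance under array artefacts or
ancestral LD.

# Quality control

`runQc` applies the array-QC cascade in fixed order -- per-sample call rate,
per-marker call rate, minor allele frequency, Hardy-Weinberg equilibrium --
with strict inequalities at the default thresholds (0.95, 0.95, 0.01,
1e-6): boundary values are retained. HWE uses the 1-df chi-square
goodness-of-fit against $p^2, 2pq, q^2$ without continuity correction,
computed in controls only; at a 1e-6 screening floor the chi-square and
exact tests are interchangeable, and the chi-square is closed-form
testable. Monomorphic markers return p = 1 (no test possible) and a marker
failing several filters is attributed to the first applicable one. Under
two-way admixture the Wahlund effect depresses heterozygosity mildly
(fixation index $\lambda(1-\lambda)\delta^2 / (\bar p \bar q) \lesssim
0.1$), far from the 1e-6 floor, so the HWE filter removes essentially
nothing on simulated admixed cohorts -- a property test asserts this.

# Local ancestry inference

Markers are first restricted to AIMs ($|freq_{afr} - freq_{eur}| > 0.2$,
strict) and LD-pruned by a greedy sliding window (window 50, step 5,
$r^2 > 0.1$ removes the later marker). The hidden Markov model then treats
the diploid European copy count $k \in \{0,1,2\}$ as the hidden state:

* initial distribution $\mathrm{Binomial}(2, \lambda)$;
* transitions: the two haplotypes evolve independently under the tract
  kernel above, composed into a 3x3 diploid matrix per marker interval;
* emissions: each haplotype contributes an alternate allele with
  probability `freq_eur` or `freq_afr` by its ancestry, so
  $P(g \mid k)$ is a Binomial mixture; frequencies are floored to
  $[10^{-4}, 1 - 10^{-4}]$ so that a panel frequency recorded as 0 or 1
  (always an estimate) cannot produce a zero-likelihood lock-in; missing
  genotypes emit likelihood 1 in every state.

Posteriors come from the scaled forward-backward recursion per chromosome
(exactness is asserted against an exhaustive-path oracle on up to 4-marker
instances at $10^{-10}$), and calls are the per-marker posterior mode
rather than Viterbi -- the calls are consumed downstream as an additive
0/1/2 dosage, so marginal-posterior optimality per marker is the right
criterion. Global ancestry is $\theta_i = \sum_m c_{im} / (2M)$; the
divisor $2M$ puts $\theta$ on the proportion scale. The population
parameter $\lambda$ is used for the prior even though individuals vary;
with AIM-density marker maps the emissions dominate and decoding accuracy
at the bundled desk scale (2,000 AIMs, 300 individuals) is about 0.97.

Principal components are computed from all post-QC markers (not only AIMs:
the PCs serve as confounder controls, not ancestry estimates), with markers
mean-imputed, centered by $2f$ and scaled by $\sqrt{2f(1-f)}$; scores are
left singular vectors scaled by singular values, with the deterministic
sign convention that each component's largest-magnitude marker loading is
positive.

# Association models

All models are logistic regressions fitted by IRLS (`stats::glm.fit`) with
tolerance $10^{-8}$ and at most 50 iterations. A fit is flagged
non-converged when IRLS fails to converge or any coefficient exceeds 15 on
the logit scale (a separation guard: odds ratios beyond $e^{15}$ are never
data-supported at these sample sizes). Rank-deficient designs drop aliased
columns and record them; untestable and missing results carry
machine-readable reason codes and are excluded from permutation minima.
Interaction inference is by Wald test except for the group-by-BMI-category
comparison, which the study design specifies as a 3-df likelihood-ratio
test between nested models.

BMI categories are left-closed: $[25, 30)$ and $[30, \infty)$ for 3-level
analyses, splitting at 35 for the 4-level group analysis. Published
category labels ("25-30", ">30") do not resolve the boundary; left-closed
is fixed and stated. Per-SD BMI standardization uses the pooled
within-dataset mean and SD. Strata require both outcome classes and at
least 10 cases; smaller strata yield missing results with a reason, which
the meta-analysis step simply omits. PCs are always computed per dataset
and never pooled across cohorts -- each study is analyzed separately and
only summary estimates are combined.

# Meta-analysis and significance

Study estimates combine as $\hat\beta = \sum w_i \beta_i / \sum w_i$ with
$w_i = 1/se_i^2$, $se = (\sum w_i)^{-1/2}$; heterogeneity is Cochran's
$Q = \sum w_i (\beta_i - \hat\beta)^2$ against $\chi^2_{k-1}$ and
$I^2 = \max(0, (Q - (k-1))/Q) \cdot 100$, floored at zero. Published
tables reporting ORs with 95% CIs are inverted via
$se = (\ln hi - \ln lo) / (2 \times 1.959964)$; the constant is the exact
normal quantile rather than 1.96 so the inversion is deterministic at more
digits than any printed table. The bundled worked examples reproduce every
printed meta OR of the motivating study's tables within the +-0.02
tolerance implied by input rounding.

The min-p permutation estimates the family-wise threshold for the
interaction scan: within each dataset the (case status, PC1) *pairs* are
jointly permuted against all other columns, preserving the
global-ancestry-case correlation while breaking marker-level association;
the full scan and cross-study meta-analysis are recomputed per iteration
and the smallest testable interaction p is stored. The threshold is the
$\alpha$ empirical quantile of the minima using the linear-interpolation
(type 7) definition -- the "5th percentile of rank-ordered statistics"
phrasing does not name a quantile rule, so one is fixed and documented.
PCs are *not* recomputed inside iterations: the pair-shuffle construction
explicitly preserves the PC1-outcome linkage and recomputation would break
it. On independent null markers with fully exchangeable outcomes the
threshold matches the Sidak value $1 - (1-\alpha)^{1/M}$, which the
acceptance suite checks at $M = 50$ markers and 2,000 iterations. One
subtlety worth knowing: when the outcome genuinely depends on a retained
covariate (say BMI), permuting raw outcomes breaks that dependence and the
permutation null becomes mildly conservative in the far tail (we measure
thresholds about 25-35% above Sidak at desk scale with a BMI main effect
present). This is inherent to raw-outcome permutation under nuisance
covariates, not an error: the empirical threshold then correctly reflects
the procedure actually run, which is exactly why the empirical threshold,
not the closed form, is used for inference. For candidate-region SNP analyses the
alternative is simpleM: the effective number of tests is the smallest
number of top eigenvalues of the marker correlation matrix capturing 99.5%
of the trace, and the threshold divides $\alpha$ by the most conservative
Meff across datasets.

# Numerical and design notes

* All randomness is seeded through configuration objects; identical
  configurations reproduce every output bit-exactly.
* Posterior-mode ties (rare, only with degenerate frequencies) resolve to
  the smallest copy count.
* The quantile of the permutation minima is monotone non-increasing in the
  number of testable markers; iterations with no testable marker are
  redrawn and counted.
* Effect alleles are always VCF alternate alleles; positions are 1-based
  throughout; TSV with `NA` sentinels is the interchange format.
* AIM selection precedes LD pruning (the reverse order is defensible; this
  order prunes within the marker set actually used for inference).

# Problem sizes used by the test and acceptance harnesses

The bundled harnesses run at desk scale, chosen to keep the full suite in
the tens of minutes while leaving the asserted properties
Monte-Carlo-stable: estimator coverage uses 100 cohorts of n = 1,500 at 500
AIMs; null calibration uses 1,000 independent tests (20 cohorts, one
marker per chromosome); the permutation-vs-Sidak check uses 50 independent
markers, n = 1,000 individuals and 2,000 iterations; local-ancestry
accuracy uses 2,000 AIMs at 150 kb density with 300 individuals. The
coverage and calibration harnesses evaluate the interaction estimator at
the simulator's true local ancestry: they target the sampling properties
of the estimator itself, while HMM call accuracy is measured by its own
criterion -- at 500-AIM desk scale, call error would attenuate the planted
interaction and conflate the two properties.

# Known limitations

The HMM assumes the ancestral allele frequencies are known (panel
estimates enter as truth, softened only by flooring); no EM re-estimation
is performed. Ancestry-ancestry LD between AIMs left after pruning is
modelled only through the Markov chain. The simulator's independence
assumptions above mean calibration results transfer to real data only to
the extent those assumptions hold; the QC, scan, meta and threshold
machinery, however, are generic and make no simulator-specific
assumptions.
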