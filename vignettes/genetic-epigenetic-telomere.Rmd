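---
title: "Methods: genetic-epigenetic analysis of newborn telomere length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic-epigenetic analysis of newborn telomere length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloscan)
```

## Scope and data model

`teloscan` analyses the interplay of candidate SNP genotypes and
cord-blood DNA methylation in shaping newborn telomere length. The
phenotype is the qPCR T/S ratio (telomere repeat copy number over a
single-copy gene, normalized to the sample-set mean); methylation is
modelled on the M-value scale, `M = log2((meth + 1)/(unmeth + 1))`,
where the unit offset keeps the transform defined at zero intensity
(a beta-value pipeline with zero offset is undefined there). Genotypes
are minor-allele dosages in {0, 1, 2}; the minor allele is defined by
the observed sample frequency, with an exact 0.5 tie keeping the file's
alternate allele as minor so parsing is deterministic. Coordinates are
1-based inclusive everywhere inside the package; BED manifests are the
single 0-based surface and are converted at the boundary.

A `study_dataset` bundles the dosage matrix, M-value matrix, covariate
table and phenotype under one sample ordering; `validate_dataset()`
checks every structural invariant and returns a report rather than
failing, so a pipeline can surface all problems at once.

## The four analysis steps

**Step 1, SNP association.** Telomere length is regressed on each coded
SNP with the full covariate design. Dominant coding (carrier of the
minor allele) is the primary analysis; additive coding (allele count)
is the robustness companion. Significance is nominal at `alpha` (0.05):
this step is a candidate screen, not a discovery scan.

**Step 2, cis-mQTL.** Every SNP-CpG pair with `|pos_CpG - pos_SNP| <=
cis_window_bp` (500 kb, boundary inclusive, same chromosome) is tested
by regressing the CpG M-value on the coded SNP plus covariates.
Because the number of pairs far exceeds the sample size, residual
variances are moderated: Smyth's method-of-moments fit of a scaled
inverse-chi-square prior on the log variances (the trigamma equation is
inverted by Newton iteration to 1e-8), each pair's variance shrunk to
`(d0*s0^2 + df*s^2)/(d0 + df)` and the t statistic referred to
`df + d0` degrees of freedom. Family-wise control is Bonferroni over
the full pair universe with the boundary convention `p <= alpha/m`
(ties at the threshold are significant). The mQTL set is the
*intersection* of the dominant-model and additive-model significant
sets; `rule = "either"` relaxes this to the union for sensitivity
analyses.

**Step 3, mediation.** CpGs in significant mQTLs are screened for a
marginal telomere association (TL ~ CpG + C, nominal 0.05); the screen
deliberately omits the SNP — the wording of the design is marginal —
but `include_snp = TRUE` provides the conditional variant. For each
candidate pair the product-of-coefficients decomposition is estimated
from the mediator model (`M ~ SNP_dom + C`, coefficient `a`) and the
outcome model (`TL ~ SNP_dom + M + C`, coefficients `c'` and `b`):
DE = c', IE = a*b, TE = DE + IE. In linear models without a
treatment-mediator interaction this coincides exactly with the causal
ACME/ADE decomposition, so the quasi-Bayesian machinery of
simulation-based mediation packages is unnecessary; the difference
method (total-model SNP coefficient minus c') agrees with the product
method to numerical precision, and the test suite asserts it. The
proportion mediated IE/TE is reported only when DE and IE share a
sign; with opposite signs the ratio is not a proportion and is left
undefined.

Inference is by bootstrap percentiles: individuals (whole rows, so the
covariate joint distribution is preserved) are resampled with
replacement `n_boot` times (default 1,000), both models refit, and each
effect's 95% interval taken as the 2.5/97.5 empirical percentiles with
linear interpolation (quantile type 7). The bootstrap p-value is the
symmetric two-sided form `2*min(P(est <= 0), P(est >= 0))`, capped at
1. Replicates in which the resampled SNP or CpG is constant cannot be
fit; they are redrawn and counted, and more than 10% degenerate draws
aborts with an error — at that point the data are too sparse for
resampling inference. The proportion-mediated distribution uses only
same-sign replicates, and their count is reported alongside.

**Step 4, effect modification.** The interaction model
`TL ~ SNP + CpG + SNP*CpG + C` uses additive coding (a dominant-coded
product column is more often degenerate in small strata). Pairs that
were significant mQTLs are excluded *before* testing: when the SNP
drives the CpG, genotype and methylation are collinear by construction
and the interaction coefficient is not interpretable. The Bonferroni
denominator for the interaction is the size of this reduced universe —
the exclusion rule defines the tested family; the SNP main effects are
separately Bonferroni-controlled over the number of SNPs (26 in the
default panel; `m_snp_main` overrides).

## The QC chains

Genotype QC runs in a fixed order: SNP call rate, then sample call
rate over retained SNPs, then imputation, then MAF and HWE filters.
All thresholds are strict ("lower than 95%" drops only < 0.95; a MAF of
exactly 0.01 survives). The HWE test is the 1-df Pearson chi-square at
the observed allele frequency without continuity correction, with
monomorphic input defined as chi2 = 0, p = 1. Imputation draws missing
dosages from each SNP's empirical genotype distribution: the candidate
panel is sparse (no surrounding haplotype scaffold), so LD/reference
based imputation has nothing to condition on here; the scheme is
deterministic under a seed and documented in the QC report.

Methylation QC mirrors the array-processing order: detection filtering
(a call fails when detection p > 1e-16; the conventional threshold is
used for the config default `detection_p_max`, and any other reading is
one config entry away), probe then sample call-rate drops, KNN
imputation, empirical-Bayes batch and position adjustment, 3-IQR
trimming, probe blacklists, cell-type deconvolution. KNN imputation is
probe-wise: the K = 10 nearest probes by Euclidean distance over
co-observed samples (normalized by their number) supply an unweighted
mean, skipping neighbours missing at the target sample, with the probe
mean as fallback; distance ties break by row order so the procedure is
deterministic. Note the averaging is unweighted, so an exact duplicate
probe dominates only at K = 1.

The batch adjustment is a parametric location-scale empirical-Bayes
model fitted per technical factor (batch first, then array position —
sequential rather than joint, so each factor's report is attributable):
probes are standardized to pooled mean/variance, per-level location
shifts get a normal prior whose variance is estimated by method of
moments with estimation noise subtracted (truncated at zero, so a
common shift collapses to full pooling and is removed essentially
exactly), per-level scale factors get an inverse-gamma prior, the two
posteriors are iterated to 1e-10, and the pooled scale is restored.
Each probe is finally recentred so its pooled mean is preserved
exactly. The adjustment is only approximately idempotent: a second
pass re-estimates the small shrinkage leftovers (an order of magnitude
below the first-pass change), which is inherent to any genuine
empirical-Bayes shrinkage, not a defect.

Deconvolution solves `min ||R w - m||^2, w >= 0` per sample by
Lawson-Hanson NNLS against a cell-type reference matrix and rescales
`w` to sum to one. Seven cord-blood cell types are modelled; in
downstream designs the granulocyte column — the dominant cord-blood
fraction — is dropped to break the sum-to-one collinearity.

Within regression, categorical covariates (parity, education, smoking)
are dummy-coded against their first declared level. Education in
particular could be entered ordinally (its levels are ordered); the
categorical encoding is the default because it is robust to
non-monotone effects, and nothing in the model layer depends on the
choice.

## The synthetic cohort generator

The generator emulates the study's data structure with every
generative parameter retained: ~26 biallelic candidate SNPs with fixed
MAFs drawn under Hardy-Weinberg equilibrium (so the HWE filter is
calibrated at its nominal level); cis CpGs whose latent M-values are a
cell-type mixture plus mQTL effects plus Gaussian noise; Dirichlet
cell mixtures calibrated to a granulocyte-dominated cord-blood profile;
per-(probe, batch) location and scale technical effects; detection
failures and missingness as independent Bernoulli events; ten
covariates drawn from the reference cohort margins (sex ~ Bern(0.505),
gestational age ~ N(39.03, 1.64^2) weeks, birth weight ~ N(3.38,
0.48^2) kg, and so on); and a telomere phenotype realized from the
structural model `TL = 1.03 + sum c'*dosage + sum b*M + sum
beta12*dosage*M + covariate effects + N(0, 0.20^2)` in T/S units.
The default baseline mean 1.03 and SD 0.20 are the cohort's marginal
telomere moments; the residual (post-covariate) SD is not reported
anywhere, so the marginal SD is used as a documented upper bound.
Covariate effects default to zero so the marginal calibration holds
exactly. Each mediation path's true total effect obeys TE = c' + a*b
identically, which recovery tests exploit.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium between the
candidate SNPs (they are drawn independently), joint dependence among
covariates (only margins are matched), genome-scale probe counts,
array control probes (so functional normalization is out of scope; the
generator emits already-normalized intensities), and any real
cell-type reference (the deconvolution reference is synthetic, with
well-separated cell-specific means, so deconvolution is validated by
recovery, not by replication of a published reference).

The default MAFs of the 26-SNP panel are likewise synthetic: observed
cohort frequencies are deposited in an external archive rather than
printed, so a fixed, documented spread over (0.1, 0.5) is used.

Determinism: every generator accepts a seed, and `seed = NA` switches
to stream mode (draws from the ambient RNG state), which experiment
drivers use to generate many cohorts from one seeded stream.

## Numerical choices and degenerate inputs

* OLS is QR-based; standard errors come from `s^2 (X'X)^{-1}` and
  two-sided p-values from the t distribution on `n - rank` df. Designs
  are checked for full rank up front and dependent columns are named.
* In the moderation fit, when the observed log-variance dispersion does
  not exceed the chi-square sampling noise `trigamma(df/2)`, the prior
  is degenerate: `d0 = Inf` and every moderated variance equals the
  geometric mean variance, so equal observed variances pass through
  unchanged and the moderated t reduces exactly to the ordinary t. The
  chi-square log-bias correction is applied only in the finite-`d0`
  branch (applying it in the degenerate branch would rescale equal
  variances away from their common value).
* Constant coded genotypes (e.g. no minor-allele carriers in a dominant
  coding) make a pair untestable; scans report the row with missing
  estimates and a flag instead of failing.
* Scans fit complete cases per pair; with trimming-induced missingness
  the residual df can differ across pairs, in which case moderation
  hyperparameters are estimated from the modal-df pairs and each pair
  is shrunk with its own df (with complete data this reduces to the
  common-df formula).
* IQR trimming is single-pass (quartiles are not recomputed after
  removal) with type-7 interpolated quartiles; a constant probe has
  IQR 0 and nothing is trimmed.
* The bootstrap uses percentile intervals with linear interpolation;
  no BCa or studentization, matching the percentile convention of the
  inference it reimplements.

## Problem sizes in the test suite

The suite validates the pipeline at desk scale: descriptive arithmetic
on the 281-pair margins; interaction-model recovery on 200 cohorts of
n = 5,000 (mean recovered coefficients checked against the generative
values within two Monte-Carlo standard errors); Bonferroni family-wise
error on 400 all-null scans of 2,000 pairs each; bootstrap mediation
coverage and size on 300 simulations of n = 500 with 500 bootstrap
replicates; and oracle equivalences (QR OLS vs normal equations, HWE
vs the direct chi-square formula, cis enumeration vs a brute-force
double loop, product- vs difference-method indirect effects) on
hundreds to thousands of random systems. Two-MC-SE recovery checks
are, by construction, ~5%-level statistical assertions: on a frozen
seed a correct implementation can land outside the band, which is why
the suite pairs them with the exact oracle equivalences.

## Known limitations

Mediation assumes the causal ordering genotype -> methylation ->
telomere length and no unmeasured mediator-outcome confounding;
sensitivity analysis for the latter is out of scope. Methylation and
telomere dynamics are intertwined in reality (either can regulate the
other's machinery), so indirect effects are associational evidence,
not proof of mechanism. Trans effects, haplotype-based tests, multiple
joint mediators and Mendelian randomization are deliberate non-goals
of this package.
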