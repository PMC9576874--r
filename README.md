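# teloscan

Genetic and epigenetic regulation of newborn telomere length.

Telomere length at birth — measured in cord blood as the qPCR T/S ratio,
the telomere repeat copy number relative to a single-copy gene — tracks
into later life and varies substantially between same-aged newborns.
Part of that variation is heritable, and part of the heritable signal
may act *through* or be *modified by* DNA methylation at CpGs near the
variant. `teloscan` implements, as a tested and reusable pipeline, the
four-step candidate-gene analysis that dissects this interplay in a
birth-cohort setting (a few dozen ageing/telomere-related SNPs, array
methylation, ~300 mother–newborn pairs), together with the full
genotype and methylation QC chain and a synthetic-cohort generator with
known ground truth so every stage is verifiable at desk scale.

It is aimed at molecular-epidemiology analysts who want the model layer
(scans, mediation, interaction) decoupled from cohort-specific data
wrangling, and at methodologists who want a calibrated simulation
harness for cis-mQTL/mediation designs.

## The models

With covariates **C** (newborn sex, gestational age, ethnicity, birth
weight, maternal pregnancy complications, pre-pregnancy BMI, parity,
education, smoking, paternal age, and estimated cord-blood cell-type
proportions), the four steps are:

1. **SNP association** — `cordTL = β0 + β1·SNP + Cᵀγ + ε`, one model
   per SNP under dominant (minor-allele carrier) and additive
   (minor-allele count) coding; nominal significance at 0.05.
2. **cis-mQTL scan** — `M_cpg = β0 + β1·SNP + Cᵀγ + ε` for every
   SNP–CpG pair within ±0.5 Mb, with empirical-Bayes moderated t
   statistics (residual variances shrunk toward a scaled
   inverse-chi-square prior fitted across pairs) and Bonferroni control
   over all tested pairs; a pair is called an mQTL when significant
   under **both** codings.
3. **Mediation** — for mQTL CpGs also nominally associated with
   telomere length: mediator model `M = a·SNP + Cᵀγ₁` and outcome model
   `cordTL = c′·SNP + b·M + Cᵀγ₂`, giving direct effect DE = c′,
   indirect effect IE = a·b, total effect TE = DE + IE, and proportion
   mediated IE/TE (reported only when DE and IE share a sign).
   Inference by bootstrap percentiles over resampled individuals
   (default 1,000 replicates).
4. **Effect modification** —
   `cordTL = β0 + β1·SNP + β2·CpG + β12·SNP×CpG + Cᵀγ + ε` with
   additive coding, over all cis pairs *except* significant mQTLs
   (excluded because genotype–methylation independence cannot be
   assumed); Bonferroni over the interaction universe, and separately
   over SNPs for the β1 main effects.

QC implements the study-design filter chain: SNP call rate < 95% and
sample call rate < 90% dropped, empirical genotype imputation,
MAF < 0.01 and HWE chi-square p < 0.05 dropped; methylation detection
p > 1e-16 treated as failed call, probe call rate < 95% and sample call
rate < 99% dropped, KNN imputation (K = 10), empirical-Bayes
batch/position adjustment, 3-IQR outlier trimming, sex-chromosome /
SNP-overlap / cross-reactive probe blacklists, and reference-based
deconvolution of the seven cord-blood cell types (nRBC, granulocytes,
monocytes, NK, B, CD4T, CD8T) by non-negative least squares.

## Worked example

Simulate a small cohort with one built-in mediation path (SNP→CpG
effect a = 0.8 M-units per allele, CpG→telomere effect b = 0.25 T/S per
M-unit, direct effect c′ = 0.05), then run the mQTL scan, candidate
selection and bootstrap mediation:

```r
library(teloscan)
spec <- default_snp_spec()[1:4, ]
cpg  <- default_cpg_spec(spec, n_per_snp = 4)
cfg <- simulation_config(
  n_samples = 300, snp_spec = spec, cpg_spec = cpg,
  mediation_paths = data.frame(snp_id = "rs6669117", cpg_id = cpg$id[14],
                               a = 0.8, b = 0.25, c_prime = 0.05),
  seed = 11)
sim <- simulate_study(cfg)

mqtl <- scan_mqtl(sim$dataset)
mqtl
#> mqtl_scan: 58 cis pairs tested, Bonferroni threshold 0.000862
#>   significant pairs (rule = both ): 1

cand <- select_candidates(mqtl, sim$dataset)
med <- bootstrap_mediation(sim$dataset, cand$snp_id[1], cand$cpg_id[1],
                           n_boot = 1000, seed = 1)
med
#> mediation_result: rs6669117 -> cg00000014 -> T/S, n = 288 , 1000 bootstrap replicates
#>      estimate       lower     upper boot_p
#> a  0.98724070  0.90337402 1.0707861  0.000
#> b  0.23933471  0.17389957 0.3111972  0.000
#> de 0.05590812 -0.02874741 0.1349543  0.188
#> ie 0.23628097  0.16646184 0.3120963  0.000
#> te 0.29218910  0.23915471 0.3440932  0.000
#>   proportion mediated: 0.81 (p = 0, 906 same-sign replicates)
```

The scan tests the 58 cis pairs, Bonferroni-flags exactly the injected
pair under both codings, and the bootstrap recovers the generative
effects: `a` ≈ 0.99 (the per-allele effect 0.8 rescaled onto the
dominant carrier indicator), `b` ≈ 0.24 against the true 0.25, a
nonsignificant direct effect, and a clearly nonzero indirect effect
with a 95% percentile interval covering the truth. Note the telomere
units: effects are on the T/S-ratio scale (cohort mean ≈ 1.03,
SD ≈ 0.20).

The full chain (association → mQTL → mediation → interaction) is one
call: `run_analysis(dataset)`.

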