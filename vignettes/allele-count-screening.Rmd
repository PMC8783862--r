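---
title: "Screening testosterone-increasing alleles and scoring carriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening testosterone-increasing alleles and scoring carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyscreen)
```

## The problem

Circulating testosterone is a heritable trait with anabolic effects on
skeletal muscle, and GWAS of large population biobanks have identified
hundreds of variants whose alleles associate with higher testosterone.
`polyscreen` implements a cascade that asks which of those
testosterone-increasing alleles also associate with muscle-related
phenotypes — the cross-sectional area (CSA) of fast-twitch (type II)
muscle fibers, handgrip strength, and fat-free mass — and then summarizes
the survivors as a per-individual *allele-count polygenic score* used to
compare strength/power athletes with controls.

## The screening cascade

Starting from a sex-stratified panel of testosterone-associated variants,
four filters are applied in order:

1. **Sex concordance.** A variant whose male and female effect estimates
   disagree in sign has no single "testosterone-increasing allele" and is
   removed (`sex_concordance_filter()`). A beta of exactly zero in either
   stratum is treated as discordant, the conservative choice.
2. **Association with the discovery trait.** For each variant, the trait
   is regressed on effect-allele dosage with covariates in the design
   matrix (`per_variant_association()`), and variants with a Wald
   *P* < α and a positive dosage coefficient are retained
   (`nominal_direction_filter()`). The inequality is strict, so
   *P* = α fails.
3. **Autosomes only** (`autosome_filter()`); chromosome labels are
   normalized first, so `chrX` and `X` compare equal.
4. **Multi-trait replication.** Survivors must be nominally significant
   with the same (positive) direction in external summary statistics for
   *every* listed additional trait (`lookup_filter()`). A variant absent
   from any trait's records is excluded and logged, never silently
   imputed.

Alongside the cascade, `bonferroni_threshold(alpha, n_variants,
n_traits)` reports the family-wise threshold α/(m·t). Selection itself is
at the nominal level: the cascade's repeated, direction-constrained
replication across traits is the multiplicity control the procedure
relies on, and the Bonferroni figure is reported so readers can see which
associations would survive it.

### Linear versus logistic association

The discovery trait (fiber CSA in μm²) is continuous and published
per-allele effects are in trait units (hundreds to thousands of μm² per
allele), which is a linear-regression scale. The default model is
therefore ordinary least squares on the continuous trait. A
logistic-on-median-split variant (`model = "logistic"`) is available for
workflows that dichotomize the trait; it reports log-odds per allele and
is not the default because it discards information and changes the beta
units. Covariates are adjusted by inclusion in the design matrix (the
standard GWAS convention), not by pre-residualizing the trait.

## The allele-count score

`allele_count_score()` counts effect alleles over the selected set: a
heterozygote contributes 1, an effect homozygote 2, so the score lies in
0…2m (0–10 for the five-variant panel). The score is deliberately
*unweighted* — no multiplication by beta — because the downstream carrier
analysis classifies individuals by the number of favorable alleles, not
by a predicted trait value. `dichotomize()` splits at a configurable
carrier threshold, default ≥ 2 versus 0–1.

Missing genotypes: the default policy excludes the individual from
scoring (their score is `NA` and they drop out of carrier tables); an
alternative `maf_impute` policy substitutes the Hardy–Weinberg
expectation 2·maf, producing non-integer scores, and is off by default
because silent imputation can manufacture carriers.

Under Hardy–Weinberg equilibrium and linkage equilibrium the score is a
sum of independent Binomial(2, p<sub>i</sub>) variables.
`score_distribution_hwe()` computes its exact distribution by
sequentially convolving the per-locus genotype triples
((1−p)², 2p(1−p), p²); the result matches brute-force enumeration of all
3^m genotype combinations to 10⁻¹², and probabilities sum to 1 within
10⁻¹². Allele frequencies of exactly 0 (one control-panel variant) or 1
are legal and contribute point masses.

```{r}
d <- score_distribution_hwe(study_panel("controls")$maf)
round(d, 4)
carrier_probability_hwe(study_panel("controls")$maf)   # P(score >= 2)
carrier_probability_hwe(study_panel("athletes")$maf)
```

## Validation statistics

- `carrier_case_control()` builds the group × carrier 2×2 table and
  reports carrier proportions, the odds ratio (a·d)/(b·c) with Woolf's
  log-based 95% CI, and the Pearson χ² test.
- **Yates continuity correction is on by default** for the 2×2 test. On
  the carrier table reconstructed from the published group sizes and
  percentages, the corrected test gives *P* ≈ 0.012 and the uncorrected
  one *P* ≈ 0.009; the corrected value is the one consistent with the
  published report. The correction is applied as in `chisq.test()`,
  capped at the observed-expected deviation, so the corrected statistic
  never exceeds the uncorrected one. Because the correction is
  conservative by construction, size-calibration checks in the test
  suite use the uncorrected statistic.
- `odds_ratio()` applies the Haldane–Anscombe 0.5 correction (with a
  message) when a single cell is zero; a zero margin is an error.
- `reconstruct_counts()` turns a printed percentage back into integer
  counts, rounding half away from zero.
- `partial_correlation()` implements "Pearson correlation adjusted for
  covariates" as residualization: x and y are each regressed on the
  covariates and the residuals are correlated, with the t test on
  n − 2 − k degrees of freedom. With no covariates it reduces exactly
  (to 10⁻¹²) to the plain Pearson correlation, which is also the default
  reading when reproducing published unadjusted-looking correlations.
- `wilks_points()` normalizes a weightlifting total across body weights:
  total (kg) × 500/(a + bx + … + fx⁵) with the published 1994
  coefficients per sex, stored in a `wilks_params()` object so
  alternative coefficient tables can be swapped in. Validity ranges are
  40–201 kg (male) and 40–150 kg (female); beyond these the published
  polynomials stop decreasing in bodyweight and the function refuses to
  extrapolate.

## The synthetic-cohort generator

No individual-level genotype or phenotype data accompany the published
analysis, so the package ships a generator that reproduces the
*statistical structure* the method assumes:

- **Genotypes** are drawn per variant as Binomial(2, maf) —
  Hardy–Weinberg proportions within variants, linkage equilibrium
  between them. Each variant consumes its own seed sub-stream derived
  from the master seed, so extending a panel never perturbs previously
  generated columns.
- **Traits** are additive-linear in dosage with Gaussian noise:
  intercept + Σβ<sub>j</sub>·dosage<sub>j</sub> + covariate effects +
  N(0, σ). The default CSA model uses sex-specific intercepts (females
  ≈ 4305 μm², males ≈ 5925 μm², matching the reported cohort means) and
  the published per-allele CSA effects; additivity is consistent with
  the score's treatment of heterozygotes as intermediate.
- **Discovery panels** (`simulate_discovery_panel()`) yield
  sex-stratified summary statistics with an exact, configurable number
  of direction-discordant variants — the input the concordance filter
  consumes.
- **Case-control samples** (`simulate_case_control()`) draw each group
  at its own allele frequencies; with the published athlete/control
  frequencies the exact implied carrier probabilities are 0.673 vs
  0.612, so simulated enrichment is modest but reliably positive at
  large n.

Free parameters the published study does not determine were fixed once:
residual CSA SD 1000 μm² (each variant then explains well under 5% of
variance at its study allele frequency), testosterone residual SD
4.6 nmol/l (the reported within-group SD), age ~ N(30, 8) truncated at
18, three standard-normal principal components, and categorical
activity/training covariates with plausible weights. They are
configurable through `cohort_spec()` / `trait_model()`.

What the generator does **not** emulate: linkage disequilibrium,
imputation uncertainty, genotyping error, population stratification,
dominance or gene–gene interaction, and sex-specific effect sizes
(outside the discovery-panel generator, which needs them). Passing tests
on synthetic cohorts therefore validate the *machinery* — filter logic,
estimator calibration, exact distributions — not the biological claims,
which depend on the real cohorts.

## Numerical and design choices

- Strict `p < alpha` everywhere a nominal filter is applied.
- Zero beta fails any direction requirement (it cannot be "increasing").
- Constant-dosage variants are flagged untestable rather than raising,
  since a monomorphic variant is an expected outcome of sampling at low
  frequency; a singular covariate block, by contrast, is a user error
  and raises with the offending column named.
- Listwise deletion per analysis for missing data; no silent zero-fill.
- Variants are matched by rsid; coordinates are 1-based as in VCF, and
  the pipeline is genome-build-agnostic because nothing depends on
  position.
- Multi-allelic VCF records: dosage counts only the named effect allele.
- All randomness flows from one integer master seed through fixed
  sub-stream derivations (kept below 2³¹), making every table and report
  byte-reproducible.

## Problem sizes used in the test suite

Hardy–Weinberg convergence is checked at n = 10⁵ (3·SE tolerance);
effect recovery over 200 replicate cohorts of n = 5000; type-I error of
the screen and the carrier test over 1000 null replicates of n = 200 per
group; carrier-enrichment sign over 100 case-control replicates of
2000 per arm; exact-distribution agreement for panels up to m = 6
(3⁶ = 729 enumerated genotype combinations). The demo pipeline uses an
855-variant discovery panel, an association cohort of 600, and 2000
individuals per case-control arm — large enough that the five
planted-effect variants are selected with high power and carrier
enrichment is visible above sampling noise, small enough to run in
seconds.

## Limitations

The five-variant panel, its allele frequencies, and the per-variant
association table are inputs transcribed from a published report; the
package can reproduce every derived statistic (odds ratio, χ², score
distribution, thresholds) but not re-derive those inputs, which would
require the original genotype data. Correlations of the score with
testosterone and strength performance in the published athlete cohorts
(r = 0.28 and 0.34) likewise depend on real genotype–phenotype coupling
at realistic effect sizes and are not reproducible from synthetic data;
the package instead verifies the estimator is unbiased at those effect
sizes.
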