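---
title: "Methods: QTL mapping and trait-network analysis for diet-response F2 crosses"
author: "dietcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL mapping and trait-network analysis for diet-response F2 crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietcross)
```

## The analysis problem

`dietcross` implements the statistical pipeline of an F2-intercross study
of diet response: two inbred mouse lines (a B6-like and an FVB-like
strain) are crossed, the F1 hybrids are intercrossed, and the F2
offspring — both sexes, randomized to an American-style or a ketogenic
diet — are phenotyped for body-composition change (fat and lean mass
gained over the feeding trial) and serum lipids (HDL cholesterol), and
genotyped on a genome-wide marker panel. The questions the pipeline
answers, in order:

1. Which genomic regions (QTLs) are associated with each trait, at
   thresholds that control the genome-wide false-positive rate?
2. How uncertain is each QTL's location (support intervals), how large
   are its allelic effects, and does it interact with sex, diet, or
   another locus?
3. When two traits map to overlapping regions: is the locus shared
   (pleiotropic), and if so, does it act on one trait through the other
   (a causal chain) or on both independently?
4. What does the whole trait network look like as a path model, with
   standardized effect sizes and variance shares?

Because the underlying animal data are not publicly deposited, the
package ships a synthetic-cross generator whose default configuration
reproduces the *design* of the study — its scale, marker density, trait
architecture and effect pattern — so that every downstream method is
exercised and tested end to end on data with known truth.

## The scan model and its "LOD"

The combined single-marker model is the least-squares fit

    y ~ sex * diet + marker

where `marker` is a categorical genotype factor with the B6 homozygote
as reference, contributing 2 df when all three genotype classes are
observed. The marker term is tested with a partial F-test against the
covariate-only model on that marker's complete cases, and the score
reported per marker is

    LOD = -log10( p-value of the marker F-test ).

This follows the convention of the source analyses: it is **not** the
classical likelihood-ratio LOD, although for a 2-df test the two are
numerically close at large n (for the chi-square limit of the 2-df test
they coincide exactly, since the chi-square survival function is
`exp(-x/2)`); the classical LOD is provided as the `lod_classical`
column. Signed profiles (`signed_lod`) carry the sign of the FVB/FVB
effect: positive means the FVB allele increases the trait.

Numerical notes: per-marker fits use complete cases for that marker only
(rows missing that genotype are dropped for that marker alone); markers
with a single observed genotype class are skipped with a flag; p-values
that underflow are reported at a LOD ceiling of 300; ties at a profile
peak resolve to the leftmost marker.

## Permutation thresholds

Genome-wide significance is calibrated by permutation: genotype rows are
shuffled as a block against intact (phenotype, covariate) pairs, which
preserves the sex/diet-trait relationship while breaking all linkage;
the genome-wide maximum LOD is recorded per permutation; the threshold
at level alpha is the empirical (1 - alpha) quantile of those maxima. The
permutation scheme is a design choice (the source methods do not state
whether covariate-trait pairing was preserved); preserving it is the
conservative option because sex and diet carry real signal. At the
study's scale — 1667 markers on 20 linkage groups totalling 1400 cM, n =
469 — the 5% and 1% thresholds computed by `scripts/acceptance.R` land
at approximately 3.9 and 4.7.

The scan kernel (per-marker partial F over all markers, and the
permutation loop) is compiled C++ (RcppArmadillo), as is usual for QTL
packages; a 1000-permutation study-scale run takes about a minute on one
CPU. The pure-R `marker_regression()` is the per-marker reference
implementation, and the test suite holds the two to 1e-9 agreement and
both to a brute-force normal-equations oracle at 1e-10.

## Support intervals, variance explained, interactions

A QTL's support interval is the 1.5-LOD drop region: the contiguous run
of markers within 1.5 LOD of the chromosome peak, extended by one
flanking marker below the cut on each side (the conservative convention;
the drop rule alone does not define the boundary markers). Coverage of
the true locus is about 95% in calibration simulations, and the test
suite requires at least 90% over 200 replicates.

Variance explained by a marker is
`100 * (SS_model(covariates + marker) - SS_model(covariates)) / SS_total`,
i.e., the marker's incremental model sum of squares as a share of the
trait's total sum of squares; within a sex-by-diet stratum it is
computed with the marker-only model. Sex/diet modulation of a QTL is
tested by sequential-SS ANOVA of `y ~ sex * diet * marker`, reporting
the genotype-involving interaction terms. Two-locus epistasis is tested
on a 2x2 genotype grouping (default: B6-homozygous vs rest at the first
locus, FVB-carrier vs not at the second), with the interaction
contrast's Wald CI and F-test p.

## Conditioned scans and the shared-QTL rule

To ask whether a locus acts on trait A through trait B, the scan of A is
repeated with B as an extra covariate, on the rows complete for both
traits (the unconditioned scan is recomputed on the same rows so the two
profiles are comparable). A change of at least 2.0 LOD at the peak —
in either direction — is called a shared (pleiotropic) locus; the 2.0
cut-off corresponds to a 5% type-I error rate for this comparison.

## Causal-network inference at a shared locus

For two traits T1, T2 sharing a locus: each trait is residualized on the
other (plus sex, diet and their interaction), giving R1 and R2; each
residual is tested for locus association (2-df genotype-factor F-test by
default; an additive-coded t-test is available); the two p-values are
Holm-Bonferroni corrected (step-down, the i-th smallest compared to
alpha / (m - i + 1)). The decision table: only R1 associated means the
locus reaches T2 only through T1 (T1 upstream); only R2 associated means
T2 upstream; both associated means the traits are independently linked
to the locus; neither, undetermined.

The directed models are additionally scored with Gaussian information
criteria, `AIC = n log(RSS/n) + 2k` and `BIC = n log(RSS/n) + k log(n)`
with k counting coefficients plus one variance term. Two forms are
provided:

* `method = "regression"` (default reporting convention): each direction
  is one regression of the downstream trait on the upstream trait plus
  sex\*diet and the locus factor. The two models have **different
  response variables**, so their scores are dominated by the response
  scales; on trait pairs measured in very different units (grams vs
  ng/mL) the comparison effectively selects the small-scale response.
  Worse, with comparable scales the anti-causal regression has the
  systematically higher R-squared under a linear-Gaussian chain (the
  upstream trait has two explanatory sources — the locus and the
  downstream trait — while the downstream trait is explained by the
  upstream trait alone), so this form should not be read as a
  direction test. It is retained because it is the form the source
  tables report.
* `method = "joint"`: each direction is the full two-equation
  factorization (upstream ~ sex\*diet + locus; downstream ~ upstream +
  sex\*diet), scored by summed AIC/BIC. Both directions then model the
  same bivariate response, the comparison is scale-invariant, and the
  true direction is preferred consistently; the test suite requires at
  least 80% direction recovery under a strong mediation chain.

## Path model

The trait network is fitted as an observed-variable recursive path
model: one least-squares equation per outcome on z-scored outcome and
predictors, so coefficients are standardized paths with t-statistics;
markers enter additively (FVB-allele count) with one path per locus;
`sex:diet` contributes the interaction product only. Residual
correlations are reported for declared outcome pairs. There are no
latent variables and no covariance-structure optimizer — for a recursive
observed-variable diagram, per-equation least squares gives the same
paths, and the source model contains only observed variables. Each
predictor's variance share is the last-entry share,
`100 * (SS(all) - SS(all minus this)) / SS_total`, which sums to the
total R-squared only for orthogonal predictors. Pruning removes the
least-significant path (largest p above alpha, ties by declaration
order) and refits until all retained paths are significant; the result
is a fixed point of the procedure.

## Descriptive statistics and heritability

Group contrasts use Welch's t (unequal variances, Satterthwaite df),
the pooled Student t, or the Wilcoxon rank-sum test (exact null
enumeration when the smaller group has at most 8 observations and no
ties; tie-corrected normal approximation otherwise, with Hodges-Lehmann
estimate and interval). The t-tests accept published (mean, SD, n)
summaries directly, so printed group summaries can be re-analysed;
fold changes are ratios of group means, reported to 2 decimals by
convention.

Broad-sense heritability uses the F2-vs-F1 variance partition: the F1
population is genetically uniform, so its phenotypic variance estimates
the environmental variance, and `H2 = (V_F2 - V_F1) / V_F2`, truncated
to [0, 1]. The literal reading "ratio of F2 variance to F1 variance" is
available as `method = "ratio"` but can exceed 1, which is inconsistent
with heritabilities reported as percentages; the excess form is
therefore the default.

## The synthetic cross

`simulate_f2()` generates each F2 individual as the union of two
independent F1 gametes. Crossovers follow a no-interference (Haldane)
process on the centimorgan scale, implemented through its exact
marker-level law: recombination across each marker interval is an
independent Bernoulli event with probability `(1 - exp(-2d/100)) / 2`
for an interval of d cM. Since only marker genotypes are observed, this
is distributionally identical to simulating crossover locations and
reading off the mosaic, and the tests verify the 1:2:1 segregation,
Haldane recombination fractions and cross-chromosome independence.

`simulate_phenotypes()` generates each trait as intercept + sex, diet
and sex:diet effects + per-QTL additive and dominance effects (scaled by
per-locus sex/diet multipliers) + epistatic cell effects + a pleiotropic
contribution of an upstream trait + an optional unmapped polygenic
background + Gaussian noise. Missing genotypes at a QTL contribute the
population-mean effect. The X chromosome is simulated and scanned like
an autosome (the linkage group labelled "X" can simply be dropped from
the map to exclude it); sex/diet assignment is balanced-random rather
than the exact study cell counts.

The default configuration (`default_cross_config()`) mirrors the study
design: n = 469 F2s, 1667 markers on 20 linkage groups scaled to 1400
cM, roughly 1.9 Mb/cM; fat mass gain (g) with a chromosome-1 locus
(additive 1.16 g, dominance 0.28 g — also fed by serum HDL through a
lambda = 0.01 g per ng/mL pleiotropic chain), a chromosome-5 locus
(additive -0.65 g doubled in males and on the ketogenic diet) and a
chromosome-7 locus (additive -0.85 g, dominance 1.08 g); lean mass gain
sharing the chromosome-5 locus; serum HDL (ng/mL) with a strong additive
chromosome-1 locus (additive 24 ng/mL); a +5 g epistatic effect in
ketogenic males homozygous B6 at the chromosome-5 locus and carrying an
FVB allele at the chromosome-1 locus; 2% missing genotype calls; and 20
animals per parental/F1 cohort. Locus effect sizes are the reported
allele effects of the study's QTL table re-expressed in
additive/dominance coding; the polygenic-background SDs (3.2 g fat, 2.0
g lean, 20 ng/mL HDL) and environmental SDs (2.0 g, 1.4 g, 40 ng/mL)
were chosen once so that the F2/F1 variance partition reproduces
broad-sense heritabilities near the reported ~0.7-0.8 while the mapped
QTLs explain only a few percent each, as in the study.

What the generator does **not** emulate: genotyping-array intensities
and call-quality structure (missingness is a uniform random mask),
linkage-map estimation error, crossover interference, non-Gaussian trait
noise, and litter/cage effects. Tests passing on this generator
therefore validate the statistical machinery under the stated model,
not robustness to those real-data features.

## Problem sizes used by the tests and acceptance script

Simulation-backed checks run at the study scale where the claim is
scale-dependent (permutation thresholds: 1667 markers, n = 469, 1000
permutations in the test suite, 2000 in the acceptance script; null-scan
calibration: 200 replicate scans against those thresholds) and at
reduced scale where it is not (interval coverage: one 100 cM chromosome,
51 markers, 200 replicates; causal classification: single locus, n =
469, 200 replicates per scenario; path recovery: n = 2000; heritability
recovery: n = 2000 F2s, 600 per cohort). Seeds are fixed throughout;
identical seed and configuration reproduce every output byte for byte.

## Known limitations

* Single-marker scans only: no interval mapping between markers, no
  multi-QTL model search, no HMM genotype probabilities.
* The marker factor's 2-df test assumes at least two genotype classes;
  distorted segregation reduces power but is not modelled.
* The per-regression AIC/BIC direction comparison is reported for
  fidelity but is not a valid direction test (see above); use the joint
  form for direction inference.
* Holm correction is applied within a trait pair (m = 2); no
  multiplicity correction is applied across traits or across the
  descriptive comparisons, matching the source analyses.
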