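---
title: "stromasig: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stromasig: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromasig)
```

# What the package computes

`stromasig` implements an integrated expression-analysis workflow for
small paired fibroblast-activation experiments: a cohort of patients each
contributing a baseline fibroblast sample (HPF), a patient-derived
cancer-associated fibroblast sample (CAF), and two in-vitro activations
(IL6, TGFB). The stages are:

1. **Preprocessing** — detection-based probe filtering, probe-to-gene
   collapsing, miRNA probe summing and detection calling, log2 transform
   with optional quantile normalization.
2. **Paired differential expression** — within-patient differences with
   empirical-Bayes variance moderation.
3. **Pre-ranked set enrichment** — running-sum enrichment scores on the
   moderated-t-ranked list, permutation significance, NES, FDR, leading
   edges, enrichment networks and cross-contrast summaries.
4. **Centroid signatures** — threshold-selected gene lists with reference
   values (average expression in activated samples), scored against
   external datasets by per-sample correlation.
5. **miRNA integration** — differential miRNA sets from one contrast
   tested on another contrast's ranked miRNA list with per-member
   coherent/divergent calls, and genes ranked by correlation with a
   miRNA's profile fed back into the enrichment engine.
6. **qPCR quantification** — the 2^-ddCt method with reference-assay or
   spike-in normalization, undetermined-Ct capping and replicate t-tests.

A synthetic-cohort generator with a full ground-truth ledger makes every
stage testable without any external download.

# The paired moderated t

For a contrast (condition a vs baseline b) each patient contributes one
sample per condition. Per feature g, with within-patient differences
d_{g1}, ..., d_{gn}:

- logFC: beta_g = mean(d_g), residual variance s2_g = var(d_g) on
  d_g = n - 1 degrees of freedom.

This within-patient difference estimator is algebraically identical to a
blocked two-condition linear model and keeps a closed-form oracle (the
ordinary paired t) that the tests exploit. The empirical-Bayes prior
(d0, s0^2) is estimated by matching the first two moments of log s2 to a
scaled F distribution — the marginal of sample variances when true
variances follow a scaled inverse-chi-squared prior — using a Newton
inversion of the trigamma function (tolerance 1e-8, bisection fallback).
When the dispersion of log s2 does not exceed the theoretical minimum
under equal variances, d0 is infinite and every feature uses the prior
variance. The moderated statistic is

    s2_post = (d0 s0^2 + d s2) / (d0 + d),
    t = beta / sqrt(s2_post / n),    df = d0 + d,

with two-sided p-values and Benjamini-Hochberg q-values. Degenerate
features (s2 = 0 with d0 = 0) get t = +/-Inf and p = 0 with a warning:
deterministic, and visibly degenerate rather than silently dropped.

# The running-sum enrichment score

Walking down the ranked list, position j adds |r_j|^p / N_R when the
feature is a set member (N_R is the sum of |r|^p over members) and
subtracts 1/(N - N_H) otherwise; the enrichment score is the signed
extremum of this running sum (not max-minus-min). Exponent p = 1 is the
default; p = 0 gives the classic unweighted statistic used by the
closed-form tests. Two numerical choices matter:

- The accumulation is an explicit sequential double-precision sum, so a
  straightforward re-implementation reproduces it bit for bit, including
  the resolution of exact ties between the positive and negative
  extremum (first one reached wins).
- Because the walk declines linearly between hits, its extrema occur
  only at hit positions; the permutation null therefore uses an O(N_H)
  evaluation from hit positions alone, which is what makes thousands of
  permutations per set affordable in pure R. The tests verify the two
  paths agree.

**Significance.** The default null permutes *set membership*: each of B
permutations draws a random same-size set from the ranked universe. With
three pairs the phenotype-permutation null (sign flips of within-patient
differences) has only 2^3 distinct states and is hopelessly sparse, so
set permutation is the default; the phenotype scheme is implemented for
larger cohorts. The p-value is one-sided on the observed sign with the
add-one rule, ties counted as exceedances (conservative). NES divides ES
by the mean same-sign permuted |ES|; FDR q compares observed NES against
the pooled permuted-NES null, sides handled separately. Permutations are
drawn from a substream named after each set, so results are independent
of collection order and fully determined by the seed.

# Centroid signatures

A centroid is the set of genes passing a p-value threshold in one
contrast, each carrying its average log2 expression *in the activated
samples only* (not the activated-minus-baseline difference). External
samples are scored by Pearson correlation (Spearman available) between
the centroid values and the sample's values over case-insensitively
matched symbols, duplicate external rows averaged. Fewer than 10 matched
genes is a refusal, not a silent score. The correlation type is a design
choice: Pearson on log2 values matches the positive/negative-correlation
reading of signature heatmaps; affine-invariance makes it robust to
platform scaling.

The default thresholds (raw p < 0.01 for CAF and IL6; adjusted
p < 1e-4 for TGFB, chosen to equalize signature sizes when the TGFB
response is much stronger) are the field-scale values; on small
simulated cohorts the adjusted rule must be rescaled (e.g. q < 0.25) or
it selects nothing — the configuration exposes both knobs per contrast.

# miRNA integration

A miRNA set is the set of miRNAs with raw p < 0.05 and a common t sign
in one contrast; it is tested on the reference contrast's t-ranked miRNA
list by the same enrichment engine (minimum in-universe size 3 —
conventional gene-set minima of 15 would empty these small sets). Each
member is labelled *coherent* when its reference t sign agrees with the
set's direction, *divergent* otherwise; a t of exactly 0 is divergent
with a tie warning, and members absent from the reference are reported
as missing, never dropped. Correlation-guided enrichment ranks genes by
their correlation with a chosen miRNA across all shared samples by
default (a condition subset can be supplied) and delegates to the
enrichment engine unchanged.

# qPCR quantification

Technical replicate wells are averaged per (sample, assay) before
dCt = Ct_target - Ct_normalizer; ddCt subtracts the calibrator sample's
(or group mean's) dCt; RQ = 2^-ddCt assumes perfect doubling
(efficiency correction is out of scope), and -ddCt = log2(RQ) is
reported alongside for plotting. Undetermined wells are capped at 40
cycles (the run length) with the flag preserved. Replicate comparisons
default to the log scale (-ddCt), where Ct noise is additive, via a
two-sided two-sample Student t-test; aggregation order — technical
replicates within a sample first, then ddCt per biological replicate —
is fixed and documented because published reports rarely state it.

# The synthetic cohort generator

Every value is additive on the log2 scale:

    value = baseline + patient intercept + condition effect
          + latent-factor loading + N(0, noise_sd)

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 3 | patients, each with one sample per condition |
| `conditions` | HPF, CAF, IL6, TGFB | baseline + three activation states |
| `n_genes` / `n_mirnas` | 2000 / 300 | feature universe sizes |
| `patient_sd` | 0.5 | SD of gene-specific patient intercepts (log2) |
| `noise_sd` | 0.5 | residual SD (log2) |
| `effect_size` | 1.0 | planted condition effect (log2) |
| `frac_shared` / `frac_tgfb` | 0.10 / 0.10 | planted gene blocks |
| `n_latent` | 3 | patient-level factors coupling the two layers |
| `latent_sd` | 2.0 | scale of the planted factor contrasts |

One block of genes carries a single coefficient applied to both CAF and
IL6 (the shared activation that makes IL6-stimulated fibroblasts
resemble patient-derived CAFs and drives per-patient clustering); a
disjoint block carries a TGFB-only coefficient; signs alternate within
each block (+effect for the first half, -effect for the rest). Patient
intercepts are gene-specific and shared across a patient's four samples.
`patient_sd = 0.5` is a free choice, not an estimate — inter-patient
variability of fibroblast expression is not quantified in the kind of
study this emulates; 0.5 log2 units makes patient identity comparable in
magnitude to the planted biology, which is what the per-patient
clustering behaviour requires.

**Latent coupling.** The miRNA and gene layers are coupled through
patient-level latent factors: disjoint blocks of genes and miRNAs load
(with signed unit weights) on a per-patient score. Two deliberate
choices here:

- *Patient-level, not sample-level, scores.* Per-sample factor scores
  would enter the within-patient differences and inflate the variance of
  factor-loaded genes relative to the moderation prior, destroying
  type-I calibration of the paired contrasts. Patient-level programs
  couple the layers across samples while leaving every paired contrast
  unconfounded — the factors cancel exactly in within-patient
  differences.
- *Fixed contrasts, not Gaussian draws.* Scores are equally spaced
  patient contrasts of unit variance (randomly permuted and signed per
  factor) scaled by `latent_sd`. With only three patients, Gaussian
  scores have a heavy-tailed empirical variance — a sizeable fraction of
  seeds would produce a collapsed factor and no detectable coupling.
  Planting a fixed-magnitude contrast mirrors how the condition effects
  are planted and keeps the coupling strength constant across seeds.

**Outlier corruption** adds independent N(0, 5 x noise_sd) noise to one
designated sample column in both layers, emulating a gross quality
failure; the advisory screen flags samples whose median inter-sample
correlation falls 3 robust SDs below the cohort median, with the robust
SD floored at 0.04 correlation units so that ordinary patient-to-patient
divergence (a real feature of cohesive cohorts, and of this generator's
patient programs) is not flagged. A corrupted sample typically loses
about 0.3 in median correlation; a divergent patient well under 0.1, so
the floor separates the two regimes cleanly. Flags never remove
anything: removal requires an explicit config entry, keeping
judgment-based exclusions auditable.

**What the generator does not emulate:** bead-level array artifacts,
intensity-dependent dye effects, batch structure beyond patient
intercepts, realistic miRNA biogenesis, or correlated gene-gene
networks beyond the planted blocks. Passing recovery tests on this
cohort therefore demonstrates that the statistical machinery is correct
under its stated model, not that the pipeline is robust to every
pathology of real arrays.

# Normalization stand-in

The platform-native robust-spline normalization belongs to the original
array software; `normalize_log2()` offers quantile normalization (via
limma) or a plain log2 transform. Downstream statistics depend on
between-sample comparability, not on the specific smoother, so a
distribution-matching method is an adequate, well-understood stand-in.
Non-positive intensities are floored at `epsilon = 1.0` before the log.

# Tie-breaks and boundaries (all documented in the function help)

- Probe collapsing: highest detection rate, then larger IQR, then
  lexicographically smaller probe id (the source rule names the first
  two criteria without precedence; precedence is fixed here).
- Detection boundaries: detection p equal to the threshold counts as
  detected; the miRNA rule `signal > 3 x SE` is strict; "detected in at
  least 2 samples" is inclusive.
- Ranking ties: feature id ascending — stable and reproducible.
- miRNA-set membership: raw p strictly below the cutoff.
- Clustering: `stats::hclust` average linkage; deterministic given input
  order.

# Problem sizes used by the test-suite experiments

The recovery and calibration experiments run at sizes chosen to make
sampling error small relative to the tested margins while keeping the
suite quick on one CPU: null calibration at 5000 genes with 1000 random
sets and B = 999; planted-set recovery over 20 seeds at 2000 genes with
50 sets and B = 499; coupling, centroid and outlier checks over 10–20
seeds at 400–2000 genes; the reproducibility smoke run at 2000 genes,
300 miRNAs, 50 sets and B = 500. These are the package's own choices of
experiment size, stated here so the reported rates can be reproduced
exactly.

# Known limitations

- With n = 3 pairs the phenotype-permutation null is nearly degenerate;
  set permutation answers a different (gene-sampling) null question —
  the standard caveat of pre-ranked enrichment applies.
- The FDR for very small collections (e.g. a single miRNA set) pools a
  correspondingly small NES null and is coarse.
- Cross-platform matching is exact (case-insensitive) symbol equality;
  no alias resolution.
- Amplification efficiency in qPCR is fixed at 2.
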