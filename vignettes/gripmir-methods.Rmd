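---
title: "Methods: two-part mixed-model screening of censored qPCR miRNA panels against grip strength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-part mixed-model screening of censored qPCR miRNA panels against grip strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripmir)
```

## The problem

Whole-blood microRNA panels profiled by quantitative PCR report expression
as a quantification cycle (Cq): the PCR cycle at which fluorescence crosses
threshold, so *lower* Cq means *higher* expression. Below a platform's
sensitivity the transcript is simply not detected; on nano-volume
instruments a Cq of 27 cycles is a conventional detection limit. The result
is a matrix that is left-censored on the expression scale (right-censored
on the Cq scale), with per-miRNA detection rates anywhere from under 5% to
essentially 100%, and — in family cohorts — phenotypes that are correlated
within families.

`gripmir` implements a screening strategy for relating such a panel to a
continuous phenotype (hand grip strength in kilograms, a standard marker
of healthy aging), together with the machinery needed to trust a screen of
this kind: permutation calibration of the test's size,
false-discovery-rate control, downstream miRNA–mRNA coexpression, and
gene-set over-representation. Because individual-level cohorts of this
kind are access-restricted, the package also ships a synthetic cohort
generator so every stage can be exercised, tested, and calibrated end to
end without any external data.

## The two-part (hurdle) model and the adaptive p-value

For each miRNA, define the non-detection indicator

\[ X = 1 \text{ if } \mathrm{Cq} > 27, \qquad 0 \text{ otherwise}, \]

so \(X = 1\) codes undetectable (low) concentration. The rule is strict: a
Cq exactly at the limit counts as detected. Two linear mixed models are
fitted, each with a family random intercept:

* **Model 1 (binary part)** — in everyone assayed:
  \( \text{grip} \sim X + \text{covariates} + (1 \mid \text{family}) \).
* **Model 2 (continuous part)** — in the detected subset (\(X = 0\)):
  \( \text{grip} \sim \mathrm{Cq} + \text{covariates} + (1 \mid \text{family}) \).

Each model contributes a 1-df Wald chi-squared statistic
\((\hat\beta/\mathrm{SE})^2\) for its focal predictor. The miRNA is then
routed by its detection fraction \(d\) (detected / assayed):

| detection fraction | branch | adaptive p |
|---|---|---|
| under the eligibility floor | ineligible | none |
| \(d < 0.10\) | binary only | model-1 p |
| \(0.10 \le d < 0.90\) | combined | \(\Pr(\chi^2_2 \ge \chi^2_{(1)} + \chi^2_{(2)})\) |
| \(d \ge 0.90\) | continuous only | model-2 p |

On the combined branch the two statistics are recovered from the model
p-values by inverting the \(\chi^2_1\) upper tail, summed, and referred to
a \(\chi^2_2\) distribution. The intuition: when detection is moderate,
both the *whether detected* and the *how much when detected* channels
carry signal, and the 2-df sum uses both without choosing. At the
extremes one channel is empty or unstable and the test falls back to a
single model. Eligibility requires detection in at least 5% of the full
cohort, computed as `ceiling(0.05 * n_cohort)` detected participants.

The combination treats the two statistics as independent. They are
computed on overlapping participants, but the binary channel (who is
above the limit) and the continuous channel (the Cq spread among those
below it) are close to orthogonal; the permutation calibration below is
the empirical check that the nominal size survives this approximation.

Sex-stratified runs repeat the continuous model separately in women and
men for miRNAs detected in at least 90% of samples, with sex removed from
the covariate list (it is constant within a stratum and would make the
design rank-deficient).

## Estimation choices

* **Random-effect structure.** A single random intercept per family. A
  full pedigree/kinship model is deliberately out of scope; at the family
  sizes simulated here a shared intercept captures the clustering the
  phenotype inherits from the family. The same simplification is applied
  to the coexpression models.
* **REML via `lme4::lmer`.** Restricted maximum likelihood; the post-fit
  derivative check is disabled (`calc.derivs = FALSE`) because at these
  problem sizes it dominates runtime without changing estimates. A
  singular fit (between-family variance estimated at zero) is legitimate —
  the fixed effects then equal ordinary least squares — and is not
  flagged; a rank-deficient fixed design is an error, and a constant
  response or failed optimisation is reported as non-converged and
  excluded from FDR with a warning.
* **Wald statistics.** The per-model statistic is the squared
  estimate-to-SE ratio, which is what a reported (beta, SE, p) triple
  implies; likelihood-ratio statistics would require refitting nested
  models per miRNA at no practical benefit for a screen.
* **Centred Cq.** The continuous predictor is centred within the detected
  subset. This is a pure reparameterisation — slope, SE, and p are
  unchanged — but keeps the intercept well-scaled.
* **P-value floor.** A Wald statistic large enough to underflow the
  chi-squared tail is reported at the smallest positive double rather
  than 0, keeping every p in \((0, 1]\) as downstream FDR code requires.

## Permutation calibration

The calibration separates the miRNA matrix from the *clinical block* —
grip strength, all covariates, and the family identifier, which travels
with the phenotype so the random-effect grouping stays attached to it —
and re-orders the clinical block by one shared random permutation while
participant row order (hence the link to the Cq matrix) stays fixed.
Within-block relationships such as grip-versus-age are preserved exactly;
every miRNA–phenotype link is broken. The full two-part analysis is run
on each of 100 such replicates (the default), and the pooled adaptive
p-values are summarised by their empirical rejection fraction at 0.05 and
0.01 and a Kolmogorov–Smirnov test against Uniform(0, 1). Planted effects
in the original cohort do not bias this null, because the permutation
destroys them.

## FDR and downstream selection

Q-values are Benjamini–Hochberg (`stats::p.adjust`, validated in the test
suite against a direct implementation of the step-up definition),
computed jointly across all eligible miRNAs regardless of branch.
Discovery counts are reported at q < 0.10, 0.05, 0.01, 0.001 with strict
inequalities. Two selections feed the downstream stages: the top-k
miRNAs by q (ties broken by adaptive p, then name, so selection is
deterministic), and the miRNAs with a strictly positive governing beta at
q < 0.05 — positive on the Cq scale means expression negatively
associated with grip. The governing beta is the continuous-model
coefficient except on the binary-only branch, where it is the binary
coefficient; this follows the branch actually used for inference even
though the package reports auxiliary fits from the other model when they
are estimable.

## Coexpression and enrichment

For each selected miRNA, gene expression is regressed on centred Cq in
the detected subset with the same covariates and family intercept; pairs
are screened at FDR < 0.05 across all pairs of the run. Within a miRNA
the fixed design is identical for every gene, so after the first gene the
model is refitted to each new response (`lme4::refit`) rather than
rebuilt — numerically identical (checked in the tests against full
per-gene fits) and several-fold faster, which is what makes scans over
hundreds of genes practical.

Enrichment is a one-sided hypergeometric over-representation test. For a
universe of \(N\) genes, a set with \(K\) universe members and \(n\)
selected genes with overlap \(k\): expected overlap \(nK/N\), ratio of
enrichment \(k/(nK/N)\), p-value \(\Pr(X \ge k)\), BH across sets. The
universe defaults to all genes on the expression matrix. Target
predictions and gene signatures are consumed as plain files (two-column
TSV and gene lists) and only counted against, never recomputed.

## Cell-count adjustment

Blood cell composition confounds whole-blood expression. When counts are
measured in only part of a cohort, `impute_cell_counts()` completes them
by partial least squares on the expression matrix (`mixOmics::pls`,
regression mode), choosing the number of latent components per variable
by 10-fold cross-validated RMSE on the measured subset; measured values
pass through untouched. The adjusted analysis is then the identical
association code path with the count columns appended to the covariate
list — no separate machinery.

## The synthetic cohort generator

The generator's defaults encode the study conditions the package is
designed around: 5668 participants, 54% women, age 55.7 (SD 13.2) years,
grip 44.7 (10.0) kg in men and 26.5 (6.3) kg in women, height 69.3/63.9
inches and BMI 29.0/27.3 kg/m² by sex, a Cq detection limit of 27 cycles,
and per-miRNA detection fractions spanning rare to ubiquitous. Grip is
generated as a sex intercept plus centred linear-plus-quadratic age
trend, centred height and BMI terms, planted miRNA effects on the kg
scale, a family intercept, and sex-specific residual noise, floored at
0 kg. Choices worth knowing:

* **Latent Cq censoring.** Each miRNA's latent Cq is Gaussian; the mean
  is shifted so the detection probability (latent at or below the limit)
  equals the declared target, and values beyond the limit are recorded as
  undetected. Undetected (`ND` in files, `Inf` in memory — high Cq *is*
  low expression, so the censored code sorts correctly) is distinct from
  not-assayed (empty cell / `NA`), which is excluded from both models;
  this reproduces panels where some assays were run on only part of a
  cohort. At a target detection fraction of exactly 1 the latent values
  are clamped to the limit so nothing is censored.
* **Sex-specific residual SD (9.0 / 4.6 kg).** The age, height, and BMI
  terms are shared between sexes, so matching the observed total grip SD
  in *both* sexes (10.0 men, 6.3 women) requires the residual scale to
  differ by sex; a single shared value cannot satisfy both.
* **Age trend defaults** (−0.25 kg/year with a small negative quadratic)
  are chosen to give the familiar accelerating decline; they are config
  defaults that produce the right shape and marginal SDs, not a numerical
  reconstruction of any published figure.
* **Independence.** Covariates are drawn independently (no height–BMI
  correlation), family sizes are uniform (no pedigree structure), and
  technical covariates are independent Gaussians that exist to exercise
  the adjustment code path, not to model assay physics. mRNA blocks are
  built from the *latent* (uncensored) miRNA value at a declared
  correlation, plus independent null genes.

Consequently, passing tests demonstrate that the statistics do what they
claim under clean Gaussian, independently-covariate, family-exchangeable
conditions. They do not demonstrate robustness to skewed phenotypes,
covariate collinearity, pedigree-structured relatedness, batch effects,
or assay artefacts — on real data those remain the analyst's
responsibility.

## Problem sizes used for validation

The package's own validation suite (tests and `scripts/acceptance.R`)
uses: 1000 random p-value pairs against a closed-form oracle for the 2-df
combination (agreement to 1e-10 relative); 100 permutation replicates of
a 50-miRNA, n = 1000 cohort for size calibration; 200 replicates at
n = 2000 for recovery of a planted −0.20 kg/Cq effect and its 95% CI
coverage; 200 replicates of a 30-miRNA panel with 10% non-null miRNAs for
realized false-discovery proportion; one 20-gene planted block against
500 null genes at n = 2000 for coexpression recovery; and 100 seeded
gene-set fixtures for enrichment ranking. These sizes are large enough
for the binomial/Monte-Carlo bands they are checked against while keeping
a full run in the minutes range on one CPU.

## Known limitations

* The family random intercept ignores differential relatedness within and
  across generations; with real pedigrees a kinship-aware model will give
  different (usually slightly wider) standard errors.
* The adaptive combination assumes the two parts' statistics are
  independent; calibration is verified empirically by permutation, not
  proved.
* Whether a Cq exactly at the detection limit counts as detected differs
  between conventions; the package follows the strict `Cq > threshold`
  indicator, and the threshold itself is an argument everywhere it is
  used.
* Enrichment is a plain hypergeometric over-representation test; it
  ignores gene–gene correlation and set overlap, so q-values across sets
  are approximate in the way all such screens are.
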