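---
title: "Phenotype risk scores: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype risk scores: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phescore)
library(data.table)
```

## The model

A phenotype risk score (PheRS) measures how much a person's accumulated
EHR diagnoses resemble the clinical pattern of a Mendelian disease. Each
disease $k$ is represented by a set $P_k$ of phecodes — curated groupings
of ICD-9/ICD-10 billing codes. Each phecode $j$ carries a weight

$$w_j = \log_{10}\!\frac{N}{n_j},$$

where $N$ is the number of individuals in the cohort and $n_j$ the number
with at least one occurrence of phecode $j$: rare features are more
informative than common ones, on a log-prevalence (surprisal-like) scale.
The score for person $i$ and disease $k$ is

$$s_{ik} = \sum_{j \in P_k} w_j\, x_{ij},$$

with $x_{ij} = 1$ if person $i$ has at least one occurrence of phecode
$j$ and $0$ otherwise. The indicator is deliberately binary: repeat
postings of a code, including several on one day, do not raise the score.
This makes the score robust to billing intensity but blind to chronicity.

Key assumptions: (i) the cohort is large enough that $n_j/N$ estimates
the population prevalence of each feature; (ii) the phecode sets $P_k$
describe the disease's presentation under local billing practice; (iii)
features contribute additively and independently. None of these is
exactly true in real EHR data, which is why the case/control validation
step exists.

### Residual scores

Raw scores correlate strongly with utilization: someone with a long
record accumulates more codes. Per disease, the package fits an ordinary
least-squares model of the score on an intercept plus covariates —
default: biological sex, age at first visit, and the elapsed time between
first and last visits — and returns residuals divided by
$\hat\sigma = \sqrt{\mathrm{RSS}/(n-p)}$, with $p$ the number of fitted
parameters. Under this convention the residual scores have exact mean 0
(the intercept) and exact "unit variance" in the $n-p$ sense, which makes
scores comparable across diseases. The convention matters only in the
third decimal at cohort sizes of interest, but it is the one under which
the standardization is exact rather than approximate. Sex enters as a
single indicator with the alphabetically first level as reference, so
coefficients are interpretable; covariates with zero variance are dropped
with a warning; a disease whose scores are an exact linear function of
the covariates has no residual scale and is an error rather than a
silently degenerate column.

### Case/control validation

Diagnostic ICD codes — codes that denote the (genetic) diagnosis itself
rather than a feature — define per-disease status: a person with any of
the disease's diagnostic codes on at least two distinct calendar dates is
a case, with none a control, and with exactly one date neither (a single
posting is often a rule-out or coding error; requiring two distinct dates
improves positive predictive value). Dates are pooled across the
disease's diagnostic codes, and "distinct dates" is a calendar-day
concept, which is why occurrence timestamps are truncated to dates on
load. Diagnosed cases should score higher than controls; the package
tests this per disease by OLS of the (residual) score on a case indicator
plus covariates. A configurable minimum case count (default 50) screens
out diseases whose comparison would be unstable; it never affects status
assignment itself. When scores are meant to compare diagnosed with
undiagnosed individuals, the diagnostic codes can be excluded from
phecode mapping so the diagnosis does not trivially inflate its own
score.

### Genetic association

For each user-specified disease–variant pair the package regresses the
score on an encoded genotype plus covariates. Encodings: additive (allele
count), dominant (carrier indicator), recessive (homozygous-alternate
indicator), genotypic (separate heterozygous and homozygous indicators
against a homozygous-reference baseline). Missing genotypes are excluded
pairwise per variant, so each pair uses the maximal available sample,
while genotype counts are always reported over the full cohort. A design
made rank-deficient by an empty genotype class yields a row flagged
non-estimable instead of an error. p-values use the t distribution with
$n - p$ degrees of freedom; an optional Bonferroni column multiplies p by
the number of tested pairs (no multiple-testing procedure is imposed by
default). By default associations use residual scores when present, since
those are comparable across diseases; parameter-recovery analyses against
a planted raw-score effect should pass `score_column = "score"`.

## Building the disease map

The disease–phecode map can be supplied directly or built from two
assets: disease-level HPO annotations (disease, HPO term, gene,
inheritance, provisional flag) and an HPO-term-to-phecode link table.
Annotation rows with multifactorial, somatic, or unspecified inheritance,
or marked provisional, are dropped — row-level, so a disease annotated
through several genes keeps its retained rows. After joining and
deduplicating, diseases with fewer than three distinct phecodes are
removed: a one- or two-feature "pattern" is not a pattern. The
`match_quality` column (exact vs broader) is carried through for user
filtering but not used in scoring. The bundled maps are small synthetic
fixtures (see `inst/extdata/README.txt`) so that examples and tests run
without any ontology download; real analyses must supply real releases,
whose curation quality — especially of HPO-to-phecode links — directly
bounds what the scores can detect.

## The synthetic cohort generator

`simulate_cohort()` emulates the minimal structure the pipeline needs:

* **Demographics.** Sex Bernoulli(0.5); age at first visit uniform on
  0–90 years; visit span exponential with mean 8 years plus a 30-day
  floor (so two distinct diagnostic dates always fit in the window);
  first visits spread uniformly over a decade. Birth dates are included
  so age derivation from dates is exercised.
* **Background codes.** Each non-diagnostic ICD code of the map is
  present in a person with a code-specific base probability, log-uniform
  across codes and scaled so the expected number of distinct codes per
  person equals `background_code_rate` (default 2 — against the toy
  ~40-code universe this puts per-code prevalences around 5% and
  feature-phecode weights around 1, the scale real phecode prevalences
  occupy). A per-person multiplier
  $\exp(b_\text{sex} z_\text{sex} + b_\text{age} z_\text{age} +
  b_\text{span} z_\text{span})$ (defaults 0.2/0.3/0.3, normalized to
  mean 1) ties code burden to the covariates so residualization has real
  signal to remove. Present codes receive one or two occurrence dates
  uniform in the visit window.
* **Planted cases.** For each disease signal (default: 1% of the cohort
  as cases of one diagnosable toy disease), each disease phecode is
  expressed through a randomly chosen source ICD code with emission
  probability 0.8 — severe but not fully penetrant — and a diagnostic
  code is posted on exactly two distinct dates. Diagnostic codes are
  never emitted as background, so nobody becomes a case by accident.
* **Genotypes.** Hardy-Weinberg draws per variant. Carriers of an effect
  variant receive additional disease-phecode emissions planted
  *conditionally* on what they already express: the phecodes the carrier
  lacks are visited in random order and emitted until the accumulated
  expected weight reaches the target effect, the boundary phecode being
  emitted with the fractional probability that makes the conditional
  expected raw-score shift equal `effect_hom` (or `effect_het`) exactly —
  randomized rounding. Expected weights are adjusted in a second pass for
  the carriers' own contribution to phecode prevalence. This conditional
  scheme plants a nearly homogeneous shift across carriers, so the
  linear model the analysis fits is approximately correctly specified
  and its standard errors remain meaningful; an unconditional per-phecode
  Bernoulli scheme would add carrier-level variance the model does not
  see. A planted effect larger than the disease's maximum attainable
  score is rejected up front. Defaults: a pathogenic variant (allele
  frequency 0.10, homozygote effect 2.0 raw-score units, no heterozygote
  effect) and a benign variant (frequency 0.20, no effect) — the
  recessive architecture the association step should resolve. 1% of
  genotype records are masked to missing.

All randomness flows from the single config seed, so identical configs
give byte-identical outputs.

What the generator deliberately does **not** model: visit clustering and
care episodes, coding-era shifts (ICD-9 to ICD-10 migration waves),
correlated comorbidity structure, miscoding, relatedness or population
structure in genotypes, and any phenotype information beyond ICD codes.
Passing tests on synthetic cohorts therefore demonstrate that the
*computations* are correct and that the statistical machinery behaves as
designed under clean conditions — not that the scores will be well
calibrated on any particular real EHR.

## Numerical and design choices

* **N in the weight denominator** counts every demographics row, not just
  persons with a phecode — the cohort is "everyone with at least one
  visit", and orphan ICD rows referencing unknown persons are a hard
  error precisely so that N cannot drift silently.
* **Unobserved phecodes** have no defined weight ($\log_{10}(N/0)$); they
  are omitted from the weight table and contribute 0 to scores, with a
  warning naming them.
* **Zero-score persons are materialized** in a dense person-by-disease
  grid, so residualization and case/control comparisons see the full
  zero-inflated cohort rather than only the scored minority.
* **Joins are exact-string** on whitespace-trimmed, upper-cased dotted
  ICD codes, with the ICD version flag always part of the key; no
  prefix/rollup matching is attempted, because phecode maps enumerate
  codes at full code level. Unmapped codes are logged, never fatal.
* **Same-day repeat postings** collapse to one occurrence on load. Under
  the binary indicator this cannot change any score; it does change
  logged occurrence counts, which is the only place the choice is
  visible.
* **OLS everywhere** is computed through a pivoted QR decomposition, so
  rank deficiency surfaces as flagged non-estimable coefficients;
  equivalence with the closed-form $(X^\top X)^{-1}X^\top y$ solution is
  part of the test suite.
* **Problem sizes in the test suite** (cohorts of 200–5000; 100
  simulation replicates for parameter-recovery checks; 1000 replicates
  for type-I error at $n=500$; Hardy-Weinberg frequency checks at
  $n=10^5$) were chosen to give the Monte-Carlo checks tight tolerances —
  binomial 99% bands for rejection rates, a 5% band on the mean recovered
  effect — while keeping a full run around a minute on one CPU.

## Known limitations

Association p-values are classical OLS p-values; with heavy-tailed,
zero-inflated scores they are accurate for moderate and large genotype
groups but slightly anti-conservative for very small ones (a
few-dozen-person homozygote class), where the group mean's distribution
is still visibly non-normal. Robust or permutation inference is a
sensible extension. The score model itself ignores time course and
zero-inflation by design; both are natural directions for richer models,
as is phenotype input beyond ICD codes. Finally, case identification from
diagnostic billing codes alone is impossible for most Mendelian diseases,
which simply lack a specific code — the validation step can only ever
cover the diagnosable minority.
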