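---
title: "Methods: craving-phenotype association and the unweighted genetic risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: craving-phenotype association and the unweighted genetic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hucgrs)
```

## The analysis in one page

`hucgrs` implements a candidate-gene quantitative-trait pipeline for heroin
craving in methadone-maintenance (MMT) cohorts. The phenotype is the 14-item
heroin-use and craving (HUC) questionnaire: every item is scored 0–4, Part I
(items 1–6) sums to the *urge* subscore (0–24), Part II (items 7–14) to the
*ability-to-overcome* subscore (0–32), and the two together to the *total*
craving score (0–56); higher is always more severe.

For each SNP the genotype is reduced to a numeric code under an inheritance
mode — additive (risk-allele count 0/1/2), dominant (carrier vs
non-carrier), or recessive (risk homozygote vs rest) — and the phenotype is
regressed on the code with an ordinary linear model,

$$y_i = \beta_0 + \beta_g \, g_i + \beta_a\,\mathrm{age}_i +
\beta_s\,\mathrm{sex}_i + \beta_b\,\mathrm{BMI}_i + \varepsilon_i,$$

reported both without the covariates (the *unadjusted* fit, whose $R^2$ is
the marginal variance explained by the SNP) and with them. The reported
p-value is always the genotype coefficient's two-sided t-based p, not the
omnibus F; for a single coded predictor the two coincide unadjusted, and the
coefficient p is the standard adjusted-model report.

SNPs associated with the target phenotype are then combined into an
**unweighted genetic risk score** (GRS): each SNP's genotypes are mapped to
integer codes (0/1 for binary groupings, 0/1/2 for additive), and a
subject's GRS is the plain sum. For the built-in five-SNP panel
(`craving_risk_model()`: GRIN3B rs2240158, GRIN3A rs3983721, CYP2C19
rs6583954, TPH2 rs2129575, COMT rs174699 — four binary groupings plus one
additive coding) the score spans 0–6. The dose–response claim is tested by
regressing the phenotype on the integer GRS; the *p for trend* is the GRS
coefficient's p-value.

## Risk-coding assignment

The risk direction of each SNP is estimated from the genotype-stratified
phenotype means of the cohort itself:

* **additive** — the risk allele is the allele of the homozygote class with
  the higher mean; codes are risk-allele counts.
* **recessive (binary grouping)** — the grouping isolates the homozygote
  class whose mean lies *farther from the heterozygote mean*, and the group
  with the higher mean is coded 1. When the isolated homozygote is the
  low-mean class, code 1 therefore marks carriers of the other allele. This
  single rule is what panels of this kind actually report: some of the
  published groupings isolate a protective homozygote (e.g. rs2240158's
  "TT = 0 vs C-carriers = 1") even though the row is labelled recessive, and
  the far-from-heterozygote rule reproduces every such grouping while the
  strict textbook recessive coding (`code_genotypes()`) cannot.
* **dominant** — the candidate risk allele maximizing the carrier vs
  non-carrier mean difference.
* **best_fit** — all three codings are fitted (genotype-only model) and the
  smallest genotype-coefficient p wins; ties break toward larger $R^2$,
  then additive first.

Exactly tied means raise an error asking for an explicit coding rather than
silently picking a direction.

Two caveats are deliberate and prominent. First, deriving the coding from
the cohort that is subsequently scored is *circular*: single-SNP and
combined $R^2$ from the same data are optimistic, and the honest use of the
GRS is with a frozen, externally derived `risk_model` (supply one to
`compute_grs()`; `craving_risk_model()` is such a frozen model). Second, no
multiple-testing correction is applied by default — the selection rule
(raw p < `alpha` per phenotype, with `force_include` available for
borderline SNPs) mirrors how such candidate panels are typically assembled —
so the per-SNP p-values should be read as descriptive.

## Quality control

* **HWE**: the 1-df chi-square goodness-of-fit test against
  $(n\hat p^2, 2n\hat p\hat q, n\hat q^2)$, without continuity correction —
  the plain $\sum (O-E)^2/E$ form. Monomorphic SNPs are flagged, not
  errors. The asymptotic test is anticonservative at low MAF and small n;
  defaults keep it behind a lenient `hwe_alpha = 1e-4`.
* **MAF** filter at 0.05 (the panel's design threshold) and call-rate
  filter at 0.9; both configurable. The HWE alpha and call-rate defaults
  are conventional choices, stated as configuration rather than inferred
  fact.
* **Duplicate concordance** over designated sample pairs counts matches
  among jointly non-missing calls (genotyping batches of this kind are
  expected to exceed 0.99).

Descriptive cohort tables use the plain Pearson contingency chi-square and
the pooled-variance two-sample t-test (Welch by flag); the t-test accepts
either raw vectors or (n, mean, SD) summaries and gives identical answers
on matching data.

## The synthetic cohort generator

Real genotype–phenotype records for such cohorts are not publicly
deposited, so the package carries a first-class simulator whose defaults
are the study conditions the analysis assumes:

* n = 326 subjects, 79.4% male; age 43.2 (SD 7.2) years for men and 37.8
  (6.3) for women; BMI 23.0 (2.8) vs 21.6 (2.8) kg/m² — the composition of
  the MMT cohort in which the five-SNP panel was characterized. (Reported
  sizes for that cohort vary between 316 and 326 across its descriptions;
  the simulator defaults to 326.)
* biallelic genotypes drawn independently per SNP from HWE trinomial
  proportions at the configured MAF (> 0.05 for all panel SNPs);
* a latent phenotype linear in the mode-coded genotypes and covariates with
  Gaussian residual noise (default SD 9.5 score units, matching the
  observed total-score spread), baseline chosen so the expected total is
  about 27;
* per-SNP effects are conveniently sized via
  `effect_for_variance_share()`, which converts a target marginal $R^2$
  (the 3–5% per-variant scale typical of such panels) into a coefficient
  using the HWE variance of the coded genotype;
* the latent total is clipped to [0, 56], rounded, and distributed over the
  14 items round-robin in increments of 1 (capped at 4), so the scored
  total equals the clipped latent value exactly — the total is the analysed
  quantity, so allocation preserves it rather than emulating item-level
  psychometrics;
* optional upper-tail ascertainment (`apply_extreme_sampling`) emulates
  recruiting severe addicts from the extreme of the phenotype range, and
  optional independent per-call missingness emulates genotyping dropout.

One global seed feeds four fixed substreams (covariates, genotypes, noise,
missingness), so changing, say, the residual SD leaves the genotype draw
untouched, and identical (config, seed) is bit-reproducible.

What the simulator does **not** emulate: linkage disequilibrium between
SNPs (the analysis treats SNPs marginally), population stratification,
genotyping error structure beyond uniform missingness, item-level response
behaviour, and floor/ceiling effects beyond hard clipping. Green simulation
tests therefore certify the statistical machinery under the model's own
assumptions, not robustness to real-data pathologies.

## Numerical and design choices

* Least squares is solved by QR; rank deficiency is an error naming the
  offending column, as is a zero-variance response. Standard errors use the
  unbiased residual variance; p-values the t distribution with n − k df.
* Genotype calls are unordered allele pairs normalized alphabetically
  ("G/A" ≡ "A/G"); the missing code is "./." in every format. VCF input is
  read-only (GT field, biallelic records, phase ignored).
* Complete-case analysis throughout; subjects with any missing
  questionnaire item are excluded from scoring with a logged count (no
  imputation rule is defined for the instrument).
* The GRS treats the score as a continuous integer covariate in the trend
  test (an ordinal treatment is a reasonable alternative; continuous is the
  conventional "p for trend" reading). The trend is unadjusted by default,
  with an adjusted variant behind a flag.
* `missing_policy = "exclude"` drops subjects with any missing model SNP
  from the GRS by default: unweighted sums over partially observed panels
  are not comparable across subjects. `"partial"` is available and flags
  the affected subjects.
* Sex is coded 0 = female, 1 = male everywhere.

## Problem sizes used by the shipped checks

The package's own verification uses: 1000 null cohorts of n = 326 for
type-I error calibration of the association test; 200 cohorts of n = 2000
for recovering a recessive SNP simulated at a 4% variance share; 200
five-SNP cohorts of n = 326 for the combined-vs-single-SNP comparison; and
2000 trinomial draws of n = 1000 for HWE-test calibration. These sizes give
Monte-Carlo error comfortably inside the asserted bands while keeping the
default check run short.

## Worked example

```{r}
paths <- make_fixtures(file.path(tempdir(), "example"), seed = 2026)
gm <- read_genotype_table(paths[["genotypes"]])
ph <- score_huc_table(read_phenotype_table(paths[["phenotypes"]]))

qc <- qc_filter(gm, craving_snp_info())
head(qc$report)

model <- craving_risk_model()
grs <- compute_grs(gm, model)
grs_trend_test(grs, ph, "total")
```

## Known limitations

Beyond the simulator's scope above: no effect-weighted or LD-aware
polygenic scores, no cross-validation of the risk model, no mixed models or
relatedness adjustment, no X-chromosome handling, no exact HWE test, and no
genome-wide scalability (the design targets dozens of candidate SNPs, not
millions).
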