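# hucgrs

Candidate-gene association and unweighted genetic risk scores for heroin
craving phenotypes.

## What problem this solves

Craving is the motivational core of heroin addiction and a strong predictor
of relapse in methadone maintenance therapy (MMT). A practical question for
addiction genetics is whether a small panel of candidate variants in the
reward system (NMDA-receptor subunits *GRIN3A*/*GRIN3B*, the serotonin
enzyme gene *TPH2*, *COMT*, and the methadone-metabolizing *CYP2C19*) can
grade patients by craving severity. `hucgrs` is a reusable R implementation
of that analysis for quantitative craving phenotypes measured by the
14-item heroin-use and craving (HUC) questionnaire:

* **Scoring** — items 1–6 sum to the *urge* subscore (0–24), items 7–14 to
  the *ability-to-overcome* subscore (0–32), all 14 to the *total* craving
  score (0–56).
* **Genotype QC** — Hardy–Weinberg equilibrium by the 1-df chi-square
  goodness-of-fit test, minor-allele-frequency and call-rate filters,
  duplicate-sample concordance.
* **Single-SNP association** — linear models of phenotype on mode-coded
  genotype (additive 0/1/2, dominant, recessive), with and without
  adjustment for age, sex and BMI; the SNP's marginal R² is reported from
  the genotype-only fit.
* **Genetic risk score (GRS)** — per-SNP genotype→{0,1} or {0,1,2} risk
  codings assigned from genotype-stratified phenotype means, summed
  unweighted: for the built-in five-SNP panel the score runs 0–6. The
  dose–response claim is tested by regressing phenotype on the integer GRS
  ("p for trend").
* **Synthetic cohorts** — a first-class simulator (HWE genotypes,
  MMT-cohort covariates, linear latent phenotype + Gaussian noise,
  questionnaire discretization, optional extreme-phenotype ascertainment
  and missingness) provides test inputs with known truth.

The core model is ordinary least squares,

```
craving = b0 + bg * genotype_code (+ b_age age + b_sex sex + b_bmi BMI) + e,
GRS_i   = sum_k code_k(genotype_ik),    p_trend = p-value of bg in craving ~ GRS
```

See `vignettes/hucgrs-methods.Rmd` for the methods account, including why
the "recessive" binary groupings are assigned by isolating the homozygote
class farthest from the heterozygote mean, and why in-sample risk-coding
assignment is circular and flagged as such.

## Worked example

A small simulated example cohort (60 subjects, the five-SNP panel plus
three null SNPs) ships under `inst/extdata/`:

```r
library(hucgrs)
gm <- read_genotype_table(system.file("extdata", "genotypes.tsv", package = "hucgrs"))
ph <- score_huc_table(read_phenotype_table(system.file("extdata", "phenotypes.csv", package = "hucgrs")))

grs <- compute_grs(gm, craving_risk_model())
table(grs$grs)
#>  0  1  2  3  4  5  6
#>  2  9 19 16  9  4  1

grs_trend_test(grs, ph, "total")
#> GRS dose-response trend (total, unadjusted): n = 60
#>   beta = 5.177 (se 1.132), p for trend = 2.553e-05, R^2 = 0.2652
#>   grs  n  mean     sd
#> 1   0  2  7.50  9.192
#> 2   1  9 14.22 10.940
#> 3   2 19 25.11 11.695
#> 4   3 16 29.25 12.091
#> 5   4  9 29.00 10.320
#> 6   5  4 34.50  7.416
#> 7   6  1 53.00     NA
```

Each extra risk allele raises the mean total craving score by about 5
points in this cohort (simulated with every panel SNP active), and the
per-level ladder of means shows the dose–response shape the trend test
summarizes. A single-SNP fit looks like:

```r
associate_snp(gm, ph, craving_snp_info()[2, ], "total",
              mode = "recessive", risk_allele = "T")
#>         snp   gene      mode  n  beta   se p_unadjusted p_adjusted     r2
#>   rs3983721 GRIN3A recessive 60 8.889 3.72       0.0202     0.0208 0.0896
```

i.e. rs3983721 TT homozygotes average ~8.9 points higher total craving
than C-carriers, explaining ~9% of variance in this small example.

The full pipeline (QC → association → risk model → GRS → reports) is one
call:

```r
run_pipeline(list(out_dir = "run1", seed = 42))   # simulated-input mode
```

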