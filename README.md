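# loyscan

Mosaic loss of chromosome Y (mLOY) — the clonal disappearance of the Y
chromosome from a fraction of a man's blood (or saliva-derived) cells — is
the most common somatic chromosomal alteration of male aging, and an
emerging marker of genomic instability after cancer treatment. `loyscan`
is an R package for epidemiologists and statistical geneticists who need
to go from SNP-array log R ratio (LRR) matrices to treatment-association
results:

1. **Signal**: per-sample **mLRR-Y**, the median LRR over probes in the
   male-specific region of Y (MSY). A clone of cell fraction *f* shifts it
   to about `log2(1 − f)`, so the conventional absolute cutoff
   mLRR-Y ≤ −0.15 marks clones in ≈10% of cells.
2. **QC**: samples missing >1% of MSY probes or >5% of all probes are
   excluded (strict inequalities, reported per sample).
3. **Calling**: absolute threshold, or per-cohort percentile ("top *q*
   lowest mLRR-Y", k = ⌈qn⌉ with ties included) — the percentile scheme is
   what makes cohorts on different array platforms comparable — plus a
   threshold sensitivity sweep with a minimum exposed-event rule.
4. **Association**: exact Fisher r×c tests for baseline tables, crude 2×2
   odds ratios (Haldane–Anscombe corrected when needed), adjusted logistic
   regression (Wald inference, separation flagged), time-since-treatment
   strata, per-Gy dose–response models, and the age–mLRR-Y trend.
5. **Pooling**: inverse-variance fixed-effect meta-analysis with
   Cochran's Q, I² (banded <25 / 25–75 / >75), two-level pooling (cohorts
   within cancer sites, then across sites), SE reconstruction from
   published OR + 95% CI pairs, and a two-group heterogeneity z-test.
6. **Synthesis**: a seeded generator of two-platform cohorts with known
   clonal ground truth (age- and radiotherapy-dependent clone carriage,
   Beta-distributed clone fractions, probe noise, missingness), so the
   whole pipeline is testable without controlled-access genotype data.

## Worked example

Simulate two cohorts on shifted platforms and run the full study:

```r
library(loyscan)

cfg <- study_config(
  simulate = list(params = list(n_samples = 2000L, seed = 1L),
                  cohorts = c("cohort1", "cohort2"),
                  platform_shifts = c(0, -0.08)),
  sweep = list(q_grid = c(0.01, 0.05, 0.1, 0.25, 0.5),
               min_exposed_events = 10))
rep <- run_study(cfg)

rep$prevalence$absolute[, c("cohort", "n", "n_mloy", "pct_mloy")]
#>    cohort    n n_mloy pct_mloy
#> 1 cohort1 1968    189     9.60
#> 2 cohort2 1975    178     9.01

subset(rep$associations$absolute, model == "rt")[, c("stratum", "or", "ci_low", "ci_high", "p")]
#>            stratum   or ci_low ci_high        p
#> 1 cohort1/prostate 2.33   1.71    3.16 6.34e-08
#> 4 cohort2/prostate 2.99   2.17    4.12 1.79e-11

rep$meta$absolute$per_site[, c("site", "k", "or", "ci_low", "ci_high", "Q", "i2", "p_het")]
#>       site k   or ci_low ci_high    Q   i2 p_het
#> 1 prostate 2 2.62    2.1    3.27 1.23 18.9 0.267

rep$age_trend$cohort1
#> $intercept  0.0726
#> $slope     -0.00161
#> $p_slope    1.71e-05
```

Reading it: ~9% of samples are called mLOY at the absolute cutoff; the
age-adjusted radiotherapy odds ratios of the two cohorts (2.33 and 2.99,
both p < 1e-7 — the generator's default radiotherapy effect on clone
carriage is log-OR 0.9 ≈ OR 2.46) pool to OR 2.62 with no meaningful
between-cohort heterogeneity (I² = 19%, p_het = 0.27); mLRR-Y declines by
~1.6×10⁻³ per year of age, the expected inverse age trend. The sweep table
(`rep$sweep`) shows the association attenuating from OR 2.9 at the top-1%
threshold to 1.2 at the top-50% threshold — the tail-concentration
signature.

Summary-level tables from a published two-cohort radiotherapy–mLOY study
are bundled for the examples:

```r
tabs <- study_summary_tables()
ipsa <- subset(tabs$table1, characteristic == "ipsa")
fisher_exact_rxc(as.matrix(ipsa[, c("n_mloy", "n_non_mloy")]))
#> [1] 0.8205063
```

A thin command-line wrapper lives at `inst/cli/loy-scan.R`
(`Rscript loy-scan.R <simulate|run> --config cfg.yaml --out-dir DIR`).

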