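---
title: "Calling mosaic loss of chromosome Y and modelling its treatment associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mosaic loss of chromosome Y and modelling its treatment associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loyscan)
```

## The signal and its model

Mosaic loss of chromosome Y (mLOY) is a clonal somatic event in which a
fraction $f$ of a man's sampled cells — usually blood leukocytes, in
saliva a mixture of leukocytes and buccal cells — carry no Y chromosome.
On a SNP array the total fluorescence at a probe, summarised as the log R
ratio (LRR), is a proxy for copy number. A normal male carries one Y, so a
clone of fraction $f$ leaves on average $1 - f$ Y copies per cell and the
expected LRR at probes in the male-specific region of Y (MSY) is

$$\mathrm{E}[\mathrm{LRR}] = \log_2(1 - f).$$

`loyscan` summarises each sample by **mLRR-Y**, the median LRR over its
non-missing MSY probes (`compute_mlrry()`). The median, not the mean, is
the field's convention: it is insensitive to the occasional mis-clustered
probe. Under this attenuation model the conventional absolute calling rule
mLRR-Y $\le -0.15$ corresponds to a clone occupying about
$1 - 2^{-0.15} \approx 9.9\%$ of cells; `fraction_to_mlrry()` and
`mlrry_to_fraction()` expose the conversion.

Two calling schemes are supported, because absolute LRR values do not
transfer across array platforms:

* **absolute** (`call_absolute()`): mLRR-Y $\le$ a fixed cutoff, inclusive
  at the boundary; appropriate within one platform.
* **percentile** (`call_percentile()`): within each cohort, the samples in
  the bottom $q$ tail of the signal distribution are called. The cutoff is
  the $k$-th smallest signal with $k = \lceil qn \rceil$, and ties at the
  cutoff are all called. Ceiling plus tie-inclusion is a deterministic
  resolution of the inherent ambiguity of "top $q\%$" at finite $n$, and
  errs toward sensitivity. The percentile is taken per cohort by default
  (platform = cohort); a pooled scope is available but mixes platform
  location shifts into the calls.

Within-cohort standardization (`standardize_within_cohort()`) is the plain
per-cohort z-score with the $n-1$ standard deviation. Published
descriptions of standardized mLOY signals rarely pin down the exact
transform; the z-score is our explicit, documented choice, and the
percentile caller is rank-based, so any monotone alternative would produce
identical calls within a cohort.

## Sample quality control

Two missingness filters run before any signal is computed
(`qc_filter()`): samples missing more than 1% of MSY probes are excluded
(the MSY median would otherwise rest on too thin a base), and samples with
an overall missing call rate above 5% are excluded (a generic array
quality rule). Both comparisons are strict (`>`): a sample at exactly the
threshold is kept, mirroring the usual "more than 1% / exceeding 5%"
phrasing. Missing LRR entries are ignored in medians and never imputed.

## Association models

All per-sample inference is standard epidemiology, routed through base R:

* `fisher_exact_rxc()` — exact two-sided Fisher test for baseline
  $r \times c$ tables. The two-sided p-value is the probability-ordering
  definition (sum of all tables with fixed margins whose probability does
  not exceed the observed one, with $10^{-7}$ relative tolerance against
  floating-point ties). The $2\times2$ case is a single hypergeometric
  sum; larger tables are enumerated exhaustively, so grand totals are
  guarded ($\le 10^4$ for $2\times2$, $\le 10^3$ otherwise) — beyond that
  a chi-square test is the right tool, and the error says so. Tables with
  an all-zero margin return $p = 1$ by convention.
* `or_from_2x2()` — crude odds ratio with the Wald SE
  $\sqrt{1/a+1/b+1/c+1/d}$; a zero cell triggers the Haldane–Anscombe
  +0.5 correction and a flag; a zero margin yields a flagged undefined
  result rather than a number.
* `fit_logistic()` — binomial-logit maximum likelihood via `stats::glm`
  (IRLS, tolerance $10^{-10}$, at most 50 iterations), complete-case with
  the dropped count reported, Wald CIs using $z = 1.959964$. Separation
  and non-convergence are flagged, never silently repaired (no Firth
  penalty by design).
* `treatment_associations()` — one adjusted model per treatment flag
  (radiotherapy, endocrine therapy, surgery), default adjustment age +
  ever/never smoking, fitted per cohort-by-site stratum; sites with
  $n \le 1000$ are skipped when several sites are present. Separate
  per-treatment models are the default reading of forest-plot style
  reports; a joint model is a trivial variation through `fit_logistic()`.
* `time_stratified()` — one model with two indicators (irradiated
  $<1$ year before sampling; $\ge 1$ year), never-irradiated as reference.
  Exactly 1.0 year goes to the later stratum.
* `dose_response()` — per-Gy logistic model restricted to one
  radiotherapy modality; modalities with fewer than 10 samples are
  excluded.
* `age_trend()` — OLS of mLRR-Y on age in years, linear by choice (no
  published functional form to follow), two-tailed t-test on the slope.

No multiple-testing correction is applied anywhere: the workflow mirrors
reports of unadjusted two-tailed p-values at $\alpha = 0.05$, and its
sweep and stratified analyses are explicitly exploratory.

## Meta-analysis

`fixed_effect()` pools log odds ratios with inverse-variance weights
$w_i = \mathrm{se}_i^{-2}$ and reports Cochran's
$Q = \sum_i w_i(\theta_i - \hat\theta)^2$ on $k-1$ degrees of freedom,
$I^2 = \max(0, (Q - \mathrm{df})/Q) \cdot 100$ (0 when $Q = 0$, floored at
0, reported in percent and banded low/moderate/high at <25 / 25–75 / >75),
and the chi-square heterogeneity p ($1$ when $k = 1$). `two_level_meta()`
first pools cohorts within each cancer site, then the per-site estimates
into the overall effect; because inverse-variance pooling is associative
the pooled value and SE are identical to single-level pooling (a tested
$10^{-12}$ identity) and the level-2 $Q$ isolates between-site
heterogeneity — with four sites, three degrees of freedom.
`se_from_ci()` reconstructs $\mathrm{se} = (\ln \mathrm{hi} - \ln
\mathrm{lo}) / (2 \cdot 1.959964)$ from a published OR and 95% CI
(symmetric Wald interval on the log scale; printed rounding is absorbed by
using both bounds), and `subgroup_heterogeneity()` is the two-sample z
test on the log-OR scale, algebraically the df-1 between-group $Q$. The
exact normal quantile 1.959964 is used internally; agreement with printed
values is assessed at their printed precision.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage of the pipeline — QC,
calling, modelling, pooling — can run and be validated with a known
ground truth, since individual-level array data of this kind are
controlled-access. It generates, per sample:

* age $\sim N(\mu, \sigma)$, smoking and treatment flags (Bernoulli),
  radiotherapy modality (IMRT / brachytherapy / proton at 75/22/3%),
  nominal total dose (IMRT $\approx 72 \pm 2$ Gy, brachytherapy
  $\approx 158 \pm 15$ Gy — external-beam prostate schedules vs nominal
  implant doses), and an exponential time since radiotherapy (mean 2 y);
* clone carriage Bernoulli on the logit scale,
  $\mathrm{logit}\,P = c_0 + \beta_{\mathrm{age}}\,\mathrm{age} +
  \beta_{\mathrm{RT}}\,\mathrm{RT}$, with optional recency and per-Gy
  terms for experiments that need a time- or dose-structured truth;
* a clone fraction $f \sim \mathrm{Beta}(a, b)$ for carriers, $f = 0$
  otherwise (zero-inflation matches the empirical picture that most men
  have no detectable clone);
* MSY probe LRRs $\sim N(\log_2(1-f) + \text{shift}, \sigma_p)$,
  autosomal probes $\sim N(0, \sigma_p)$, and uniform missingness.

Platform differences are modelled as a pure location shift — exactly the
failure mode that motivates per-cohort percentile calling, and enough to
exercise it. Each cohort draws from its own RNG stream seeded by
`seed + cohort_index`, so adding a cohort never perturbs existing ones.

**Default calibration.** The defaults describe a small elderly prostate
cancer cohort: $n = 400$, 100 MSY + 300 autosomal probes, age
$N(70, 8^2)$, 30% irradiated, logit intercept $-6.9$,
$\beta_{\mathrm{age}} = 0.06$/y (clone odds roughly doubling per decade,
in line with the known steep age dependence),
$\beta_{\mathrm{RT}} = 0.9$, $f \sim \mathrm{Beta}(5, 15)$ (mean 25%,
$\approx 96\%$ of carrier fractions above the $\approx 9.9\%$ detection
fraction implied by the $-0.15$ cutoff, so calls track carriage),
$\sigma_p = 0.18$, 0.2% missingness. This yields an absolute-threshold
prevalence around 8–9%, matching the order observed in saliva-based
cohorts of this age, and a negative age–mLRR-Y OLS slope of order
$-2\times10^{-3}$ per year, the same order as published scatter fits.

What the generator does **not** emulate: B-allele frequencies or
genotypes, probe-specific biases (GC waves, intensity re-clustering),
non-Gaussian LRR tails, correlated missingness, sample-contamination
artefacts, or any within-sample mixture beyond a single Y-loss clone.
Passing tests therefore certify the statistical machinery under the
stated signal model, not robustness to every failure mode of real arrays.

## Validation suite: problem sizes and expectations

The package's own operating characteristics are measured by simulation
with fixed seeds:

* **CI coverage.** 500 cohorts of $n = 5000$ with
  $\beta_{\mathrm{RT}} = 0.9$; the adjusted logistic 95% CI for the
  radiotherapy coefficient should cover the truth in $95\% \pm 2.5\%$ of
  replicates. Detection thinning (the $\approx 4\%$ of carriers below the
  threshold fraction) biases the call-scale coefficient by well under a
  tenth of its standard error at this size, so coverage is interpretable
  against the carriage-scale truth.
* **Type-I error.** 1000 null ($\beta_{\mathrm{RT}} = 0$) cohorts of
  $n = 1000$, expecting $5\% \pm 2\%$ rejections. The cohort size is
  chosen so the stratum carries roughly 85 events — about the
  ten-events-per-parameter regime the Wald approximation needs. At
  $n = 400$ the Wald test is visibly conservative ($\approx 1.5\%$); that
  is a property of small-sample Wald inference, worth knowing when
  reading small-cohort p-values, and not a defect the suite should
  conflate with implementation error.
* **Age trend.** The OLS slope of mLRR-Y on age should be negative in at
  least 95% of 200 default cohorts.
* **Sweep attenuation.** With the default tail-concentrated effect, the
  crude odds ratio of the percentile sweep (`sweep_thresholds()`)
  declines toward 1 as the threshold broadens from the top 2% to the top
  50% — called samples at broad thresholds are mostly noise-ranked
  non-carriers. Thresholds with fewer than 10 exposed events are flagged
  excluded rather than dropped.

These sizes keep the full suite within a few minutes on one CPU while
leaving each band's Monte-Carlo error well inside its tolerance.

## Degenerate inputs and numerical conventions

* QC: empty matrices error; a sample with zero non-missing MSY probes
  errors in `compute_mlrry()` (it should have been excluded upstream).
* Standardization: a cohort with fewer than 2 samples or zero variance is
  a hard error, not an NaN.
* Percentile calling requires a tie-free reading of "top $q\%$" — see the
  ceiling + tie-inclusion rule above; `q` is capped at 0.5.
* Odds ratios: zero cells get +0.5 with a flag; zero margins are
  undefined with $p = 1$.
* Logistic separation is flagged; estimates from flagged fits are
  excluded from downstream pooling in `run_study()`.
* mLRR-Y above 0 maps to clone fraction 0 with a warning (noise can push
  the median above baseline).
* Exact normal quantile 1.959964 throughout; comparisons against printed
  values round to the printed precision at comparison time only.

## Reporting conventions

Count tables report both readings of an "mLOY in RT" percentage — the
exposure share among called samples and the prevalence of calls within
the exposed — because published tables are sometimes internally arithmetic
on one definition while described in prose as the other
(`summarize_prevalence()` emits both, with explicit numerators and
denominators). `run_study()` composes all stages on either simulated or
file-based inputs, logs every exclusion with counts to standard error,
and writes TSV tables plus a single `report.json` with a provenance block
(full config, seed, package and R versions), so every number in a report
is regenerable from its inputs.

## Known limitations

* The percentile scope within large multi-site cohorts (whole cohort vs
  per site) is a genuine degree of freedom in published analyses; both
  are implemented, with cohort-wide as default.
* Fisher enumeration beyond the guard totals is refused rather than
  approximated; use a chi-square test there.
* No survival modelling, propensity adjustment, B-allele-frequency or
  phase-based mosaic-event detection; raw two-channel normalization into
  LRR is upstream of this package's scope.
* Separation is reported, not repaired — strata with a handful of events
  yield flagged rows by design.
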