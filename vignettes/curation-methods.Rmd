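---
title: "Statistical curation of historical seed-regeneration phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical curation of historical seed-regeneration phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenphen)
```

## The data and the model

Genebanks regenerate stored seed every few years, and curators record
phenotypes — flowering time (FT, days), plant height (PH, cm), thousand grain
weight (TGW, g) — on the multiplication plots. Decades of this routine yield
a large but severely unbalanced record: no experimental design, one plot per
accession in a year (about 1% of accession-years have two), accessions
observed in anything from 1 to 20+ years, yearly cohorts ranging from a dozen
to thousands of accessions, and missingness that is *block-structured*
because accessions entering the genebank together were regenerated together.

All analyses in this package build on one two-way mixed model per
trait × growth habit (winter and spring material are never pooled, because FT
is counted from different reference dates):

$$y_{iyr} = \mu + g_i + u_y + e_{iyr}, \qquad
  u_y \sim N(0, \sigma^2_Y), \qquad
  e_{iyr} \sim N(0, \sigma^2_{e,y}),$$

with genotype effects $g_i$ fixed or random depending on the question and a
**separate error variance for every year** — growing conditions, measurement
protocols and staff changed over seven decades, so homoscedasticity is not
defensible. Three variants are preset:

* `spec_blue()` — genotype fixed, year random: outlier detection and BLUEs
  (estimable accession means $\hat\mu + \hat g_i$);
* `spec_varcomp()` — both random: variance components and heritability;
* `spec_yearcv()` — genotype random, year fixed: per-year coefficients of
  variation.

## REML implementation

`fit_mixed()` maximises the restricted likelihood with average-information
(AI) updates and EM fallback, working throughout on Henderson's mixed-model
equations: the per-iteration cost is a Cholesky factorisation of the
$(p+q)\times(p+q)$ coefficient matrix (a few hundred columns for the designs
used here) plus $O(n)$ bookkeeping, never an $n \times n$ solve. An AI step
is accepted only if it keeps the restricted log-likelihood from decreasing
(with up to five halvings); otherwise the iteration falls back to an EM step,
which is monotone by construction. `method = "em"` forces pure EM, and the
returned `loglik_trace` lets that monotonicity be asserted. The stopping rule
is a relative log-likelihood change below `1e-8` *and* a maximum relative
parameter change below `1e-6`, within 200 iterations.

Numerical choices:

* **Variance floor.** Components are clamped at $10^{-8}$ times the
  phenotypic variance; a floored component is reported with a boundary flag.
  This keeps noiseless and near-noiseless inputs (useful in testing) from
  producing singular systems.
* **Error-variance pooling** (`min_year_n`, default 3). A year with fewer
  records than this cannot support its own variance; such years share one
  pooled stratum. This generalises the occasional manual removal of a
  2-record year, which remains available as `drop_years_below_n` in
  `detect_and_enhance()`.
* **Identifiability.** Fixed factors use treatment coding internally (first
  sorted level as reference), but all reported quantities are estimable
  means, identical under sum-to-zero coding (`coding = "sum"` exists and the
  test suite asserts the invariance).
* **Determinism.** Nothing in fitting is randomised; all internal ordering
  is by sorted accession id and year, so refits are bit-reproducible.
* `reml_loglik()` exposes the exact objective the optimiser maximises, so an
  independent grid search over it is a valid oracle; the test suite also
  checks the objective against a direct dense-matrix implementation and the
  whole fit against `nlme::lme` with per-year variance weights.

## Outlier curation

`detect_and_enhance()` performs exactly one detect–remove–refit pass (the
procedure is two-step, not iterated to convergence):

1. fit `spec_blue()`;
2. standardise each conditional residual by the fitted error SD of its year
   stratum (heteroscedasticity contract: the same raw residual counts for
   less in a noisy year);
3. rescale the standardised residuals robustly:
   $(z - \mathrm{median}(z)) / (1.4826 \cdot \mathrm{MAD}(z))$, where 1.4826
   is the Gaussian consistency constant and the centring uses the observed
   median rather than assuming 0;
4. convert to two-sided standard-normal p-values and flag with the
   step-down Bonferroni–Holm procedure at family-wise level
   $\alpha = 0.05$;
5. remove flagged plots (never correct or impute them) and refit once on the
   enhanced data.

Flagging is done per trait × habit dataset; families are never pooled across
traits. A degenerate spread (numerically zero MAD, as on noiseless data)
scores nothing and flags nothing. `standardize_residuals(fit, studentize =
TRUE)` optionally divides by the SD of the conditional residual itself
(leverage-corrected, from $\mathrm{var}(\hat e) = R - WCW'$); the default
stays with the plain per-stratum SD, the conventional choice for this
procedure. In null simulations at the designs used in the tests the default
gives an empirical family-wise error rate near the nominal 0.05 and the
studentised variant is conservative. Records that the fixed effects fit
exactly — in particular the single plot of a once-regenerated accession —
have conditional residual identically zero and are undetectable by any
residual-based rule; power statements therefore refer to accessions with at
least a few plots.

## Summaries

* **Heritability** (entry-mean repeatability):
  $h^2 = \hat\sigma^2_G / (\hat\sigma^2_G + \bar{\hat\sigma}^2_e / \bar Y)$,
  with $\bar{\hat\sigma}^2_e$ the unweighted mean of the per-year error
  variances and $\bar Y$ the mean number of *distinct* years in which
  accessions were tested (not record counts — duplicate plots do not add
  environments). Reported at 2 decimals.
* **Per-year CV**: $\widehat{cv}_y = \hat\sigma_{e,y} / \widehat{YE}_y$ from
  the year-fixed variant, where $\widehat{YE}_y$ is the estimated year
  *mean* ($\hat\mu$ + year effect). Using the centred year effect instead
  would put a near-zero quantity in the denominator and explode the CV,
  contradicting the interpretation of a coefficient of variation; the choice
  is isolated in `year_cv()`.
* **Year-pair correlations**: Pearson correlation of accession values for
  every pair of years sharing at least `min_overlap = 50` accessions,
  within-year replicates averaged first. Under the additive model the
  expected pair correlation is
  $\sigma^2_G / (\sigma^2_G + \bar\sigma^2_e)$, which the tests exploit.
* **Origin tables**: exact string grouping of the reported collection
  places, descending, with an "Others (k origins)" tail below a rank cutoff
  (default 22) and a Total row; the optional comment-column regrouping
  (e.g. a Soviet-Union group spanning successor states) is applied only
  where the study file provides it.

## Resampling studies

`extract_balanced()` intersects the data down to a complete
accession × year grid. `sample_scenario()` removes years per accession in
three ways: independently at random per accession (S1), in randomly formed
accession clusters that share one random year set (S2, mimicking
regeneration cohorts), or in clusters given by collection origin (S3).
`bias_study()` repeatedly subsamples, refits, and reports the relative bias
$(\hat d - d)/d$ of the genetic and average error variances against the
balanced-grid fit, plus intercept, slope and $R^2$ of the regression of
subsample BLUEs on balanced-grid BLUEs. Keeping all years reproduces the
balanced fit exactly (zero bias, identity regression) — a degenerate-limit
check in the tests. Under S1 the missingness is ignorable and the mean bias
centres on zero; S2/S3 may show bias, and the suite asserts only that the
statistics are computed, not their sign.

`split_half_precision()` splits the *records* (plots) in half at random —
an accession whose only plot lands in one half simply drops out of that
run's correlation — fits BLUEs in both halves and correlates them over the
common accessions. With $k$ plots per accession per half the expected
correlation is approximately
$\sigma^2_G/(\sigma^2_G + \bar\sigma^2_e/k)$, used as a reliability oracle
in the tests, and the correlation increases with simulated heritability.

Randomness policy: every study takes one master seed; run $i$ uses a seed
derived by a fixed counter scheme, so runs are independent and individually
reproducible, and identical seeds give bit-identical results.

## The synthetic-data generator

`simulate_dataset()` draws Gaussian genotype and year effects, per-year
error variances uniform in a range, applies random or cohort-block
missingness, adds duplicate plots at `dup_rate`, and contaminates an
`outlier_rate` fraction of records with a mean shift of `outlier_shift_sd`
error SDs (the gross-error model the curation step targets). The default
preset is "FT-spring-like": mean 60 days, $\sigma^2_G = 27$,
$\sigma^2_Y = 49$, $\sigma^2_{e,y} \in [9, 25]$ — magnitudes typical of
flowering time in a large spring barley collection — with 1% duplicate
plots. The truth record carries every effect, error and flag, so generated
values can be reconstructed exactly.

What the generator emulates: additivity, year-specific error scales,
unbalanced occupancy (including entry-cohort block structure), duplicate
plots, gross errors. What it does not: genotype-by-year interaction (absent
from the model, hence confounded with error), trends or autocorrelation
across years (year effects are i.i.d.), non-Gaussian trait distributions,
and protocol changes mid-series. Passing tests therefore demonstrate
correctness of the machinery and calibration *under the model's own
assumptions*, not robustness to every feature of real historical data.

## Problem sizes used in the checks

The heavier statistical checks run at: 500 null simulations of a
100 × 8 design at occupancy 0.5 for the family-wise error rate; 100
replicates of a 200 × 10 design at occupancy 0.4 for parameter recovery
(mean relative bias of $\hat\sigma^2_G$ and $\hat\sigma^2_Y$ within 5%,
mean $h^2$ within 0.03 of its analytic value); 100 replicates of a complete
100 × 8 grid for outlier power; and balanced 400 × 6 grids for the scenario
structure. These sizes are the package's intended operating envelope —
large enough that asymptotic REML behaviour is visible, small enough that
the entire suite runs in minutes on one core.

## Known limitations

* BLUE standard errors are not reported; the downstream studies only need
  point estimates.
* No pedigree/kinship covariance, spatial adjustment, or multi-trait REML.
* The per-year variance model needs `min_year_n` records per year; sparser
  years are pooled rather than modelled.
* Exact reproduction of flag counts from other REML implementations can
  differ in boundary handling and in which residual the robust rescaling is
  applied to; both choices are documented above and switchable.
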