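---
title: "Polynomial interpolation of sparse 24 h cortisol profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial interpolation of sparse 24 h cortisol profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortinterp)
```

## The problem

Serum and salivary cortisol follow a pronounced 24 h rhythm: a morning
peak around waking, a decline across the day, an evening/night nadir,
and a pre-waking rise. The clinically interesting summary is often the
*24 h total output* — the time integral of concentration over the
admission window — but collecting the dense profiles needed to estimate
it (hourly blood draws, two-hourly saliva) is burdensome. `cortinterp`
implements a pipeline for asking: *how sparsely can one sample a 24 h
cortisol profile and still recover the dense profile, and its 24 h
output, by polynomial interpolation?*

The pipeline has five stages:

1. **Sampling schemes.** Seven canonical schemes over hours 0–24:
   equidistant Q60 (25 samples), Q120 (13), Q180 (9), Q240 (7), Q360
   (5) and two intermittent clinical schedules INT1 = {0, 2, 4, 8, 14,
   24} h and INT2 = {0, 2, 6, 16, 24} h. Q60 (serum) and Q120 (saliva)
   are the densest collected grids and serve as ground truth; every
   other scheme is an exact down-sample of them. Each scheme carries a
   maximum polynomial degree (6, 6, 5, 4, 3, 3, 3) so that a fit always
   retains residual degrees of freedom.
2. **Polynomial validation.** Per profile, ordinary least squares of
   concentration on time scaled to [-1, 1], for every degree from 1 up
   to the scheme cap. Fits are evaluated on themselves (R², RMSE),
   against the ground-truth *data*, and — after interpolation — against
   the ground-truth *model* of the same degree.
3. **Stochastic interpolation.** An alternative-scheme fit predicts the
   missing ground-truth grid values; each filled value receives a
   zero-mean truncated-Gaussian error (truncation at ±1.96 sd) whose
   scale is the fit's residual spread. The injection is repeated 100
   times with per-iteration seeds derived from one master seed; the R²
   and RMSE distributions are summarized by their kernel-density peaks,
   and the iteration nearest the peak pair (after per-axis
   standardization) is the *optimal* iteration, reproducible exactly
   from its stored seed.
4. **Output estimation and statistics.** 24 h output is the trapezoidal
   integral over [0, 1440] minutes (μg·min/dl). Interpolated outputs are
   compared with observed ground-truth outputs by paired two one-sided
   tests (TOST) on the log scale with a region of similarity ε = 0.25;
   ground-truth outputs are compared across specimen and condition by
   two-way ANOVA.
5. **Degree selection.** An explicit rule (below) picks the most
   parsimonious polynomial degree per specimen.

## The synthetic cohort generator

No public data accompany this design, so the package ships a seeded
generator (`generate_cohort()`) that emulates the study: N subjects
(default 8) × two conditions (rest, exercise) × two specimens, serum on
Q60 and saliva on Q120.

The deterministic serum curve is built from **zero-mean components over
the window**, expressed directly in the polynomial domain so that the
trend's degree content is exactly controlled:

- a *day–night contrast* term, `day_night_amp` × P₂(x) with
  x = (t − 720)/720 — high around both 06:00 endpoints, nadir in the
  evening (default amplitude 4 μg/dl);
- a *morning/evening asymmetry* term, `asymmetry_amp` × (−P₃(x)) —
  raises the morning peak above the pre-waking rise (default 1.8
  μg/dl); this term carries the curve's cubic content;
- a small *semidiurnal ripple*, a 12 h cosine (default 0.35 μg/dl),
  representing secondary structure beyond the low-order trend;
- under the exercise condition, a Gaussian transient centred on the
  10:00 bout (default height 2 μg/dl, sd 180 min), covering the
  anticipatory rise and the post-exercise elevation. The modest height
  is consistent with 24 h outputs that barely differ between rest and
  exercise days.

Each subject scales the bracketed rhythm by a log-normal effect
(log-sd 0.15). Saliva is `saliva_fraction` (default 0.06) of the serum
curve with the asymmetry, ripple and transient damped by `saliva_atten`
(default 0.2), reflecting the smoother, less complex trends seen in
salivary measurements; `saliva_atten = 1` recovers exact
proportionality. Channel noise is additive zero-mean Gaussian (serum
1.2, saliva 0.06 μg/dl — about 15% CV, covering assay error plus
pulsatile scatter about the smooth trend), floored at zero.

Why a polynomial-domain trend rather than, say, a plain two-harmonic
cosinor? A full-period shifted cosine spreads its polynomial content
across many degrees (its Chebyshev coefficients are Bessel-function
weighted, with comparable degree-3 and degree-5 content), so no
parameterization of such a family produces a trend whose information is
cleanly exhausted at a known degree. For a *validation* generator that
is a liability: one wants to know exactly which degree the data support.
With the Legendre-type construction the rest-day serum trend is, by
construction, quadratic-plus-cubic with only the small ripple beyond
degree 3, and the saliva trend is quadratic-dominant — so the generator
has a known answer (serum 3, saliva 2) against which the selection
machinery can be tested. Because P₂, P₃ and the 12 h cosine all
integrate to zero over the window, the rest-day output is exactly
1440 × mesor × subject effect, a convenient analytic anchor used in the
tests.

Defaults were calibrated once so that 24 h outputs land near
10,000–11,500 μg·min/dl (serum) and 500–700 (saliva), the magnitudes
typical of healthy adult males, and are not revisited by any test.

What the generator deliberately does **not** model: pulsatile
(ultradian) secretory bursts as a correlated process (pulsatility is
subsumed into independent Gaussian noise), binding-protein kinetics,
assay-specific heteroscedasticity, missing or irregular clinical
timestamps, and any fractal/long-memory dynamics. Passing tests
therefore demonstrate that the *machinery* behaves as specified on
smooth rhythms with symmetric noise — not that real cortisol is
polynomial.

## Error injection: reading "Gaussian within the residual 95% CI"

The stochastic interpolation draws zero-mean Gaussian errors bounded by
the residuals' 95% confidence range. The default (`"truncnorm"`) is a
rejection-sampled Gaussian with sd equal to the residual spread,
truncated at ±1.96 sd; a truncated standard Gaussian at ±1.96 has sd
≈ 0.95, which the tests check against the closed form. Two alternative
readings are available behind `method=`: `"uniform"` (uniform on the
same interval) and `"empirical"` (truncation at the 2.5%/97.5% residual
quantiles).

One numerical subtlety matters. The *scale* used when filling values
from a fit is the unbiased residual standard error
√(RSS/(n − p)) stored on the fit (`resid_scale`), not the residual
sample sd. The sample sd shrinks mechanically by √((n − p)/(n − 1)) as
parameters are added — on a 5-point grid a cubic fit's residual sample
sd underestimates the error scale by nearly 30% — which would make
interpolation error appear to improve with degree regardless of the
data. The standalone `draw_error(residuals)` helper, which only sees a
residual vector, uses the sample sd.

Per-iteration seeds are drawn from one master seed, so a single integer
reproduces an entire ensemble bit-for-bit, and the optimal iteration is
regenerated (never stored) via its seed; `regenerate_optimal()`
fingerprints the inputs and refuses mismatches.

## Ensemble metrics

By default the interpolated profile is compared against the
*ground-truth model of the same degree* (`reference = "model"`), i.e.
the polynomial fitted to the dense data; `reference = "data"` switches
to the dense observations. Metrics are computed over the full target
grid by default (`metric_points = "interpolated"` restricts them to the
filled points). The KDE peak uses a Gaussian kernel with Silverman's
rule-of-thumb bandwidth on a 512-point grid spanning the data extended
by three bandwidths; ties break toward the smaller value, and a
zero-variance distribution returns its common value.

## The degree-selection rule

The published reasoning — "gains in fit are minimal beyond degree d,
and interpolation error has converged" — is codified in
`select_optimal_degree()` as the smallest degree d such that

- **(a)** the mean R² gain (alternative model vs ground-truth data)
  from d to d + 1 is below `r2_plateau` (default 0.02), and
- **(b)** the mean interpolation RMSE at d is within `rmse_tol`
  (default 5%) of the minimum across degrees.

Three aggregation choices make this rule stable, all visible in the
code and worth recording:

- surfaces are averaged *per scheme first* (pooling subjects and
  conditions), then across schemes, because sparser schemes never reach
  high degrees and naive pooling would confound degree effects with
  scheme composition;
- each scheme's RMSE curve is normalized by its own minimum before
  averaging, for the same reason;
- condition (b) uses the across-iteration *mean* RMSE over the
  *interpolated points only*. The KDE peak is retained as the reported
  per-ensemble summary, but as a selection statistic its sampling
  jitter (5–10% per profile) is of the same order as the 5% tolerance;
  and full-grid RMSE is biased across degrees because pass-through
  observed points are compared against a same-degree reference model
  that hugs its own data more tightly as the degree grows.

At the largest degree any scheme admits, the gain is defined as zero.
If no degree satisfies both conditions, the rule falls back to the
relative-RMSE argmin with a warning.

```{r selection, eval = FALSE}
run <- run_pipeline(run_config(cohort = cohort_config(seed = 1),
                               master_seed = 1001))
select_optimal_degree(run, "serum")   # 3
select_optimal_degree(run, "saliva")  # 2
```

## Statistics

`total_output()` integrates by the trapezoidal rule with time in
minutes (the convention that reproduces outputs of ~7.5 μg/dl × 1440
min ≈ 11,000 μg·min/dl); hour-based and simple-sum variants exist via
`rule=`. `tost_paired()` forms paired differences of log outputs,
tests the mean against ±ε (default 0.25) with two one-sided paired
t-tests at α = 0.05, and reports the conventional 90% (1 − 2α) CI; the
decision "both p < α" is algebraically identical to "CI strictly inside
(−ε, ε)", and the tests assert this equivalence on randomized
instances. ε is interpreted as raw bounds on the mean log difference
(≈ ±25% ratios); a standardized-bounds mode (`bounds = "smd"`) exists
because some TOST conventions scale ε by the sd. Cohen's d is the
magnitude of mean/sd of the paired log differences. `anova_outputs()`
is a fixed-effects two-way ANOVA (specimen + condition, interaction
optional) on the raw output scale; fully degenerate inputs (zero effect
and residual variance) report F = 0, p = 1 rather than 0/0.

With fewer than three subjects the pipeline skips the TOST stage (a
paired test needs n ≥ 3) and returns an empty equivalence table.

## Degenerate inputs and edge conventions

- R² of a zero-variance reference is defined as 0 with a warning; RMSE
  stays informative.
- `fit_polynomial()` requires at least degree + 2 points, so residuals
  never vanish by saturation.
- All-zero residuals make `draw_error()` return exactly 0; a noiseless
  polynomial truth therefore collapses every ensemble iteration to
  R² = 1, RMSE = 0.
- Grid membership is exact integer-minute matching: all canonical grids
  are whole hours, and a profile that lacks a scheme time (saliva Q120
  asked for Q180's hour 3) is refused with the missing times named.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
the study-sized cohort (8 subjects, 100 iterations per ensemble — 592
ensembles per run); one run takes a few seconds, and the 20-cohort
recovery check about 80 seconds on one core. These sizes are the study
conditions themselves, not reductions.

## Known limitations

- The generator's answer (serum 3, saliva 2) is built in by
  construction; the recovery tests validate the selection machinery,
  not the physiological claim.
- The truncated-Gaussian error model is one literal reading of
  "Gaussian values within the 95% confidence interval of the
  residuals"; the alternatives are provided but untested against any
  external reference.
- Interpolation error is injected independently per time point; real
  cortisol deviations are autocorrelated, so ensemble spreads here are,
  if anything, optimistic.
- The TOST CI level (90%) and the integration rule (trapezoid, minutes)
  are conventions; both are configurable and echoed into run manifests.
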