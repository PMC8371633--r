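---
title: "Estimating anaerobic capacity from treadmill running time trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating anaerobic capacity from treadmill running time trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anaerocap)
```

## The problem

Aerobic energy turnover during exercise can be measured directly from gas
exchange, but anaerobic energy release cannot. The accumulated-oxygen-deficit
family of methods estimates it indirectly: a *demand model*, calibrated on
submaximal exercise where the effort is fully aerobic, extrapolates the total
metabolic rate (MR) an athlete *requires* at supramaximal speeds; subtracting
the *measured* aerobic MR leaves the instantaneous anaerobic MR, and its time
integral over a maximal effort is the anaerobic capacity (AnC, kJ·kg⁻¹).

`anaerocap` implements this pipeline for 4-min treadmill running time trials
(TTs), together with the between-model agreement statistics needed to judge
whether different demand models can be used interchangeably (they cannot, and
quantifying *how much* they disagree is the point).

## From gas exchange to energy

All conversions run through a Weir-type equation,

$$\mathrm{MR}\;[\mathrm{W\,kg^{-1}}] =
  \frac{4.184\,\dot{V}O_2\,(1.1\,\mathrm{RER} + 3.9)}{60},$$

with $\dot{V}O_2$ in mL·kg⁻¹·min⁻¹. The RER term tracks the substrate mix;
above 1.00 the excess CO₂ is non-metabolic, so RER is clamped at 1.00
everywhere (`metabolic_rate()`), and peak aerobic MR assumes RER = 1.00
(100% carbohydrate). Gross energy cost (GEC, J·kg⁻¹·m⁻¹) is MR divided by
speed; net energy cost subtracts the standing baseline MR first. Anaerobic
energy converts to an accumulated O₂ deficit at 0.047801 mL O₂ per joule.

## The demand models

Nine models are registered (`anc_models()`); each answers "what total MR does
speed $v$ require?"

* **5+Y_LIN / 5-Y_LIN** — OLS regression of stage MR on stage speed over the
  five submaximal stages, with (`+Y`) or without (`-Y`) the standing-baseline
  MR appended as one extra, equally weighted observation at $v = 0$. The
  intercept is always *modeled*, never forced: with the baseline included the
  fit need not pass through it.
* **GEC_AVG / GEC_LAST** — fixed-cost models, required MR $= \mathrm{GEC}
  \cdot v$, with GEC the mean of the five stage costs or the cost of the
  fastest stage. Equivalent to a regression with a zero intercept.
* **5±Y_POL** — second-degree polynomials (raw, non-centered speed; a
  condition-number warning guards the design matrix), probing curvilinearity.
* **4/3/2-Y_LIN** — linear fits on the highest-speed stages only, baseline
  excluded. Whether reduced-stage models should carry the baseline point is
  not prescribed anywhere; their `-Y` naming is taken at face value and they
  exclude it.

For a linear model with intercept $b$, the implied GEC at speed $v$ is
$b/v + s$: strictly decreasing in $v$ when $b > 0$. This is the mechanism
behind the central finding the package reproduces — anchoring the regression
at a standing baseline that sits *above* the extrapolated submaximal line
flattens the slope, lowers the required MR at TT speeds, and can depress the
AnC estimate by roughly a quarter.

Regression diagnostics follow the usual conventions: $r^2$ from the fit, SEE
$= \sqrt{\mathrm{SSE}/(n-p)}$ with $p$ the number of coefficients (residual
degrees of freedom; an exact fit with $n = p$ reports $r^2 = 1$ and an
undefined SEE). Extrapolation beyond the fitted speed range is the method
itself, but every result carries an `extrapolated` flag and the fitted range.

## The time-trial pipeline

Treadmill and gas-exchange records are linearly interpolated onto a 1-Hz
grid (`resample_to_1hz()`; edges held constant, no extrapolation — the same
rule is applied to both signals since nothing distinguishes them at this
step). Submaximal stages are averaged over 2:50–3:50 of each 4-min stage;
VO2peak is the highest 30-s moving average during the TT and peak heart rate
the highest 5-s average (`rolling_peak()`). The baseline averaging window is
configurable (`study_config(baseline_window = )`, default 60 s — protocols
record up to 2 min of standing rest but conventionally average the final
minute).

`compute_anc()` then evaluates the demand model at each second's speed,
subtracts the measured aerobic MR (instantaneous RER, clamped at 1.00, so
sub-1.00 seconds keep their measured substrate mix), and integrates by the
rectangle rule with $\mathrm{d}t = 1$ s. Negative instantaneous anaerobic MR
is *retained* — the result is a net deficit — and the number of negative
seconds is reported so suspicious decompositions are visible. No
mixing-chamber lag model is imposed; an optional fixed time shift
(`lag_shift`) is exposed, default 0 s.

## Agreement statistics

`agreement_report()` runs the battery on the participants × models AnC
matrix:

* **Bland–Altman**: mean difference, SD of differences, 95% limits of
  agreement ($\pm 1.96$ SD), and the paired $t$ test.
* **Typical error**: $\mathrm{SD}(d)/\sqrt{2}$ — the standard within-pair
  error convention.
* **Hedges $g_{av}$**: mean difference over the average of the two condition
  SDs, times the small-sample correction $J = 1 - 3/(4(n-1)-1)$.
* **Repeated-measures ANOVA**: one-way within-subjects decomposition.
  Sphericity is tested with Mauchly's test (base R's `mauchly.test`); the
  Greenhouse–Geisser correction is applied when Mauchly rejects at 0.05
  *and* $\hat\varepsilon \le 0.75$ — the $\varepsilon$ rule is conventional
  for this design and the Mauchly gate keeps near-spherical data on exact
  df. $\eta^2$ is computed against the *total* sum of squares including the
  between-subject stratum: with highly correlated model columns most
  variance is between participants, which is why published effect sizes of
  this design look small (≈0.06–0.2) next to partial $\eta^2$.
* **ICC / SEM**: ICC $= (\mathrm{BMS} - \mathrm{WMS})/\mathrm{BMS}$ from the
  repeated-measures mean squares; SEM $= \mathrm{SD_{pooled}}
  \sqrt{1 - \mathrm{ICC}}$ with $\mathrm{SD_{pooled}}$ the column SDs pooled
  in quadrature (the SD term is not prescribed by convention; the pooled
  model-column SD is the natural scale for a between-model SEM).
* Bonferroni-adjusted pairwise paired $t$ tests, $m = k(k-1)/2$ comparisons.

All tests are two-sided at $\alpha = 0.05$. Normality inspection is out of
scope.

## The synthetic-participant generator

Because raw cohort data of this kind are not publicly deposited, validation
runs on synthetic participants with *known* true AnC (`generate_cohort()`).
The generator emulates the study conditions:

* Participant-level truth drawn from the cohort's distributions: GEC
  4.39 ± 0.29 J·kg⁻¹·m⁻¹ (anchored at the mid-submaximal speed 3.13 m·s⁻¹),
  VO2peak 58 ± 6 mL·kg⁻¹·min⁻¹, standing baseline MR 1.8 ± 0.2 W·kg⁻¹.
* The demand-line intercept is a *separate* parameter from the standing MR
  (default 0.2 ± 0.5 W·kg⁻¹): standing still is not running, and the gap
  between the standing MR and the extrapolated submaximal line is exactly
  the mechanism that biases baseline-anchored models. Setting
  `baseline_mr = demand_intercept` puts the baseline on the line and makes
  every regression model exactly recoverable — the configuration the
  recovery tests use.
* Five stages at 57–79% of peak aerobic MR, stage RER interpolating
  0.90 → 0.95; VO2 is the Weir-equation inversion of the true MR plus
  Gaussian noise (SD 0.45 mL·kg⁻¹·min⁻¹, which yields a stage-to-stage GEC
  SD near 0.05 J·kg⁻¹·m⁻¹ — the within-participant scatter is not published,
  so this is a plausibility choice, flagged as such).
* The TT speed controller accelerates at ≤ 0.50 and decelerates at ≤ 0.40
  km·h⁻¹·s⁻¹ from a start speed of the final stage minus 2 km·h⁻¹, toward a
  target where demand is 102% of peak (the supramaximal intensity the
  4-min-TT literature reports), with a small sinusoidal drift and a 15-s
  end-spurt to exercise both controller limits.
* Aerobic on-kinetics are a single mono-exponential (τ = 25 ± 3 s) toward
  the instantaneous ceiling min(required MR, peak MR) — the simplest
  mechanism consistent with observed ~98–102% supramaximal requirements; no
  slow component, no cardiodynamic delay. TT RER is fixed at 1.00.

True AnC is the integral of (true required − true aerobic)/1000 by
construction, so estimator bias is measurable exactly. What passing these
tests shows is that the *computational* pipeline is faithful; the generator
deliberately omits breath-by-breath noise structure, analyzer drift, VO2
slow components and biomechanical speed–cost individuality, so it cannot
certify the physiological validity of any demand model on real athletes.

## Worked-example construction

The group-mean worked example (README and `scripts/acceptance.R`) feeds the
published stage table (speeds 2.60–3.66 m·s⁻¹, MR 11.5–16.1 W·kg⁻¹, baseline
1.8 W·kg⁻¹) through the fitting code. One subtlety: the relative AnC
contrast between the baseline-anchored model and the other three requires
the aerobic energy integral of the TT, which group means do not determine.
The package computes the *required-energy difference* between models from
its own fits (0.18 kJ·kg⁻¹ over a 240-s TT at 4.7 m·s⁻¹) and anchors the
shared aerobic integral with the single published baseline-anchored AnC
(0.54 kJ·kg⁻¹, itself checked independently through the O₂-deficit
conversion); the contrast is then a genuine prediction of the other three
models' AnC. Group-mean fits also differ slightly from means of individual
fits (a ratio-of-means vs mean-of-ratios gap), which is why e.g. the
group-mean slope 3.86 sits beside a published individual-mean 3.85.

## Numerical choices and degenerate inputs

* OLS via `lm()`; coefficients verified against a normal-equations oracle to
  1e-10 in the tests.
* Underdetermined fits (fewer points than coefficients) and zero speed
  variance raise errors; exact fits report SEE = NA rather than 0/0.
* `rolling_peak` uses a cumulative-sum scan, verified against the O(n·w)
  brute-force oracle.
* All-identical ANOVA columns report F = 0, p = 1 rather than 0/0; a zero
  between-subjects mean square flags the ICC as undefined.
* Greenhouse–Geisser ε is computed from the double-centered condition
  covariance and is 1 exactly at k = 2.
* File writes are atomic (temp + rename); all randomness flows through one
  seeded generator, and reproducibility (same seed ⇒ identical cohort and
  byte-identical results) is part of the contract.
* Problem sizes in the shipped tests: cohorts of 15 participants, 200
  replicate cohorts for the ordering study, 500 participants for
  distributional checks, 240-s TTs throughout — small enough to run the
  whole suite in well under a minute while leaving Monte-Carlo error far
  below the asserted tolerances.

## Known limitations

* The package quantifies *between-model* disagreement; it cannot say which
  model is closest to true physiology on real data (on synthetic linear
  truths, the regression models are unbiased by construction).
* No protein oxidation correction, no fat/carbohydrate partitioning beyond
  the RER term, no grade correction (the 1% incline is metadata).
* Mixing-chamber dynamics are reduced to an optional constant shift.
* Reduced-stage and polynomial models inherit all the fragility of
  extrapolating few-point fits; the SEE and extrapolation flags make this
  visible but do not repair it.
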