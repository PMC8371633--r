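# anaerocap

Anaerobic capacity (AnC) estimation for maximal treadmill running time
trials, and the statistics to judge whether different ways of estimating it
agree.

## The problem

During a maximal 4-min run, part of the energy comes from anaerobic
metabolism, which gas exchange cannot measure directly. The
accumulated-oxygen-deficit approach estimates it indirectly:

1. Convert gas exchange to metabolic rate (MR, W·kg⁻¹) with a Weir-type
   equation, `MR = 4.184·V̇O₂·(1.1·RER + 3.9)/60`, RER clamped at 1.00.
2. Calibrate a **demand model** on five submaximal stages: either an OLS
   regression of MR on speed — with (`5+Y_LIN`) or without (`5-Y_LIN`) the
   standing-baseline MR as an extra point at zero speed — or a fixed gross
   energy cost (GEC, J·kg⁻¹·m⁻¹) times speed (`GEC_AVG`, `GEC_LAST`).
   Quadratic and reduced-stage variants are also registered
   (`anc_models()`).
3. During the time trial, evaluate the required MR at each second's speed,
   subtract the measured aerobic MR, and integrate the difference:
   `AnC = Σ(MR_required − MR_aerobic)·Δt / 1000` kJ·kg⁻¹, convertible to an
   O₂ deficit at 0.047801 mL·J⁻¹.

The choice of demand model changes the answer substantially — a regression
anchored at a standing baseline that lies above the extrapolated submaximal
line yields a flatter slope, a lower supramaximal requirement, and roughly a
quarter less estimated AnC. The package reproduces that effect and
quantifies between-model agreement with Bland–Altman limits of agreement,
typical error, Hedges g\_av, repeated-measures ANOVA
(Greenhouse–Geisser-corrected), and the ICC-based standard error of
measurement. A synthetic-participant generator with known true AnC supports
validation throughout. It is aimed at exercise physiologists analyzing
treadmill TT data and at methodologists comparing oxygen-deficit variants.

## Worked example

Group-mean submaximal data (five stages, 2.60–3.66 m·s⁻¹, plus a standing
baseline of 1.8 W·kg⁻¹) and the baseline-anchored linear model:

```r
library(anaerocap)
st <- stage_table(speed = c(2.60, 2.87, 3.13, 3.40, 3.66),
                  mr = c(11.5, 12.6, 13.7, 14.9, 16.1))
bl <- baseline_summary(mr_bl = 1.8)
m <- demand_model("5+Y_LIN", st, bl)
m
#> Demand model 5+Y_LIN: MR = 1.692 + 3.860*v (linear, 5 stages + baseline point)
#>   r2 = 0.9986, SEE = 0.214 W/kg, fitted speeds 2.60-3.66 m/s
required_mr(m, 4.7)            # 19.83 W/kg at the mean TT speed,
100 * required_mr(m, 4.7) / peak_aerobic_mr(58)  # i.e. 98% of peak
```

The modeled Y-intercept (1.69 W·kg⁻¹) sits *below* the measured standing MR
(1.8), and the requirement at the TT speed is only 98% of the peak aerobic
MR — the signature underestimation of baseline-anchored models.

A synthetic cohort end-to-end:

```r
coh <- generate_cohort(15, seed = 1)
pl <- run_pipeline(coh, study_config())
pl
#> AnC pipeline: 15 participants x 4 models
#>     model mean AnC (kJ/kg)
#>   5-Y_LIN            0.501
#>   5+Y_LIN            0.358
#>   GEC_AVG            0.561
#>  GEC_LAST            0.533
#> Omnibus: F(1.15, 16.08) = 36.71, p = 9.458e-06, eta^2 = 0.257, SEM = 0.057
```

The baseline-anchored model gives the lowest AnC of the four; the
Greenhouse–Geisser-corrected omnibus test (note the fractional degrees of
freedom) rejects interchangeability, and the SEM expresses the
between-model error on the AnC scale. Pairwise:

```r
bland_altman(pl$results$anc[pl$results$model_id == "5+Y_LIN"],
             pl$results$anc[pl$results$model_id == "5-Y_LIN"])
#> Bland-Altman (n = 15): mean diff -0.143 [LoA -0.365, 0.078]
#>   typical error 0.080, paired t = -4.91 (p = 0.0002299), Hedges g_av = -0.94
```

`write_fixture()` / `read_stages()` / `read_tt()` move cohorts through plain
CSV schemas, and `inst/scripts/anc_pipeline.R` wraps simulation and analysis
for shell use.

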