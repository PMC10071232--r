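# chromadoe

A desk-scale workbench for reversed-phase liquid-chromatography (UPLC/HPLC)
method development and validation, written for analytical chemists who want
the statistical half of that workflow — factorial optimization, validation
statistics, and greenness scoring — as tested, reusable code rather than a
spreadsheet. Its running example is the simultaneous assay of four antiviral
drugs (oseltamivir phosphate, dexamethasone, daclatasvir, remdesivir); since
instrument chromatograms are not shippable, a peak simulator with known
ground truth takes the instrument's place, so every estimator in the chain
can be verified against the truth that generated its input.

## What it computes

**Chromatogram simulation.** Peaks are exponentially modified Gaussians
(EMG): a Gaussian of width σ convolved with an exponential tail of constant
τ, the standard model for tailed chromatographic peaks. Retention and
tailing respond linearly (in coded units) to three method factors: methanol
% (A), ammonium acetate concentration (B), and flow rate (C).

**System suitability** from measured peak geometry:

- capacity factor k′ = (t_R − t_m) / t_m
- resolution R_s = 2 (t_R2 − t_R1) / (W_b1 + W_b2)
- tailing factor T = W_5% / 2f
- theoretical plates N = 5.54 (t_R / W_50%)²

**Factorial design.** The 2³ full factorial in standard order; effects as
signed contrasts (equivalently, exact least squares on the saturated 8 × 8
model matrix); Lenth's pseudo-standard-error significance screen for
unreplicated designs; coded ↔ natural-unit coefficient conversion; and the
resulting prediction equations.

**Desirability optimization.** Derringer ramps d ∈ [0, 1] per response,
composite D = (∏ dᵢ^wᵢ)^(1/Σwᵢ), maximized over the design region by a
grid scan plus simplex refinement.

**Validation statistics.** Calibration lines with the full dispersion set
(S_a, S_b, S_y/x), LOD/LOQ by both 3.3σ/S–10σ/S and signal-to-noise (S/N =
2H/h) conventions, recovery/RSD/relative-error summaries, classic and
instrumental standard addition (content = intercept/slope), slope-ratio
solution stability (regress 100·S_day/S_0 on day, solve for the 102%
bound), one-way ANOVA and t/F equivalence tests, and Eco-scale / AGREE
greenness scores.

## Worked example

Simulate the eight factorial runs, estimate effects, and optimize:

```r
library(chromadoe)
study <- simulate_doe_study()   # default ground truth, no noise
round(study[, c("methanol_pct", "aa_conc", "flow_rate",
                "kprime_ostp", "tailing_ostp", "rs_rem")], 3)
#>   methanol_pct aa_conc flow_rate kprime_ostp tailing_ostp rs_rem
#> 1           73       5      0.03       0.758        1.934  2.681
#> 2           77       5      0.03       0.563        1.934  2.534
#> ...
#> 8           77      20      0.07       0.672        1.467  1.405
```

All 24 responses sit inside the ranges reported for the real separation
(k′ 0.48–0.91, T 1.30–2.30, R_s 1.39–2.83). Buffer concentration dominates
resolution, with a negative effect:

```r
fit <- estimate_effects(study, "rs_rem")
fit
#> 2^3 full factorial fit for `rs_rem`
#>                   A        B        C     AB     AC     BC    ABC
#> effect     -0.14722 -0.78507 -0.34349 -2e-05 -2e-05 -2e-05 -2e-05

fits <- list(kprime_ostp = estimate_effects(study, "kprime_ostp"),
             tailing_ostp = estimate_effects(study, "tailing_ostp"),
             rs_rem = fit)
optimize_settings(fits, uplc_goals())
#> <desirability_optimum>
#>  methanol_pct  aa_conc flow_rate
#>            73 15.86762      0.03
#> composite D = 0.5387 (d: kprime_ostp=0.568, tailing_ostp=0.674, rs_rem=0.408)
```

Validation statistics work directly from printed report numbers. The
oseltamivir low-range calibration (intercept SD 55.290, slope 80.859) gives
the published detection limits, and the day-indexed slope percentages give
the admissible freezer storage:

```r
lod_loq_sigma(sigma = 55.290, slope = 80.859)
#> <sensitivity_limits> (sigma_slope) LOD = 2.256, LOQ = 6.838   # ng/mL

s <- to_ratio_series(c(0, 7, 8), c(80.859, 80.993, 82.002))
storage_period(s)
#> <stability_estimate> 17.247 days to the 102% bound (drift up, 0.1203 %/day)

eco_scale(uplc_method_inventory())
#> <eco_scale_score> 92 (100 - 8 penalty points) - excellent green analysis
```

`run_pipeline(seed = 1)` chains all of the above (simulate → suitability →
effects → optimize → calibrate → standard addition → stability → greenness)
into one report object, optionally written as JSON + CSV.

## Package layout

- `R/emg.R`, `R/synthetic-data.R` — EMG peaks, traces, study generators
- `R/peak-metrics.R` — detection, geometry, system suitability
- `R/doe.R`, `R/desirability.R` — factorial analysis and optimization
- `R/calibration.R`, `R/standard-addition.R`, `R/stability.R` — validation
- `R/method-comparison.R`, `R/greenness.R`, `R/workbench.R` — equivalence
  statistics, greenness scores, dosage-form arithmetic, orchestration
- `vignettes/method-workbench.Rmd` — models, assumptions, design choices
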