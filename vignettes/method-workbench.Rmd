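---
title: "A simulated workbench for chromatographic method development and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A simulated workbench for chromatographic method development and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromadoe)
```

## The problem

Developing a liquid-chromatography assay for several co-administered drugs
means jointly tuning the mobile-phase composition, buffer concentration,
and flow rate until every peak retains adequately (capacity factor k′ above
0.5), stays symmetric (tailing factor T between 0.8 and 2), and separates
from its neighbour (resolution R\_s above 1.5) — and then validating the
result: linearity, detection limits, accuracy, selectivity against
excipients, solution stability, and environmental footprint. This package
implements the statistical side of that workflow end to end. Because raw
instrument data cannot travel with the code, a chromatogram simulator with
declared ground truth replaces the instrument, and every estimator is
tested against the truth that generated its input.

## The peak model

Peaks are exponentially modified Gaussians (EMG): the convolution of a
Gaussian of standard deviation $\sigma$ (min) with a one-sided exponential
decay of time constant $\tau \ge 0$ (min),

$$h(t) = \frac{A}{2\tau}\exp\!\left(\frac{\sigma^2}{2\tau^2} -
\frac{t-\mu}{\tau}\right)\operatorname{erfc}\!\left(\frac{1}{\sqrt 2}
\left(\frac{\sigma}{\tau} - \frac{t-\mu}{\sigma}\right)\right),$$

which integrates to the area $A$ and degenerates continuously to a Gaussian
as $\tau \to 0$. An EMG rather than a pure Gaussian is essential here: the
tailing factors the workflow must reproduce reach well above 2, which a
symmetric shape cannot express; $\tau$ is the tailing dial. Numerically the
amplitude is evaluated through the scaled complementary error function on
the leading side and the direct form on the trailing side, so it is finite
at any distance from the apex (`emg_signal()` is tested against a
brute-force numerical convolution).

## Ground truth and what the simulator does (not) emulate

`uplc_truth()` declares four peaks. Retention times are linear in the coded
factors — methanol % (A), ammonium acetate (B), flow rate (C) — with a
common negative methanol coefficient, the smallest model consistent with a
two-level factorial analysis and with eluent-strength physics (all peaks
move earlier as the eluent strengthens). The first peak's $\tau$ falls with
B (buffer masks free silanols, so tailing improves), and the gap between
the last two peaks narrows with B and C (resolution falls). With these
defaults and zero noise, all 24 factorial responses land inside the ranges
reported for the real separation: k′ 0.48–0.91, T 1.30–2.30, R\_s
1.39–2.83.

Two parameters are declared rather than inferred, because a printed report
never states them: the dead time (default $t_m = 4.10$ min, consistent with
the published k′ at the published retention times) and the detector scale
(peak areas near $5\times10^4$ response units·min). Sampling defaults to
10 Hz over 12 min, covering the 9.5-min run with ~26 points per $\sigma$.
Noise is white and Gaussian on the trace; there is no baseline drift,
detector nonlinearity, gradient elution, or column-temperature term. A
passing test suite therefore certifies the estimators, not the instrument:
real traces add baseline wander and correlated noise that the baseline-zero
assumption in `detect_and_measure()` does not model.

The spec-level type for a peak carries scalar $\sigma$/$\tau$; here
`retention` and `tau` optionally take coded coefficient vectors, because a
tailing factor that varies across the design (as the reported 1.30–2.30
range requires) is impossible with a constant $\tau$.

## Measuring peaks

`detect_and_measure()` finds strict local maxima above a threshold
(fraction of the global maximum, default 5%), refines each apex with a
three-point parabola (so retention is far more precise than the grid step),
and measures widths at 50% and 5% of apex height by linear interpolation
between bracketing samples. Crossing searches never pass the valley
separating two peaks; an unreached crossing is `NA` rather than a wrong
number, and shoulder maxima merge into their parent peak when the valley
between them stays above half the lower apex. Ties on plateau samples
resolve to the outermost crossing. The baseline is taken as zero because
simulated traces are baseline-free by construction; no baseline estimator
is implemented.

Two conventions deserve a note:

* **Plate number.** The half-height form $N = 5.54\,(t_R/W_{50})^2$ is
  used. The unsquared variant sometimes seen in print is dimensionally
  wrong and inconsistent with the plate counts reported for this
  separation (N ≈ 8600 at $t_R$ = 6.3 min implies $W_{50} \approx 0.16$ min
  only under the squared form).
* **Resolution width.** The baseline width entering R\_s is the tangent
  width, computed as $1.699\,W_{50}$ — exact for a Gaussian ($4\sigma =
  1.699 \times 2.355\sigma$) and a good approximation for the mild tails
  here, since the defining report does not state which width it used.

## Factorial analysis

`build_design()` enumerates the $2^3$ runs in standard (Yates) order; run
randomization is not modelled (no run-order information exists to emulate).
Effects are signed contrasts, identical to least squares on the orthogonal
saturated model matrix — the test suite checks this equivalence to machine
precision — and responses are analysed untransformed. Natural-unit
("uncoded") coefficients are produced by an exact linear solve on the
natural-unit polynomial basis rather than symbolic expansion; both forms
predict identically everywhere, which is also tested.

Significance on a saturated, unreplicated design needs an effect-based
error estimate; Lenth's pseudo standard error is the de-facto standard:
$s_0 = 1.5\,\mathrm{med}|e|$, $\mathrm{PSE} = 1.5\,\mathrm{med}\{|e| :
|e| < 2.5 s_0\}$, margin of error $t_{1-\alpha/2,\,m/3}\,\mathrm{PSE}$.
With many exactly-zero effects the median degenerates and the function
says so rather than inventing a scale.

## Desirability optimization

Each response gets a Derringer ramp $d \in [0,1]$ (one-sided for
maximize/minimize, tent-shaped for target; the importance weight is both
ramp exponent and geometric-mean weight, range 0.1–10, default 1), and the
composite $D = (\prod d_i^{w_i})^{1/\sum w_i}$ is maximized over the design
region by a deterministic $41^3$ grid scan followed by Nelder–Mead
refinement clamped to the bounds. Near-ties on the grid break to the lowest
flow rate, then the lowest methanol % — the solvent-frugal choice — and the
refined optimum is accepted only if it improves $D$. The default goals
encode the published acceptance limits (k′ maximized past 0.5, T targeted
inside [0.8, 2], R\_s maximized past 1.5); whether the original optimizer
treated k′ and R\_s as "maximize" or "target" goals is not recorded, and
both are expressible through `response_goal()`. The optimizer is tested
against a $101^3$ dense-grid oracle on random interaction surfaces
(agreement within $10^{-3}$ in $D$).

## Validation statistics

* **Calibration** is unweighted ordinary least squares (no weighting scheme
  is on record), with $S_{y/x} = \sqrt{SSE/(n-2)}$, $S_b = S_{y/x} /
  \sqrt{S_{xx}}$, $S_a = S_{y/x}\sqrt{\sum x^2 / (n S_{xx})}$. Two-point
  fits return the line with dispersion statistics flagged `NA`.
* **Detection limits**: $\mathrm{LOD} = 3.3\sigma/S$, $\mathrm{LOQ} =
  10\sigma/S$ (their ratio is exactly $10/3.3$ by construction), and a
  signal-to-noise route using the pharmacopoeial $S/N = 2H/h$ with $h$ the
  peak-to-peak noise in a stated blank window — the defining report names
  the 3:1 and 10:1 ratios but not the noise estimator, so the convention is
  declared here.
* **Recovery**: the relative-error summary is the mean absolute relative
  error in percent; that formula is a package convention (the source
  formula is unpublished) and is stated in the object's documentation.
* **Standard addition**: content $= $ intercept/slope. Per-level recovery
  is $100\,((y_i - y_0)/b)/\mathrm{added}_i$, again a declared convention.
  The instrumental variant treats the autosampler mixing as pure
  bookkeeping (0.1 µL of sample plus µL-scale standard aliquots; dilution
  effects neglected, as in the source procedure).
* **Stability**: regress $100\,S_{day}/S_0$ on day and solve for the day
  the line reaches 102% — the bound embedded in the published regression
  equations; since its rationale (an assay acceptance band) is inferred,
  the threshold is a visible argument, never hidden. Downward drift is
  solved against the symmetric 98% bound, an extension documented as such;
  a fitted slope below $10^{-8}$ in magnitude is reported as "no detectable
  drift" rather than a quadrillion-day estimate.
* **Equivalence**: classical one-way ANOVA (cross-checked against
  `stats::aov`), upper-tail F critical values, and the pooled-variance
  t / variance-ratio F pair (Welch by flag). Pooled t is the classical
  pharmaceutical-validation choice. The degrees of freedom behind the
  published robustness critical value 9.552 are not stated; (2, 3)
  reproduces it and the function takes explicit df.

## Greenness

The Eco-scale charges penalty points per reagent (amount class × GHS
pictogram count × signal-word multiplier), for instrument energy,
occupational exposure, and waste; the score is 100 minus the total, and 75+
is "excellent green analysis". The AGREE overall score is the weighted
arithmetic mean of twelve principle scores in [0, 1]. The bundled
`uplc_method_inventory()` is a labelled reconstruction built from the
optimum run conditions (0.456 mL of mobile phase per 9.5-min run at 0.048
mL/min, ~2 mL of dilution methanol, closed UPLC, treated waste); the
original per-item penalty breakdown is unpublished, so the reconstruction
is validated only against the >75 bound, which it meets with margin.

## Dosage-form arithmetic

`dilution_chain()` folds aliquot/flask steps into the nominally injected
amount (e.g. 98.50 mg capsule content → 100 mL, 250 µL → 10 mL, 0.1 µL
drawn gives 2.4625 ng), and `bp_uniformity_test()` classifies which BP
dosage-unit uniformity test applies (25 mg / 25%-by-weight rule); the
acceptance-value statistic itself is out of scope. Concentrations are
carried in explicit units (mg/mL internally, ng at the injection) because
the validated ranges mix ng/mL and µg/mL scales.

## Problem sizes and determinism

Every generator is a pure function of its parameters and a seed, and seeded
noise never disturbs the caller's RNG stream. The shipped tests use the
eight-run factorial at 10 Hz (7 201 points per trace), 200-seed Monte-Carlo
loops for parameter-recovery checks, 2 000 replicates for the t-test
type-I-error calibration, and a $101^3$ oracle grid for the optimizer —
sizes chosen so the full suite runs in well under a minute while leaving
the Monte-Carlo standard errors far smaller than the tolerances they guard.

## Known limitations

Overlapping peaks are not deconvolved — the measurement contract is
"resolved peaks in, geometry out". No weighted or robust calibration, no
lack-of-fit ANOVA, no nonlinear (Arrhenius-type) degradation models, no
fractional or response-surface designs, and no qualitative greenness
pictograms (a three-colour pictogram has no number to compute). The
simulator's realism limits are listed above; conclusions about real
instruments require real traces.
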