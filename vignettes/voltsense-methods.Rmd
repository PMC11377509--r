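---
title: "From voltammograms to tumor grade: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From voltammograms to tumor grade: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltsense)
```

## The measurement and the analysis problem

An electrochemical immunosensor for the canine mammary-tumor biomarkers
CA 15-3 and MUC-1 is read out by cyclic voltammetry (CV): the electrode
potential is swept (here from −0.05 V to −0.45 V at 50 mV/s) while the
current is recorded. Antibody–antigen binding at the sensor surface
modulates electron transfer, so the redox peak in the current–potential
trace grows with biomarker concentration, and biomarker concentration in
turn rises with tumor burden and grade. The analysis chain this package
implements has four stages:

1. reduce each voltammogram to 14 engineered descriptors;
2. relate descriptors (and clinical variables) to histological grade by
   Spearman rank correlation;
3. rank descriptors by random-forest importance and keep those above a
   working threshold (0.08);
4. benchmark four classifier families under leave-one-out
   cross-validation (LOOCV) for tumor-presence and tumor-grade
   prediction.

Alongside these, a calibration module provides the standard analytic
figures of merit (linear fit, limit of detection, area-normalised
sensitivity, selectivity ratio), and a packaged 17-case + 1-control
clinical cohort supports an exact reproduction of the clinical
rank-correlation analysis.

## The synthetic signal model

Raw instrument traces from the original study are not public, so the
package ships a seeded generator that produces voltammograms with the
statistical structure the downstream analysis assumes:

$$ I(E) = b_0 + b_1 E + A \exp\!\left(-\frac{(E - E_0)^2}{2\sigma^2}\right) + \varepsilon,
\qquad \varepsilon \sim \mathcal{N}(0, s^2) $$

a linear capacitive baseline plus a single Gaussian faradaic peak plus
i.i.d. Gaussian noise, over a uniform potential grid. This is the
simplest model that makes all 14 descriptors non-degenerate. An
exponentially modified Gaussian peak is available (`peak_shape = "emg"`)
when skewness and kurtosis should carry class signal. Defaults mirror
the instrument window: sweep −0.05 → −0.45 V, 50 mV/s, 256 points,
peak near −0.25 V with σ = 0.045 V, noise s = 0.02 µA.

Concentration enters through a saturating linear dose–response:
amplitude $A = a_0 + a_1 \cdot c$ for $c$ inside the linear window
(default 5–100 U/mL, $a_0 = 0.1$ µA, $a_1 = 0.004$ µA per U/mL),
clamped to the boundary value outside it. Class labels map to
concentrations via lognormal distributions with increasing medians —
by default control 2, grade I 15, grade II 45, grade III 85 U/mL, each
with coefficient of variation 0.25 and 5% electrode-to-electrode
jitter on peak position, width and baseline. The medians were chosen
once to spread the three grades across the sensor's linear window with
realistic overlap between adjacent grades (the control median sits
below the window, where the sensor saturates); they are study
conditions, not tuning knobs.

What the generator deliberately does **not** emulate: electrode
kinetics (no Butler–Volmer or Randles–Ševčík physics), capacitive
charging transients, multi-peak chemistry, fouling drift, or the full
two-branch CV cycle (a single sweep branch is generated by default —
the descriptor definitions are branch-agnostic). Tests passing on
synthetic data therefore establish that the *pipeline* is correct and
well-behaved, not that the original sensor's accuracy figures
generalise.

## The 14 descriptors and their numeric conventions

For a trace $(E_i, I_i)$ with scan rate $v$:

* **Charge (Q)** — trapezoidal integral of current over time, with the
  time axis reconstructed as accumulated $|\Delta E|/v$ (CV exports
  carry only $E$ and $I$). The charge is *signed*: anodic and cathodic
  contributions cancel.
* **Positive/negative peak current and potential** — the raw maximum
  and minimum of $I$ and their potentials.
* **Half-peak potential and peak width at half height** — these need a
  baseline to be meaningful. The package fits a straight line through
  the means of the first and last 10% of samples, subtracts it, takes
  the dominant peak (larger baseline-corrected magnitude), and finds
  the linearly interpolated half-maximum crossings. The half-peak
  potential is the crossing on the flank *preceding* the peak in sweep
  order; the width is the distance between both crossings, with an
  uncrossed flank clamped to the sweep endpoint. A flat trace returns
  zeros with a degenerate flag rather than an error, so batch runs
  survive a dead electrode.
* **Mean, median, standard deviation** — over the current samples; the
  standard deviation uses the $n-1$ denominator.
* **Skewness and kurtosis** — third standardised moment and *excess*
  kurtosis (normal → 0), population-moment form. Zero-variance traces
  return flagged zeros.
* **Peak first/second derivative** — central differences (one-sided at
  the sweep ends); the reported value is the extremum of the absolute
  derivative, signed as at the maximising point. The extremum (rather
  than the derivative at the peak, which is ~0) is baseline-robust.
  One consequence worth knowing: on a nearly symmetric peak the two
  flanks have almost equal $|dI/dE|$, so the *sign* of the first
  derivative extremum is effectively arbitrary — scale-sensitive
  consumers should standardise or take magnitudes.

All descriptor routines are validated against closed forms on
noiseless Gaussian signals (charge $A\sigma\sqrt{2\pi}/v$, FWHM
$2\sqrt{2\ln 2}\,\sigma$, derivative extremum $A e^{-1/2}/\sigma$) and
against independent textbook recomputation for the moments, with
grid-refinement convergence checks.

## Clinical rank-correlation analysis

The packaged cohort transcribes the study's clinical and
histopathology tables: 17 malignant cases (age, breed, weight, mammary
lobe, TNM staging, grade I–III, SILN metastasis, MUC-1 IHC score 0–3)
plus one healthy control. Two transcription notes: the published
summary labels "median age 11.17 ± 1.59", but those values equal the
arithmetic mean ± SD of the tabulated ages (the median is 11), so the
summary reports both; and the published MUC-1 "staining rate of 54.5%"
is inconsistent with the tabulated 11 stained tumors out of 17
(64.7%) — the package reports the count.

The correlation analysis codes location as the lobe number (3/4/5),
size as T stage (1/2), nodal and lung metastasis as 0/1, MUC-1 as its
0–3 score and grade as 1–3, excludes the control, assigns average
ranks to ties, and computes Spearman's ρ as the Pearson correlation of
the ranks. Two-sided p-values come from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom. Neither
the coding nor the p-value method is externally documented for this
table; this combination reproduces all five published coefficient/
p-value pairs to three decimals, which is why it is the default. An
exact permutation p-value is available for small samples
(`method = "permutation"`).

```{r}
correlation_table()
cohort_summary()
```

## Feature ranking and threshold selection

`feature_target_correlations()` reuses the same Spearman engine per
descriptor column. `rf_importance()` uses mean impurity (Gini)
decrease from a seeded 500-tree random forest, normalised to sum to 1;
permutation importance is available as an option. Impurity importance
is the conventional default for this algorithm; 500 trees keeps the
ranking stable at the n ≤ 20 sample sizes this field works with.

`select_features()` applies a *strict* inequality at the threshold
("surpassing" 0.08, not meeting it). On the published CA 15-3 column
this keeps exactly five descriptors. On the published MUC-1 column
eight values exceed 0.08, although the accompanying text lists seven
(it omits the peak derivative at 0.0835); the package follows the
arithmetic rule and flags the discrepancy here rather than
special-casing.

```{r}
select_features(published_importance("ca153"), threshold = 0.08)
```

## Classifier benchmark under LOOCV

Four families are benchmarked: a random forest; two gradient-boosted
tree variants (`"xgb"`: depth-3 trees; `"gbm"`: depth-6 trees with 80%
row/column subsampling — both 200 rounds at learning rate 0.1 on the
same boosting engine); and a feed-forward neural network (one hidden
layer of 16 units, weight decay 1e-3, 500 iterations, inputs
standardised with statistics fitted on the training fold only). All
hyperparameters are fixed rather than searched: with ~18–60 samples,
tuning inside LOOCV would overfit the folds. The network uses a single
hidden layer because that is what the installed single-hidden-layer
implementation supports; at these sample sizes additional depth adds
variance, not capacity that can be used.

Both boosted variants use exact greedy splits. Histogram-based
splitting — the engine's modern default — places split thresholds *at*
training feature values; under LOOCV with tiny n, the held-out extreme
of a class then falls on the wrong side of a threshold pinned to the
remaining training minimum, even for arbitrarily wide class margins.
Exact splits sit mid-way between neighbouring training points and do
not have this artifact.

Scoring pools all n held-out predictions into one confusion matrix and
computes accuracy, precision, recall and F1 from it (per-fold metrics
are degenerate when each fold has one sample). Multiclass tasks are
macro-averaged over one-vs-rest; zero-denominator cases yield 0 with
an explicit flag. A class with a single member (the study's lone
control) is scored with that class absent from its training fold —
the honest LOOCV semantics — with a warning.

The published model accuracies cannot be recomputed (the instrument
dataset is not public; with 18 samples they are also not multiples of
1/18, so their provenance is unclear). The benchmark is therefore
validated by properties instead: perfect separation of a wide-margin
two-class task (n = 40) by all four families; chance-level behaviour
on label-permuted data (50 permutations, mean accuracy within 3
standard errors of chance — run at n = 24 with reduced-capacity
configurations of the same four families, which keeps the Monte Carlo
inside a desk-scale runtime without changing the leakage property
being tested); ≥ 0.7 accuracy for the best family on a three-grade
task with monotone concentration signal (n = 60); and exact fold
accounting at the study's n = 18.

## Calibration conventions

The limit of detection uses the ICH convention
$\mathrm{LOD} = 3.3\,\sigma_{\text{blank}}/\text{slope}$ (multiplier
configurable, e.g. 3.0). Sensitivity is the calibration slope divided
by the electrode area (2 cm² by default). The selectivity ratio is
defined as the target response magnitude divided by the mean
interferent response magnitude — the simplest definition consistent
with reporting a single "selectivity value"; published selectivity
numbers for this sensor cannot be reproduced because the underlying
panel responses are not public, so this definition is a package
convention, not an authoritative reconstruction. A related caveat:
published LOD figures for this sensor appear once in U/mL and once in
µM with the same digits; the two unit systems cannot be reconciled
from the available information, and the package treats concentration
as a single abstract dose axis (nominally U/mL) throughout.

## Pipeline orchestration and reproducibility

`run_pipeline()` executes a mode's stage sequence (simulate → features
→ analysis → evaluation for the synthetic benchmark; single-stage
modes for the clinical table, feature extraction and calibration) and
writes a manifest recording the configuration, package version,
per-stage seeds and an md5 checksum of every file written. One global
seed is fanned out to per-stage seeds by fixed offsets (+101 simulate,
+211 features, +307 analysis, +401 evaluation) so stages can be rerun
in isolation yet reproducibly. Failures leave partial outputs next to
a `FAILED` marker naming the stage.

## Known limitations

* The synthetic generator's class structure is a modelling choice
  motivated by, not measured from, the original sensor; absolute
  benchmark accuracies on synthetic data say nothing about the
  published accuracies.
* Features are computed on one sweep branch; if a full two-branch
  cycle is supplied the descriptors remain well-defined but the
  baseline fit straddles both branches.
* The clinical cohort is small (n = 17); the rank correlations carry
  wide sampling uncertainty, and the package deliberately offers no
  multivariable modelling on it.
* No smoothing, multi-peak deconvolution or capacitive-current
  modelling: traces are assumed single-peak after linear baseline
  removal.
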