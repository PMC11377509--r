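# voltsense

Signal analysis for electrochemical immunosensors that read out canine
mammary-tumor biomarkers (CA 15-3 and MUC-1) by cyclic voltammetry
(CV). The package is aimed at biosensor groups and veterinary-oncology
researchers who want a tested, reproducible route from a raw
current–potential trace to a tumor-presence or tumor-grade call — plus
the clinical rank-correlation analysis that accompanies such studies.

## What it computes

**Feature engineering.** Each voltammogram $(E_i, I_i)$ with scan rate
$v$ is reduced to 14 descriptors: signed charge
$Q = \int I\,dt$ (time reconstructed as $|\Delta E|/v$), half-peak
potential and peak width at half height (after straight-line baseline
removal), mean/median/SD of current, skewness, excess kurtosis, the
extrema of $dI/dE$ and $d^2I/dE^2$, and the positive/negative peak
currents and potentials.

**Rank correlation.** Spearman's $\rho$ with tie-averaged ranks;
two-sided p-values from $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$
degrees of freedom (exact permutation optional). Applied both to the
packaged 17-case clinical cohort (location, size, nodal and lung
metastasis, MUC-1 score vs grade) and to CV descriptors vs grade.

**Feature selection.** Seeded random-forest (Gini) importance,
normalised to sum to 1, with strict-threshold selection (the working
threshold is 0.08).

**Classifier benchmark.** Leave-one-out cross-validation of four
families (random forest, two gradient-boosted tree variants, a small
neural network), scored by pooling held-out predictions into one
confusion matrix: accuracy, precision, recall, F1 (macro-averaged for
multiclass).

**Calibration.** OLS dose–response fit, limit of detection
$3.3\,\sigma_{\text{blank}}/\text{slope}$, area-normalised
sensitivity, selectivity ratio against an interferent panel.

**Synthetic data.** A seeded generator (linear baseline + Gaussian
redox peak + noise, concentration-dependent amplitude over a 5–100
U/mL linear window) makes every stage testable without instrument
data, emulating the study design of 17 tumor + 1 control samples.

## Worked example

Reproduce the clinical correlation analysis from the packaged cohort:

```r
library(voltsense)
correlation_table()
#>     variable    rho p_value  n label
#> 1   location  0.512   0.036 17     +
#> 2       size  0.622   0.008 17    ++
#> 3 lymph_node  0.069   0.792 17    NS
#> 4       lung  0.410   0.102 17    NS
#> 5       muc1 -0.193   0.457 17    NS
```

Tumor location and size correlate significantly with grade; nodal or
lung metastasis and MUC-1 immunostaining do not, at this sample size.

Run the synthetic grade-prediction benchmark end to end:

```r
ds  <- simulate_labeled_dataset(grade_class_specs(include_control = FALSE),
                                n_per_class = 10, seed = 42)
fm  <- extract_feature_matrix(ds$voltammograms, labels = ds$labels)
imp <- rf_importance(fm[cv_feature_names()], ds$labels, seed = 42)
select_features(imp, threshold = 0.08)
#> [1] "skewness"              "positive_peak_current" "std_current"
#> [4] "charge_Q"              "mean_current"

benchmark_models(fm[cv_feature_names()], ds$labels,
                 default_model_specs(seed = 42))
#>   model  accuracy precision    recall        f1
#> 1   gbm 0.8333333 0.8387446 0.8333333 0.8360302
#> 2    rf 0.8000000 0.7954545 0.8000000 0.7977208
#> 3   xgb 0.8000000 0.8115773 0.8000000 0.8057471
#> 4   ann 0.6333333 0.6269360 0.6333333 0.6301184
```

Five descriptors clear the 0.08 importance threshold on this draw, and
the boosted-tree variant classifies 25 of the 30 synthetic grade
samples correctly under LOOCV. `run_pipeline(run_config(...))` wraps
the same sequence with a reproducibility manifest; a thin CLI wrapper
lives at `inst/cli/voltsense-pipeline.R`.

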