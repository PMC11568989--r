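# gaitfall

Fall-risk classification of older adults from a single waist-worn tri-axial
accelerometer recorded during a short walk at a self-selected pace.

Routine clinical fall screening relies on questionnaires and stopwatch tests
that are subjective and weakly predictive. A one-minute walk with a cheap
belt-worn accelerometer is an objective alternative: the vertical (V),
mediolateral (ML) and anterior–posterior (AP) acceleration of the trunk
carries the regularity, symmetry and spectral signature of a person's gait.
**gaitfall** implements the full analysis chain from raw signal to
classifier evaluation, plus a seeded synthetic gait generator so the whole
pipeline is testable end to end without clinical data.

## The method

1. **Preprocessing** (per axis): 3-sample median filter → gravity removal
   (zero-phase 0.25 Hz low-pass subtraction) → two zero-phase Butterworth
   bandpass versions — 0.5–3 Hz for step detection, 0.5–15 Hz for all
   features — each normalized to its maximum absolute value.
2. **Step detection**: local maxima of the normalized 0.5–3 Hz V axis
   (height ≥ 0.2, separation ≥ 0.25 s) give step and stride durations and
   cadence.
3. **Feature extraction**: a fixed registry of **168 features** — 3
   gait-cycle timings, 6 cross-axis correlations/covariances, and per axis
   21 time-domain statistics (per-step statistics, step/stride regularity
   from the normalized autocorrelation at the step/stride lag, mean trend)
   plus 32 descriptors of a Tukey-windowed (α = 0.5) periodogram restricted
   to 0.5–15 Hz (dominant-peak frequency/amplitude/width/prominence F1 and
   F2, spectral centroid/spread/skewness/kurtosis/flatness/crest, band
   powers, …).
4. **Feature selection**: from-scratch two-class **ReliefF**
   (all-instances, Manhattan distance, hit/miss update
   `W[f] ← W[f] − Σ_hits diff/(mK) + P·Σ_miss diff/(mK)`), swept over
   neighbor counts K = 1..40 and retained-feature counts N = 5..40.
5. **Classification**: single-hidden-layer perceptron (ReLU hidden units,
   sigmoid faller score, L2 α = 1e-4, ≤ 200 epochs, Adam) with hidden
   widths 10..200, evaluated by stratified 10-fold cross-validation. All
   out-of-fold predictions pool into one TP/FN/FP/TN table; accuracy =
   (TP+TN)/total, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), AUC
   from pooled scores. The best (K, N, hidden) cell maximizes accuracy,
   then sensitivity, then parsimony.

## Worked example

```r
library(gaitfall)

# a small labeled synthetic cohort: 8 fallers (irregular gait),
# 8 non-fallers (regular gait), one-minute walks at 100 Hz
cohort <- generate_cohort(cohort_spec(n_fallers = 8, n_nonfallers = 8,
                                      duration_s = 60, seed = 7))
fm <- build_matrix(cohort)
fm
#> <feature_matrix> 16 subjects x 168 features (8 faller / 8 non-faller), 0 excluded

round(fm$X[1, c("avg_step_dur_s", "cadence_spm", "StpReg_V", "StrReg_V",
                "corr_V_AP", "flatness_PSD_ML")], 3)
#>  avg_step_dur_s     cadence_spm        StpReg_V        StrReg_V       corr_V_AP
#>           0.556         108.008           0.951           0.981          -0.749
#> flatness_PSD_ML
#>           0.001

# ReliefF (K, N) sweep with MLP evaluation, then lexicographic selection
fms <- minmax_scale(fm)
ev  <- make_eval_fn(hidden_range = c(10L, 50L), n_folds = 8L, seed = 7)
sw  <- selection_sweep(fms, K_range = c(5, 10), N_range = c(5, 10, 15),
                       eval_fn = ev)
model_select(sw)
#>   K N hidden_units AUC accuracy sensitivity specificity TP FN FP TN skipped
#> 1 5 5           10   1        1           1           1  8  0  0  8   FALSE

head(sw$weightings[["10"]]$ranking, 5)
#> [1] "StrReg_V"    "reg_ratio_V"    "StrReg_AP"    "entropy_PSD_V"
#> [5] "entropy_PSD_AP"
```

The first subject walks at cadence 108 steps/min with highly repeatable
steps (step regularity 0.95 on V). The sweep's best configuration
classifies the 16 subjects perfectly out of fold — expected here, because
the generator's default faller/non-faller jitter regimes are deliberately
well separated — and ReliefF puts regularity-type features at the top of
the ranking, which is exactly what separates the two simulated groups.

For a full run (feature table, grid CSV, best-model JSON and a replayable
log) use `run_pipeline()`, or the thin CLI in `inst/cli/gaitfall.R`
(`synth`, `extract`, `run-all`, `select-best` subcommands).

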