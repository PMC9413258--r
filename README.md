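# gaitage

Age prediction for elderly adults from a single trunk-worn IMU recorded
during two standard clinical tests of dynamic balance ability: the **Timed
Up and Go test (TUG)** and the **six-minute walk test (6MWT)**.

Dynamic balance declines with age, but instrumented balance readouts are
hard for non-specialists to interpret. Mapping the sensor signal to a
*predicted age* gives clinicians, caregivers and the elderly themselves an
immediately interpretable indicator. `gaitage` implements the complete
analysis chain:

1. **Synthetic cohort generator** — harmonic-sum gait signals with
   controllable step time, asymmetry, smoothness and noise, TUG trials
   built from chair (pitch) and turn (yaw) angular-velocity pulses, and
   age-coupled parameters with per-recording ground truth. Defaults emulate
   a cohort of 136 subjects aged 60–90 (36/64/36 per decade, 33 M / 103 F),
   three TUG trials and one 6MWT each at 100 Hz.
2. **Preprocessing** — minimal-order zero-phase Butterworth low-pass
   filters specified as (passband, steepness, stopband attenuation),
   rectification, and the resultant acceleration
   `ACC_RES = sqrt(ACC_VT² + ACC_ML² + ACC_AP²)`.
3. **TUG segmentation** — threshold detection on rectified, filtered pitch
   (25 deg/s, chair transfers) and yaw (32 deg/s, turns) splits each trial
   into six sub-tasks: sit-to-stand, forward gait, mid-turn, backward gait,
   end-turn, stand-to-sit.
4. **Feature engineering (132 features)** — 111 TUG features (6 timings +
   rms/min/max of 7 signals over 5 sub-task groups) and 21 6MWT features:
   gait parameters, step/stride regularity from the unbiased
   autocorrelation

   `A(m) = 1/(N−m) Σᵢ xᵢ xᵢ₊ₘ`  (mean-removed, normalized by `A(0)`),

   symmetry index `SI = (SR − STR)/max(SR, STR)`, stride-harmonic ratio
   (even/odd for VT and AP, odd/even for ML), and Pincus approximate
   entropy `ApEn = Φᵐ(r) − Φᵐ⁺¹(r)`.
5. **Age regression** — subject-level 70/10/20 split, XGBoost tuned by
   Bayesian (GP expected-improvement) search on validation MAE, evaluation
   by `MAE = mean(|ŷ − y|)` and `MAPE = 100·mean(|ŷ − y|/y)`, gain-based
   feature-importance scores normalized to sum to 1, and an OT (TUG-only)
   vs OS (6MWT-only) vs AG (pooled) feature-set comparison.

## Worked example

```r
library(gaitage)

co <- simulate_cohort(
  cohort_spec(n_subjects = 30,
              age_group_counts = c(`60s` = 8, `70s` = 14, `80s` = 8),
              sex_counts = c(M = 7, F = 23)),
  coupling = planted_age_coupling, seed = 42, duration_6mwt = 120)
co
#> <gaitage_cohort> 30 subjects, 120 recordings

tab <- extract_cohort_features(co)   # subjects x (id, age, 132 features)

segment_tug(co$recordings$recording[[1]])
#> # A tibble: 6 × 3
#>   subtask       start_s end_s
#> 1 sit_to_stand     1.21  2.3
#> 2 forward_gait     2.3   5.47
#> 3 mid_turn         5.47  6.99
#> 4 backward_gait    6.99 10.2
#> 5 end_turn        10.2  11.7
#> 6 stand_to_sit    12.7  13.8

fit <- fit_age_model(tab, feature_set = "AG", seed = 7, n_trials = 10)
fit
#> <gaitage_fit> AG (132 features): test MAE 4.60 y, MAPE 5.72%
#> top features:
#>   tug.time.total                      0.290
#>   6mwt.gp.step_time                   0.192
#>   tug.time.gait                       0.070
#>   tug.gait.pitch.rms                  0.058
#>   6mwt.sr.acc_vt                      0.058
```

The fitted model predicts held-out subjects' ages with a mean absolute
error of 4.6 years (5.7 %) on this small demonstration cohort — versus a
no-skill baseline of the label SD (about 7.6 years) — and the importance
ranking recovers where the generator planted the age signal: walking pace
(TUG total/gait time, 6MWT step time) and gait regularity. Broom-style
accessors are available (`tidy()` for importances, `glance()` for the
one-row summary, `augment()` for per-subject predictions), along with
`autoplot()` methods and `plot_tug_segmentation()` /
`plot_feature_importance()`.

`compare_feature_sets(tab, seed = 1)` runs the identical protocol on the
OT, OS and AG sets and reports per-set MAE/MAPE plus their across-set
mean ± SD.

## Package layout

* `R/synth.R` — cohort/trial generators and age couplings
* `R/preprocess.R`, `R/tug-segment.R` — filtering and segmentation
* `R/features-tug.R`, `R/features-6mwt.R`, `R/features-pipeline.R` — the
  132-feature scheme
* `R/model.R`, `R/tune.R` — split/train/evaluate/importance and the GP
  search
* `R/io.R`, `R/feature-schema.R` — CSV formats, manifests, schema census
* `src/apen.cpp` — approximate-entropy kernel
* `vignettes/gaitage-methods.Rmd` — models, assumptions and design choices
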