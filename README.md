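# gaitrel

Between-session (test-retest) reliability of gait analysis from bilateral
lower-limb kinematics.

Clinical gait analysis increasingly happens outside the motion-capture
laboratory, and any system used to track patients over time must come
with a number answering one question: *how much of a between-day change
is just measurement noise?* `gaitrel` implements the full pipeline that
produces that number from raw walking passes — synchronized joint-angle
signals (hip/knee/ankle × sagittal/frontal/transverse × both sides,
degrees) and landmark trajectories (heel, toe, sacrum; meters) sampled
at a fixed rate — and, because raw two-session cohorts are rarely
shared, a synthetic gait-cohort generator with a known variance
hierarchy so that every stage can be validated against ground truth.

The pipeline:

1. **Event detection** (coordinate-based): initial contact at local
   maxima of the progression-aligned heel-sacrum fore-aft distance,
   toe-off at minima of the toe-sacrum distance.
2. **Stride segmentation and time normalization** to 101 points of the
   gait cycle, with automated stride quality rules.
3. **Feature extraction**: 32 discrete kinematic variables (windowed
   extrema, values at named cycle points, ranges of motion) and 15
   spatiotemporal parameters (stride/stance/swing/support/step times,
   cadence, stride/step length, step width, gait speed, leg-length
   normalized variants).
4. **Reliability**: per joint/plane full-curve RMSD between the two
   sessions' ensemble-average curves, and per variable the standard
   error of measurement from the subjects × sessions repeated-measures
   ANOVA,

   SEM = √MS_error, with SEM% = 100 · SEM / |grand mean| for
   spatiotemporal parameters, and ICC(3,1)·based SEM as an internal
   cross-check (SD·√(1−ICC) equals √MS_error under the matching
   decomposition).

See `vignettes/gait-reliability-methods.Rmd` for the model, parameter
and design details, and the `analysis/` scripts for the full study-scale
workflow (simulate → detect/extract → reliability report → estimator
validation), which write their tables under `results/`.

## Worked example

Simulate a small two-session cohort at self-selected walking speed and
run the full pipeline:

```r
library(gaitrel)
cfg <- cohort_config(task = "SSWS", n_subjects = 8,
                     passes_per_session = 3, seed = 42)
rep <- run_pipeline(cfg)
print(rep)
#> <reliability_report> task SSWS
#>   kinematic SEM: 32 variables, range 0.16-2.28 deg
#>   full-curve RMSD: 9 joint/plane curves, range 1.55-2.36 deg
#>   spatiotemporal SEM%: range 3.3-11.7%
#>   excluded stride windows: 0
```

Spatiotemporal reliability (selected rows):

```r
rep$stp[, c("variable", "session1_mean", "session2_mean", "sem", "sem_pct")]
#>       variable session1_mean session2_mean   sem sem_pct
#>     gait_speed         1.394         1.400 0.060   4.265
#>        cadence       118.346       118.048 4.165   3.523
#>    stride_time         1.017         1.021 0.036   3.499
#>  stride_length         1.416         1.417 0.053   3.760
#>     step_width         0.179         0.178 0.021  11.733
```

A gait-speed SEM of 0.06 m/s means a between-day speed change smaller
than that is indistinguishable from measurement noise; step width, with
its small mean, has the largest relative error — the usual pattern for
between-day protocols. Discrete kinematics and full-curve RMSD land in
the conventional "good/acceptable" bands (<5°):

```r
head(rep$kinematic[, c("variable", "session1_mean", "session2_mean", "sem", "band")], 4)
#>                     variable session1_mean session2_mean  sem          band
#>             Hip_Sagittal_RoM         46.22         46.03 1.17 good (<2 deg)
#>  Hip_Sagittal_MaxFlex_Stance         27.31         27.84 1.51 good (<2 deg)
#>   Hip_Sagittal_MaxFlex_Swing         29.21         29.66 1.46 good (<2 deg)
#>   Hip_Sagittal_MaxExt_Stance        -17.01        -16.36 1.78 good (<2 deg)

rep$rmsd[1:3, c("joint", "plane", "rmsd", "band")]
#>  joint    plane rmsd          band
#>    hip sagittal 1.78 good (<2 deg)
#>   knee sagittal 1.55 good (<2 deg)
#>  ankle sagittal 1.86 good (<2 deg)
```

Because the generator injects a *known* between-session error, the same
machinery validates the estimators: `sem_recovery()` shows the ANOVA SEM
recovering injected error SDs within a few percent at n = 21 subjects,
and `event_detection_fidelity()` confirms every ground-truth contact and
toe-off is found within one sample on noise-free cohorts.

Trials round-trip through a plain CSV dialect (`write_trial()` /
`read_trial()`; commented header block plus one row per sample), and
cohort configurations load from YAML (`read_cohort_config()`).

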