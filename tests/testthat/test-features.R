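test_that("phase windows follow the event-phase definitions", {
  pw <- phase_windows(0.60, 0.50, 0.12)
  expect_equal(pw$dls1, c(0, 0.12))
  expect_equal(pw$sls, c(0.12, 0.50))
  expect_equal(pw$dls2, c(0.50, 0.60))
  expect_equal(pw$swing, c(0.60, 1))
  expect_equal(pw$midstance, 0.30)
  expect_equal(pw$midswing, 0.80)
  expect_equal(pw$stsw, c(0.30, 0.60 + 0.2 * 0.40))
  # partition identity: support-phase lengths sum to the stance length
  expect_equal(diff(pw$dls1) + diff(pw$sls) + diff(pw$dls2),
               diff(pw$stance))
  expect_error(phase_windows(0.6, 0.12, 0.50), "out of order")
})

test_that("double-support phases are symmetric when the contralateral offset is 0.5", {
  coh <- generate_cohort(noise_free_config(strides = 4))
  an <- analyze_cohort(coh$trials)
  f <- an$features
  # generator ground truth: offset exactly 0.5 makes DLS1 = DLS2 up to
  # one-sample event quantization on each bounding event
  expect_lt(max(abs(f$dls1_time - f$dls2_time)), 2.5 / 60)
  expect_lt(abs(mean(f$dls1_time) - mean(f$dls2_time)), 0.5 / 60)
})

test_that("reducers behave on elementary curves", {
  pw <- phase_windows(0.6, 0.5, 0.12)
  reg <- kinematic_registry()
  rom <- reg[reg$name == "Knee_Sagittal_RoM", ]
  curve <- c(-10, 5, 20, rep(0, 98))
  expect_equal(extract_discrete(curve, rom, pw), 30)

  const <- rep(4, 101)
  for (r in seq_len(nrow(reg))) {
    v <- extract_discrete(const, reg[r, ], pw)
    expect_equal(v, if (reg$reducer[r] == "range") 0 else 4)
  }
})

test_that("signed minima stay signed on all-positive curves", {
  pw <- phase_windows(0.6, 0.5, 0.12)
  reg <- kinematic_registry()
  ext <- reg[reg$name == "Hip_Sagittal_MaxExt_Stance", ]
  curve <- 5 + sin(2 * pi * seq(0, 1, length.out = 101))  # all positive
  v <- extract_discrete(curve, ext, pw)
  expect_equal(v, min(curve[seq(0, 1, length.out = 101) <= 0.6]))
  expect_gt(v, 0)  # signed value, no absolute-value behaviour
})

test_that("extraction equals the exhaustive window-scan oracle on random curves", {
  set.seed(7)
  reg <- kinematic_registry()
  for (r in 1:50) {
    curve <- as.numeric(arima.sim(list(ar = 0.9), 101)) * 10
    pw <- random_phase_windows()
    for (k in seq_len(nrow(reg))) {
      expect_identical(extract_discrete(curve, reg[k, ], pw),
                       scan_oracle(curve, reg[k, ], pw))
    }
  }
})

test_that("RoM dominates every windowed excursion of the same channel", {
  set.seed(8)
  reg <- kinematic_registry()
  for (r in 1:10) {
    curve <- as.numeric(arima.sim(list(ar = 0.8), 101)) * 8
    pw <- random_phase_windows()
    rom <- max(curve) - min(curve)
    for (k in which(reg$reducer %in% c("max", "min"))) {
      v <- extract_discrete(curve, reg[k, ], pw)
      expect_gte(rom, max(curve) - v)
      expect_gte(rom, v - min(curve))
    }
  }
})

test_that("knee swing-flexion extraction matches the template's analytic peak", {
  coh <- generate_cohort(noise_free_config(strides = 3))
  an <- analyze_cohort(coh$trials)
  # analytic maximum of the default knee sagittal template over swing
  ph <- seq(0, 1, length.out = 5001)
  knee <- joint_angle_template("knee", "sagittal", ph)
  sf <- coh$config$stp_means$stance_fraction
  peak <- max(knee[ph >= sf])
  got <- an$features$Knee_Sagittal_MaxFlex_Swing
  expect_equal(mean(got), peak, tolerance = 0.01)
  expect_equal(peak, 64, tolerance = 0.05)  # published swing-flexion scale
})

test_that("feature table has one row per stride and all registry columns", {
  coh <- generate_cohort(small_noisy_config(n_subjects = 2, passes = 1))
  tr <- coh$trials[[1]]
  dom <- tr$dominant_side
  oth <- if (dom == "L") "R" else "L"
  st <- segment_strides(detect_gait_events(tr, dom),
                        detect_gait_events(tr, oth))
  ns <- normalize_strides(tr, st)
  ft <- feature_table(ns)
  expect_equal(nrow(ft), nrow(st))
  expect_true(all(kinematic_registry()$name %in% names(ft)))
  expect_false(anyNA(ft))
})

test_that("noise-free cohorts give (numerically) zero across-stride variance", {
  # stride time = 66 samples exactly, so every stride samples the template
  # at identical phases
  coh <- generate_cohort(noise_free_config(
    n_subjects = 2, strides = 4,
    stp_means = list(gait_speed = 1.3, stride_length = 1.43)))
  an <- analyze_cohort(coh$trials)
  f <- an$features
  for (v in kinematic_registry()$name) {
    expect_lt(max(tapply(f[[v]], f$subject, sd)), 1e-8)
  }
})
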