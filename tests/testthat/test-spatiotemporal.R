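# direct-arithmetic fixture: a hand-built trial with events at known samples
make_arith_trial <- function(fs = 60) {
  n <- 200
  t <- (0:(n - 1)) / fs
  speed <- 1.3
  sac <- speed * t
  lm <- list(
    "R.heel.AP" = sac + 0.35, "L.heel.AP" = sac - 0.36,
    "R.heel.ML" = rep(0.10, n), "L.heel.ML" = rep(-0.09, n),
    "R.toe.AP" = sac + 0.5, "L.toe.AP" = sac - 0.2,
    "pelvis.sacrum.AP" = sac)
  structure(list(trial_id = "arith", subject_id = "S", session = 1, pass = 1,
                 task = "SSWS", sampling_rate = fs, leg_length = 0.84,
                 dominant_side = "R", progression_sign = 1, n_samples = n,
                 angles = list(), landmarks = lm),
            class = "motion_trial")
}

test_that("temporal parameters are direct arithmetic on event indices", {
  tr <- make_arith_trial()
  st <- data.frame(stride = 1, ic_start = 0, ic_end = 66, to = 40,
                   contra_ic = 33, contra_to = 11)
  stp <- compute_stp(tr, st)
  expect_equal(stp$stride_time, 1.1)
  expect_equal(stp$stance_time, 40 / 60)
  expect_equal(stp$swing_time, 26 / 60)
  expect_equal(stp$cadence, 120 / 1.1)   # ~109 steps/min at usual pace
  expect_equal(stp$dls1_time, 11 / 60)
  expect_equal(stp$dls2_time, 7 / 60)
  expect_equal(stp$sls_time, 22 / 60)
  expect_equal(stp$step_time, 33 / 60)
  # constant-speed sacrum: gait speed recovers it exactly
  expect_equal(stp$gait_speed, 1.3)
  # heel offsets are constant, so stride length = sacrum advance
  expect_equal(stp$stride_length, 1.3 * 1.1)
  expect_equal(stp$step_length, 0.71)
  expect_equal(stp$step_width, 0.19)
})

test_that("leg-length normalization is plain division", {
  tr <- make_arith_trial()
  st <- data.frame(stride = 1, ic_start = 0, ic_end = 66, to = 40,
                   contra_ic = 33, contra_to = 11)
  stp <- compute_stp(tr, st, leg_length = 0.84)
  expect_equal(stp$stride_length_ll, stp$stride_length / 0.84)
  expect_equal(stp$gait_speed_ll, stp$gait_speed / 0.84)
  # a 1.43 m stride on a 0.84 m leg is 1.7024 leg lengths
  expect_equal(1.43 / 0.84, 1.7024, tolerance = 1e-4)
})

test_that("time-partition identities hold exactly on every processed stride", {
  coh <- generate_cohort(small_noisy_config(seed = 13))
  an <- analyze_cohort(coh$trials)
  f <- an$features
  expect_gt(nrow(f), 20)
  expect_identical(f$stride_time, f$stance_time + f$swing_time)
  expect_equal(f$stance_time, f$dls1_time + f$sls_time + f$dls2_time,
               tolerance = 1e-15)
  expect_true(all(f$stride_time > 0 & f$stance_time > 0 & f$swing_time > 0))
  expect_true(all(f$stride_length >= 0 & f$step_width >= 0))
})

test_that("gait speed times stride time equals the sacrum displacement", {
  coh <- generate_cohort(small_noisy_config(seed = 17, n_subjects = 2))
  for (tr in coh$trials[1:4]) {
    dom <- tr$dominant_side
    oth <- if (dom == "L") "R" else "L"
    st <- segment_strides(detect_gait_events(tr, dom),
                          detect_gait_events(tr, oth))
    stp <- compute_stp(tr, st)
    sac <- tr$landmarks[["pelvis.sacrum.AP"]]
    disp <- tr$progression_sign * (sac[st$ic_end + 1] - sac[st$ic_start + 1])
    expect_equal(stp$gait_speed * stp$stride_time, disp)
  }
})

test_that("symmetric gait yields step length near half the stride length", {
  coh <- generate_cohort(noise_free_config(strides = 4))
  an <- analyze_cohort(coh$trials)
  f <- an$features
  expect_equal(f$step_length, f$stride_length / 2, tolerance = 0.02)
})

test_that("per-stride estimates recover the generator draws", {
  coh <- generate_cohort(small_noisy_config(seed = 23, n_subjects = 3))
  an <- analyze_cohort(coh$trials)
  f <- an$features
  gt <- coh$ground_truth$strides
  key_f <- paste(f$trial_id, f$stride)
  key_g <- paste(gt$trial_id, gt$stride)
  m <- match(key_f, key_g)
  expect_false(anyNA(m))
  # one-sample event quantization at 60 Hz is ~17 ms; the heel advances at
  # roughly walking speed near contact, so length errors are up to 2 v/fs
  expect_lt(max(abs(f$stride_time - gt$stride_time[m])), 2.5 / 60)
  expect_lt(max(abs(f$stride_length - gt$stride_length[m])),
            2.5 * max(gt$gait_speed) / 60)
  expect_lt(max(abs(f$step_width - gt$step_width[m])), 1e-6)
  expect_equal(cor(f$stride_time, gt$stride_time[m]), 1, tolerance = 0.02)
})

test_that("Monte-Carlo cohort means converge to the configured parameters", {
  cfg <- cohort_config(n_subjects = 40, passes_per_session = 2,
                       strides_per_pass = 4, seed = 29)
  coh <- generate_cohort(cfg)
  an <- analyze_cohort(coh$trials)
  f <- an$features
  expect_gt(nrow(f), 500)
  for (v in c("gait_speed", "stride_length", "step_width")) {
    sm <- tapply(f[[v]], f$subject, mean)
    se <- sd(sm) / sqrt(length(sm))
    expect_lt(abs(mean(sm) - cfg$stp_means[[v]]), 3.5 * se + 0.01)
  }
  sm_t <- tapply(f$stride_time, f$subject, mean)
  expect_equal(mean(sm_t), 1.43 / 1.35,
               tolerance = 3.5 * sd(sm_t) / sqrt(length(sm_t)) / 1.06 + 0.03)
})
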