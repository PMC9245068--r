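test_that("ensemble average is the pointwise mean", {
  one <- matrix(rnorm(101), 1)
  expect_equal(ensemble_average(one), as.numeric(one))
  c0 <- rnorm(101)
  expect_equal(ensemble_average(rbind(c0, -c0)), rep(0, 101))
  set.seed(5)
  m <- matrix(rnorm(7 * 101), 7)
  oracle <- vapply(1:101, function(j) sum(m[, j]) / 7, numeric(1))
  expect_equal(ensemble_average(m), oracle, tolerance = 1e-12)
})

test_that("RMSD has its closed-form values on elementary curve pairs", {
  c1 <- rnorm(101)
  expect_equal(rmsd_between_sessions(c1, c1), 0)
  expect_equal(rmsd_between_sessions(c1, c1 + 2), 2)
  # sinusoidal offset of amplitude A: RMSD tends to A/sqrt(2)
  p <- seq(0, 1, length.out = 10001)
  A <- 3.2
  expect_equal(rmsd_between_sessions(rep(0, 10001), A * sin(2 * pi * p)),
               A / sqrt(2), tolerance = 1e-3)
  expect_error(rmsd_between_sessions(c1, c1[-1]), "equal length")
})

test_that("SEM worked examples and the two algebraic forms agree", {
  # pure systematic +2 shift: interaction error is zero
  m <- cbind(c(10, 20, 30), c(12, 22, 32))
  expect_equal(sem_anova(m), 0)
  # two subjects with differences {0, 2}: hand-computed MS_error = 1
  m2 <- cbind(c(5, 9), c(5, 11))
  expect_equal(sem_anova(m2), 1)
  expect_equal(sem_from_differences(m2), 1)
  # ANOVA form vs sd(d)/sqrt(2) identity on random matrices
  set.seed(9)
  for (r in 1:25) {
    mm <- matrix(rnorm(2 * sample(3:40, 1)), ncol = 2)
    expect_equal(sem_anova(mm), sem_from_differences(mm), tolerance = 1e-12)
  }
  expect_error(sem_anova(matrix(1:2, 1)), "at least 2 subjects")
})

test_that("sem_anova equals the residual mean square of stats::aov", {
  set.seed(10)
  for (r in 1:5) {
    n <- sample(4:15, 1)
    m <- matrix(rnorm(2 * n, sd = 3), ncol = 2)
    d <- data.frame(y = as.vector(m),
                    subj = factor(rep(seq_len(n), 2)),
                    sess = factor(rep(1:2, each = n)))
    fit <- stats::aov(y ~ subj + sess, data = d)
    ms_err <- summary(fit)[[1]]["Residuals", "Mean Sq"]
    expect_equal(sem_anova(m), sqrt(ms_err), tolerance = 1e-10)
  }
})

test_that("SEM is shift-invariant; SEM% scales inversely with the mean", {
  set.seed(11)
  m <- matrix(rnorm(40, mean = 50, sd = 4), ncol = 2)
  expect_equal(sem_anova(m), sem_anova(m + 17.3), tolerance = 1e-12)
  s <- sem_anova(m)
  p1 <- sem_percent(s, colMeans(m))
  p2 <- sem_percent(s, colMeans(m + 50))
  expect_gt(p1, p2)
  expect_equal(p1 / p2, mean(colMeans(m + 50)) / mean(colMeans(m)),
               tolerance = 1e-12)
  expect_warning(expect_true(is.na(sem_percent(1, c(-1, 1)))), "zero")
})

test_that("SEM% reproduces published spatiotemporal worked examples", {
  # cadence, usual pace: SEM 2.92 on session means 109.5 / 111.95 -> 2.6%
  expect_equal(round(sem_percent(2.92, c(109.5, 111.95)), 1), 2.6)
  # cadence, fast pace: SEM 2.51 on 134.9 / 135.3 -> 1.9%
  expect_equal(round(sem_percent(2.51, c(134.9, 135.3)), 1), 1.9)
  expect_equal(sem_percent(0, c(109.5, 111.95)), 0)
})

test_that("ICC cross-check matches the ANOVA SEM under the shared decomposition", {
  # zero between-session error: perfect reliability
  m0 <- cbind(1:6, 1:6)
  icc0 <- icc_cross_check(m0)
  expect_equal(icc0$icc, 1)
  expect_equal(icc0$sem_icc, 0)
  # no subject effect: ICC near zero, SEM_icc near the total SD
  set.seed(12)
  m1 <- matrix(rnorm(2000, sd = 2), ncol = 2)
  icc1 <- icc_cross_check(m1)
  expect_lt(abs(icc1$icc), 0.1)
  expect_equal(icc1$sem_icc, 2, tolerance = 0.15)
  # algebraic identity on random matrices
  for (r in 1:20) {
    mm <- matrix(rnorm(2 * sample(3:30, 1), sd = 3), ncol = 2) +
      rnorm(1, sd = 5)
    expect_lt(abs(sem_anova(mm) - icc_cross_check(mm)$sem_icc) /
                sem_anova(mm), 1e-6)
  }
  # degenerate zero-variance input: ICC undefined
  expect_true(is.na(icc_cross_check(matrix(3, 4, 2))$icc))
})

test_that("stride counts are matched between sessions by earliest-n truncation", {
  f <- data.frame(
    subject = rep("S1", 7),
    session = c(1, 1, 1, 1, 2, 2, 2),
    pass = c(1, 1, 2, 2, 1, 1, 2),
    stride = c(1, 2, 1, 2, 1, 2, 1),
    v = c(10, 20, 30, 40, 1, 2, 3))
  m <- session_matrix(f, "v")
  # 4 vs 3 strides -> both truncated to the 3 earliest
  expect_equal(attr(m, "strides_per_cell")[["S1"]], 3)
  expect_equal(m["S1", "session1"], mean(c(10, 20, 30)))
  expect_equal(m["S1", "session2"], mean(c(1, 2, 3)))
  # a subject missing session 2 is dropped
  f2 <- rbind(f, data.frame(subject = "S2", session = 1, pass = 1,
                            stride = 1, v = 99))
  expect_false("S2" %in% rownames(session_matrix(f2, "v")))
})

test_that("the pipeline recovers the injected between-session error", {
  # angle channels carry a 2-degree between-session offset SD and no
  # other noise; discrete-variable SEM estimates should sit near 2
  cfg <- cohort_config(
    n_subjects = 14, passes_per_session = 2, strides_per_pass = 3,
    seed = 31,
    var_between_session = utils::modifyList(zero_var(),
                                            list(angle_offset = 4)),
    var_between_stride = zero_var())
  rep <- run_pipeline(cfg)
  offs <- rep$kinematic$sem[rep$kinematic$variable %in%
    c("Hip_Sagittal_MaxFlex_Stance", "Hip_Sagittal_MaxExt_Stance",
      "Knee_Sagittal_MaxFlex_Swing", "Ankle_Sagittal_InitialContact",
      "Hip_Frontal_MaxAdd_DLS1", "Knee_Transverse_MidStance")]
  expect_equal(mean(offs), 2, tolerance = 0.3)
  # RMSD shares the same error source and lands in the same band
  expect_equal(mean(rep$rmsd$rmsd), 2, tolerance = 0.5)
  # range-of-motion variables see the offset cancel: much smaller SEM
  roms <- rep$kinematic$sem[grepl("RoM", rep$kinematic$variable)]
  expect_lt(mean(roms), 0.5)
})

test_that("zero injected error gives an all-zero report", {
  rep <- run_pipeline(noise_free_config(n_subjects = 3, strides = 3))
  expect_equal(max(rep$kinematic$sem), 0, tolerance = 1e-9)
  expect_equal(max(rep$rmsd$rmsd), 0, tolerance = 1e-9)
  expect_equal(max(rep$stp$sem), 0, tolerance = 1e-9)
  expect_true(all(rep$kinematic$band == "good (<2 deg)"))
  # report shape: full registry and all spatiotemporal parameters
  expect_equal(nrow(rep$kinematic), 32)
  expect_equal(nrow(rep$stp), 15)
  expect_equal(nrow(rep$rmsd), 9)
})
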