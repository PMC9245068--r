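test_that("coordinate-based detection finds the analytic peaks of a sinusoid", {
  t <- (0:299) / 60
  s <- sin(2 * pi * t / 1.0)     # heel - sacrum, 1 s stride
  sac <- rep(0, 300)
  ev <- detect_events_cb(s, -s, sac, progression_sign = 1)
  expect_equal(ev$ic, c(15, 75, 135, 195, 255))
  # reversed progression: IC at the minima of the raw difference
  ev2 <- detect_events_cb(s, -s, sac, progression_sign = -1)
  expect_equal(ev2$ic, c(45, 105, 165, 225, 285))
})

test_that("detection is invariant to a constant shift of all AP channels", {
  coh <- generate_cohort(noise_free_config())
  tr <- coh$trials[[1]]
  ev <- detect_gait_events(tr, "R")
  tr2 <- tr
  for (nm in grep("\\.AP$", names(tr2$landmarks), value = TRUE)) {
    tr2$landmarks[[nm]] <- tr2$landmarks[[nm]] + 3.7
  }
  ev2 <- detect_gait_events(tr2, "R")
  expect_identical(ev$ic, ev2$ic)
  expect_identical(ev$to, ev2$to)
})

test_that("peak finder matches an independent implementation on smooth signals", {
  skip_if_not_installed("pracma")
  set.seed(2)
  for (r in 1:5) {
    t <- seq(0, 8, by = 1 / 60)
    x <- sin(2 * pi * t / runif(1, 0.9, 1.3)) + 0.05 * sin(7 * t)
    ours <- find_local_maxima(x, refractory_frac = 0)
    ref <- pracma::findpeaks(x)[, 2]
    expect_setequal(ours, sort(ref) - 1)
  }
})

test_that("fewer than two initial contacts raises an insufficient-strides error", {
  x <- c(0, 1, 0, -1, 0)  # single peak
  expect_error(detect_events_cb(x, -x, rep(0, 5), progression_sign = 1),
               "insufficient strides")
  tr <- generate_cohort(noise_free_config())$trials[[1]]
  tr$landmarks[["R.heel.AP"]] <- NULL
  expect_error(detect_gait_events(tr, "R"), "R.heel.AP")
})

test_that("stride segmentation pairs events and reports exclusions", {
  mk <- function(ic, to) structure(list(ic = ic, to = to, fs = 60),
                                   class = "gait_events")
  ipsi <- mk(c(0, 66, 132), c(40, 106))
  contra <- mk(c(33, 99), c(10, 76, 142))
  st <- segment_strides(ipsi, contra, fs = 60)
  expect_equal(st$ic_start, c(0, 66))
  expect_equal(st$to, c(40, 106))
  expect_equal(st$contra_ic, c(33, 99))
  expect_equal(st$stride_time, c(1.1, 1.1))

  # a window lacking a contralateral IC is excluded, with a reason
  contra2 <- mk(c(33), c(10, 76))
  st2 <- segment_strides(ipsi, contra2, fs = 60)
  expect_equal(nrow(st2), 1)
  ex <- attr(st2, "exclusions")
  expect_match(ex$reason, "contralateral IC")
})

test_that("stride count equals ipsilateral ICs minus one minus discarded", {
  for (seed in c(2, 8)) {
    coh <- generate_cohort(small_noisy_config(seed = seed, n_subjects = 2,
                                              passes = 1))
    for (tr in coh$trials) {
      dom <- tr$dominant_side
      oth <- if (dom == "L") "R" else "L"
      ev_i <- detect_gait_events(tr, dom)
      ev_c <- detect_gait_events(tr, oth)
      st <- segment_strides(ev_i, ev_c)
      ex <- attr(st, "exclusions")
      expect_equal(nrow(st), length(ev_i$ic) - 1 - nrow(ex))
    }
  }
})

test_that("quality rules drop implausible strides with logged reasons", {
  mk <- function(ic, to) structure(list(ic = ic, to = to, fs = 60),
                                   class = "gait_events")
  # last stride twice as long as the median
  ipsi <- mk(c(0, 60, 120, 180, 300), c(40, 100, 160, 260))
  contra <- mk(c(30, 90, 150, 240), c(15, 75, 135, 200))
  st <- segment_strides(ipsi, contra, fs = 60)
  expect_false(5 %in% st$stride)
  expect_true(any(grepl("40%", attr(st, "exclusions")$reason)))
})

test_that("time normalization matches an independent interpolation oracle", {
  # nearest-two-sample linear interpolation, coded independently
  interp_oracle <- function(x, a, b, n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      pos <- a + (b - a) * (i - 1) / (n - 1)
      lo <- floor(pos); hi <- ceiling(pos)
      w <- pos - lo
      out[i] <- (1 - w) * x[lo + 1] + if (hi > lo) w * x[hi + 1] else 0
    }
    out
  }
  set.seed(3)
  for (r in 1:20) {
    x <- rnorm(120)
    a <- sample(0:20, 1); b <- a + sample(40:80, 1)
    got <- time_normalize(x, a, b, 101)
    expect_equal(got, interp_oracle(x, a, b, 101), tolerance = 1e-9)
    expect_identical(got[1], x[a + 1])     # endpoints preserved exactly
    expect_identical(got[101], x[b + 1])
  }
  expect_equal(time_normalize(rep(7, 50), 0, 49), rep(7, 101))
  ramp <- seq(0, 1, length.out = 61)
  expect_equal(time_normalize(ramp, 0, 60), seq(0, 1, length.out = 101),
               tolerance = 1e-12)
  expect_error(time_normalize(ramp, 5, 5), "at least 2 samples")
})

test_that("stance fraction matches ground truth within one sample's phase", {
  coh <- generate_cohort(noise_free_config(strides = 4))
  gt <- coh$ground_truth$strides
  for (tr in coh$trials) {
    dom <- tr$dominant_side
    oth <- if (dom == "L") "R" else "L"
    st <- segment_strides(detect_gait_events(tr, dom),
                          detect_gait_events(tr, oth))
    g <- gt[gt$trial_id == tr$trial_id, ]
    tol <- 1 / min(st$ic_end - st$ic_start)
    expect_equal(st$stance_fraction, g$stance_fraction[st$stride],
                 tolerance = 2 * tol, ignore_attr = TRUE)
  }
})
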