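# Shared fixtures: small cohort configurations built in code.

# all variance components zero -> bit-reproducible, noise-free gait
zero_var <- function() {
  vars <- c("gait_speed", "stride_length", "step_width", "stance_fraction",
            "contra_offset", "angle_offset", "angle_scale")
  stats::setNames(as.list(rep(0, length(vars))), vars)
}

noise_free_config <- function(n_subjects = 2, passes = 1, strides = 3,
                              seed = 1, task = "SSWS", ...) {
  cohort_config(task = task, n_subjects = n_subjects,
                passes_per_session = passes, strides_per_pass = strides,
                seed = seed,
                var_between_subject = zero_var(),
                var_between_session = zero_var(),
                var_between_stride = zero_var(), ...)
}

small_noisy_config <- function(n_subjects = 4, passes = 2, strides = 3,
                               seed = 11, ...) {
  cohort_config(n_subjects = n_subjects, passes_per_session = passes,
                strides_per_pass = strides, seed = seed, ...)
}

# independent exhaustive-scan oracle for discrete extraction
scan_oracle <- function(curve, spec, windows) {
  ph <- seq(0, 1, length.out = length(curve))
  w <- windows[[spec$window]]
  if (spec$reducer == "range") {
    vals <- curve
    return(max(vals) - min(vals))
  }
  if (spec$reducer == "value_at_point") {
    d <- abs(ph - w[1])
    return(curve[order(d)[1]])
  }
  vals <- curve[ph >= w[1] & ph <= w[2]]
  if (spec$reducer == "max") max(vals) else min(vals)
}

random_phase_windows <- function() {
  to <- stats::runif(1, 0.55, 0.72)
  cic <- stats::runif(1, 0.40, to - 0.05)
  cto <- stats::runif(1, 0.05, cic - 0.1)
  phase_windows(to, cic, cto)
}
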