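# Synthetic two-session gait cohorts with a known variance hierarchy.
# Every downstream stage (event detection, feature extraction, reliability)
# can be validated against the ground truth this module returns.

#' Deterministic seed for a named random stream
#'
#' Derives a 32-bit seed from a base seed and a sequence of labels
#' (e.g. subject index, session, pass) so that each unit of the simulation
#' has its own reproducible stream: adding subjects to a cohort does not
#' perturb the draws of existing subjects.
#'
#' @param seed Base integer seed.
#' @param ... Labels (coerced to character) identifying the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, ...) {
  toks <- unlist(lapply(list(...), as.character), use.names = FALSE)
  codes <- unlist(lapply(toks, utf8ToInt), use.names = FALSE)
  h <- as.double(seed) %% 2147483647
  for (v in c(codes, 17L)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# population-scale presets per walking task (units: m/s, m, m, fraction of
# cycle); magnitudes follow published healthy-adult values for self-selected
# (SSWS) and fastest-comfortable (FCWS) walking speed
task_presets <- function(task) {
  switch(task,
    SSWS = list(gait_speed = 1.35, stride_length = 1.43, step_width = 0.19,
                stance_fraction = 0.667, contra_offset = 0.5),
    FCWS = list(gait_speed = 1.95, stride_length = 1.68, step_width = 0.22,
                stance_fraction = 0.644, contra_offset = 0.5),
    stop("unknown task: ", task))
}

# hard physical bounds used when truncating Gaussian draws
.gait_bounds <- list(
  gait_speed      = c(0.2, 4),
  stride_length   = c(0.3, 3),
  step_width      = c(0.01, 0.6),
  stance_fraction = c(0.42, 0.82),
  contra_offset   = c(0.30, 0.70),
  angle_offset    = c(-Inf, Inf),
  angle_scale     = c(0.2, 3)
)

#' Configuration for a synthetic two-session gait cohort
#'
#' Defines the cohort structure (subjects, sessions, passes, strides), the
#' population means of the spatiotemporal primitives, and the variance
#' hierarchy from which subject-, session-, and stride-level values are
#' drawn. The session-level variance is the ground-truth squared
#' measurement error that the reliability stage is expected to recover.
#'
#' Spatiotemporal primitives are `gait_speed` (m/s), `stride_length` (m),
#' `step_width` (m), `stance_fraction` and `contra_offset` (fractions of
#' the gait cycle); stride time, stance/swing and double/single support
#' times, cadence and step measures all follow from them. Angle channels
#' carry an additive offset (`angle_offset`, degrees) and a multiplicative
#' excursion scale (`angle_scale`, dimensionless around 1), each with its
#' own hierarchy.
#'
#' @param task `"SSWS"` (self-selected) or `"FCWS"` (fastest-comfortable
#'   walking speed); sets the spatiotemporal population means.
#' @param n_subjects Number of subjects (>= 2).
#' @param passes_per_session Walking passes per subject per session
#'   (default 7, i.e. six to eight passes).
#' @param strides_per_pass Full strides per pass on the analysis side
#'   (default 4; within-session stride counts per pass are rarely reported,
#'   and 4 clean strides per 10 m pass is typical).
#' @param sampling_rate Sampling rate in Hz (default 60).
#' @param leg_length Leg length in meters (default 0.84).
#' @param dominant_side `"L"` or `"R"`; the analysis side.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @param stp_means Named list overriding the task preset means.
#' @param var_between_subject,var_between_session,var_between_stride Named
#'   lists of variances (units squared) per variable; unnamed entries keep
#'   the defaults. Set all entries of a level to 0 for noise-free cohorts.
#' @param speed_length_coupling Slope (m per m/s) tying the stride-length
#'   deviation to the speed deviation at every level of the hierarchy;
#'   faster walkers take longer strides, which compresses the spread of
#'   the derived stride time relative to independent draws. `0` makes the
#'   draws independent.
#' @param template_coefficients Joint-angle templates, see
#'   [default_template_coefficients()].
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_subjects = 3, seed = 42)
#' @export
cohort_config <- function(task = c("SSWS", "FCWS"),
                          n_subjects = 21,
                          passes_per_session = 7,
                          strides_per_pass = 4,
                          sampling_rate = 60,
                          leg_length = 0.84,
                          dominant_side = "R",
                          seed = 1,
                          stp_means = list(),
                          var_between_subject = list(),
                          var_between_session = list(),
                          var_between_stride = list(),
                          speed_length_coupling = 0.55,
                          template_coefficients = default_template_coefficients()) {
  task <- match.arg(task)
  means <- utils::modifyList(task_presets(task), stp_means)

  v_subj <- utils::modifyList(list(
    gait_speed = 0.26^2, stride_length = 0.19^2, step_width = 0.055^2,
    stance_fraction = 0.018^2, contra_offset = 0.004^2,
    angle_offset = 3.0^2, angle_scale = 0.05^2), var_between_subject)
  v_sess <- utils::modifyList(list(
    gait_speed = 0.07^2, stride_length = 0.06^2, step_width = 0.018^2,
    stance_fraction = 0.008^2, contra_offset = 0.003^2,
    angle_offset = 1.5^2, angle_scale = 0.02^2), var_between_session)
  v_strd <- utils::modifyList(list(
    gait_speed = 0.035^2, stride_length = 0.03^2, step_width = 0,
    stance_fraction = 0, contra_offset = 0,
    angle_offset = 1.0^2, angle_scale = 0.012^2), var_between_stride)

  for (v in list(v_subj, v_sess, v_strd)) {
    if (any(unlist(v) < 0)) stop("all variances must be >= 0")
  }
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  stopifnot(dominant_side %in% c("L", "R"),
            passes_per_session >= 1, strides_per_pass >= 1)

  structure(list(
    task = task, n_subjects = n_subjects,
    passes_per_session = passes_per_session,
    strides_per_pass = strides_per_pass,
    sampling_rate = sampling_rate, leg_length = leg_length,
    dominant_side = dominant_side, seed = as.integer(seed),
    stp_means = means,
    var_between_subject = v_subj, var_between_session = v_sess,
    var_between_stride = v_strd,
    speed_length_coupling = speed_length_coupling,
    template_coefficients = template_coefficients
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> task=%s  %d subjects x 2 sessions x %d passes x %d strides @ %g Hz, seed %d\n",
              x$task, x$n_subjects, x$passes_per_session, x$strides_per_pass,
              x$sampling_rate, x$seed))
  invisible(x)
}

# truncated normal draw by rejection; bounded retries so truncation can
# never silently distort the distribution
draw_trunc <- function(n, mean, sd, lo, hi, max_retry = 100) {
  mean <- rep_len(mean, n)
  x <- stats::rnorm(n, mean, sd)
  for (r in seq_len(max_retry)) {
    bad <- x < lo | x > hi
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd)
  }
  stop("could not draw values inside [", lo, ", ", hi,
       "] after ", max_retry, " retries (mean=", mean, ", sd=", sd, ")")
}

draw_level <- function(base, sds, bounds_key, n = 1) {
  b <- .gait_bounds[[bounds_key]]
  draw_trunc(n, base, sds, b[1], b[2])
}

# correlated speed/length draws: faster walkers (sessions, strides) take
# longer strides, so the stride-length deviation is `coupling` times the
# speed deviation plus an independent residual. Keeps the marginal SDs at
# the configured values while giving stride time (= length/speed) the
# compressed spread seen in real cohorts.
draw_speed_length <- function(n, base_v, base_l, sd_v, sd_l, coupling,
                              max_retry = 100) {
  bv <- .gait_bounds$gait_speed
  bl <- .gait_bounds$stride_length
  sd_resid <- sqrt(max(0, sd_l^2 - (coupling * sd_v)^2))
  draw_pair <- function(m, idx) {
    dv <- stats::rnorm(m, 0, sd_v)
    dl <- coupling * dv + stats::rnorm(m, 0, sd_resid)
    cbind(rep_len(base_v, n)[idx] + dv, rep_len(base_l, n)[idx] + dl)
  }
  x <- draw_pair(n, seq_len(n))
  for (r in seq_len(max_retry)) {
    bad <- x[, 1] < bv[1] | x[, 1] > bv[2] | x[, 2] < bl[1] | x[, 2] > bl[2]
    if (!any(bad)) return(list(gait_speed = x[, 1], stride_length = x[, 2]))
    x[bad, ] <- draw_pair(sum(bad), which(bad))
  }
  stop("could not draw speed/length pairs inside physical bounds after ",
       max_retry, " retries")
}

# all 18 angle channels: side x joint x plane
angle_channels <- function() {
  g <- expand.grid(side = c("L", "R"), joint = c("hip", "knee", "ankle"),
                   plane = c("sagittal", "frontal", "transverse"),
                   stringsAsFactors = FALSE)
  g$channel <- paste(g$side, g$joint, g$plane, sep = ".")
  g
}

#' Generate a synthetic two-session gait cohort
#'
#' Simulates every walking pass of a two-session cohort as a fully
#' synchronized set of joint-angle and landmark signals, kinematically
#' consistent with per-stride spatiotemporal draws: the heel advances by
#' the drawn stride length each stride, heel-minus-sacrum fore-aft position
#' peaks exactly at ground-truth initial contact, toe-minus-sacrum troughs
#' at ground-truth toe-off, and the contralateral limb is phase-shifted by
#' the contralateral offset (about 50% of the cycle).
#'
#' Values are drawn from an additive Gaussian hierarchy: subject mean,
#' plus an independent session offset per session (variance
#' `var_between_session` — the injected measurement error), plus a
#' stride-level draw where applicable. Stance fraction, contralateral
#' offset and step width vary at subject/session level only, keeping the
#' landmark signals smooth within a pass.
#'
#' @param config A [cohort_config()].
#' @return A list of class `gait_cohort` with elements
#'   \describe{
#'     \item{trials}{list of `motion_trial` objects (one per subject x
#'       session x pass);}
#'     \item{ground_truth}{list with `events` (per-trial true event times in
#'       continuous sample units), `strides` (per-stride drawn and derived
#'       spatiotemporal values), and `sessions` (subject x session level
#'       values of every primitive);}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 2, passes_per_session = 1))
#' length(coh$trials)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  chans <- angle_channels()
  stp_vars <- c("gait_speed", "stride_length", "step_width",
                "stance_fraction", "contra_offset")

  trials <- list()
  gt_events <- list()
  gt_strides <- list()
  gt_sessions <- list()

  for (i in seq_len(cf$n_subjects)) {
    sid <- sprintf("S%02d", i)
    set.seed(stream_seed(cf$seed, cf$task, "subject", i))
    subj <- draw_speed_length(
      1, cf$stp_means$gait_speed, cf$stp_means$stride_length,
      sqrt(cf$var_between_subject$gait_speed),
      sqrt(cf$var_between_subject$stride_length),
      cf$speed_length_coupling)
    for (v in setdiff(stp_vars, names(subj))) {
      subj[[v]] <- draw_level(cf$stp_means[[v]],
                              sqrt(cf$var_between_subject[[v]]), v)
    }
    subj_ang_off <- stats::rnorm(nrow(chans), 0,
                                 sqrt(cf$var_between_subject$angle_offset))
    subj_ang_scl <- draw_trunc(nrow(chans), 1,
                               sqrt(cf$var_between_subject$angle_scale),
                               .gait_bounds$angle_scale[1],
                               .gait_bounds$angle_scale[2])

    for (j in 1:2) {
      set.seed(stream_seed(cf$seed, cf$task, "session", i, j))
      sess <- draw_speed_length(
        1, subj$gait_speed, subj$stride_length,
        sqrt(cf$var_between_session$gait_speed),
        sqrt(cf$var_between_session$stride_length),
        cf$speed_length_coupling)
      for (v in setdiff(stp_vars, names(sess))) {
        sess[[v]] <- draw_level(subj[[v]],
                                sqrt(cf$var_between_session[[v]]), v)
      }
      sess_ang_off <- subj_ang_off +
        stats::rnorm(nrow(chans), 0, sqrt(cf$var_between_session$angle_offset))
      sess_ang_scl <- draw_trunc(nrow(chans), subj_ang_scl,
                                 sqrt(cf$var_between_session$angle_scale),
                                 .gait_bounds$angle_scale[1],
                                 .gait_bounds$angle_scale[2])

      gt_sessions[[length(gt_sessions) + 1]] <- data.frame(
        subject = sid, session = j, task = cf$task,
        variable = c(stp_vars, "stride_time", "stance_time", "swing_time",
                     "dls1_time", "dls2_time", "sls_time", "step_time",
                     "cadence", "step_length"),
        value = {
          Tm <- sess$stride_length / sess$gait_speed
          c(unlist(sess[stp_vars], use.names = FALSE),
            Tm,
            sess$stance_fraction * Tm,
            (1 - sess$stance_fraction) * Tm,
            (sess$contra_offset + sess$stance_fraction - 1) * Tm,
            (sess$stance_fraction - sess$contra_offset) * Tm,
            (1 - sess$stance_fraction) * Tm,
            (1 - sess$contra_offset) * Tm,
            120 / Tm,
            sess$stride_length * (1 - cos(2 * pi * sess$contra_offset)) / 4)
        },
        stringsAsFactors = FALSE)

      for (p in seq_len(cf$passes_per_session)) {
        set.seed(stream_seed(cf$seed, cf$task, "pass", i, j, p))
        K <- cf$strides_per_pass
        vl <- draw_speed_length(
          K, sess$gait_speed, sess$stride_length,
          sqrt(cf$var_between_stride$gait_speed),
          sqrt(cf$var_between_stride$stride_length),
          cf$speed_length_coupling)
        v_k <- vl$gait_speed
        L_k <- vl$stride_length
        strd_ang_off <- matrix(
          stats::rnorm(K * nrow(chans), 0,
                       sqrt(cf$var_between_stride$angle_offset)),
          nrow = K)
        strd_ang_scl <- matrix(
          stats::rnorm(K * nrow(chans), 0,
                       sqrt(cf$var_between_stride$angle_scale)),
          nrow = K)

        tr <- synth_trial(
          subject_id = sid, session = j, pass = p, config = cf,
          sess = sess, v_k = v_k, L_k = L_k,
          ang_off = sweep(strd_ang_off, 2, sess_ang_off, "+"),
          ang_scl = sweep(strd_ang_scl, 2, sess_ang_scl, "+"),
          direction = if (p %% 2 == 1) 1 else -1)

        trials[[length(trials) + 1]] <- tr$trial
        gt_events[[length(gt_events) + 1]] <- tr$events
        gt_strides[[length(gt_strides) + 1]] <- tr$strides
      }
    }
  }

  structure(list(
    trials = trials,
    ground_truth = list(
      events = do.call(rbind, gt_events),
      strides = do.call(rbind, gt_strides),
      sessions = do.call(rbind, gt_sessions)),
    config = cf
  ), class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %s: %d trials (%d subjects x 2 sessions x %d passes), %g Hz\n",
              x$config$task, length(x$trials), x$config$n_subjects,
              x$config$passes_per_session, x$config$sampling_rate))
  invisible(x)
}

# Build one walking pass. All positions are first constructed in a
# progression-aligned frame (walking towards +AP), then mirrored onto the
# 10 m walkway when the pass runs in the return direction.
synth_trial <- function(subject_id, session, pass, config, sess,
                        v_k, L_k, ang_off, ang_scl, direction) {
  cf <- config
  fs <- cf$sampling_rate
  K <- length(v_k)
  chans <- angle_channels()
  T_k <- L_k / v_k
  if (any(!is.finite(T_k)) || any(T_k <= 0)) {
    stop("non-positive stride time drawn for ", subject_id)
  }
  Tbar <- sess$stride_length / sess$gait_speed
  vbar <- sess$gait_speed
  sf <- sess$stance_fraction
  off <- sess$contra_offset
  W <- sess$step_width

  # snap the lead-in so the first initial contact falls on the sample grid
  pre <- round(0.75 * Tbar * fs) / fs
  post <- pre
  knot_t <- c(0, pre + c(0, cumsum(T_k)), pre + sum(T_k) + post)
  knot_phi <- c(-pre / Tbar, 0:K, K + post / Tbar)
  knot_pos <- c(0, vbar * pre + c(0, cumsum(L_k)),
                vbar * pre + sum(L_k) + vbar * post)

  n <- floor(knot_t[length(knot_t)] * fs) + 1
  t <- (seq_len(n) - 1) / fs
  phi <- stats::approx(knot_t, knot_phi, t, rule = 2)$y
  sacrum_ap <- stats::approx(knot_t, knot_pos, t, rule = 2)$y

  A_h <- sess$stride_length / 4
  A_t <- 0.9 * A_h
  dom <- cf$dominant_side
  other <- if (dom == "L") "R" else "L"
  phis <- list()
  phis[[dom]] <- phi
  phis[[other]] <- phi - off

  landmarks <- list()
  for (s in c("L", "R")) {
    ph <- phis[[s]]
    ml_sign <- if (s == "R") 1 else -1
    landmarks[[paste0(s, ".heel.AP")]] <- sacrum_ap + A_h * cos(2 * pi * ph)
    landmarks[[paste0(s, ".toe.AP")]] <-
      sacrum_ap + 0.12 - A_t * cos(2 * pi * (ph - sf))
    landmarks[[paste0(s, ".heel.ML")]] <- rep(ml_sign * W / 2, n)
    landmarks[[paste0(s, ".toe.ML")]] <- rep(ml_sign * W / 2, n)
    landmarks[[paste0(s, ".heel.vertical")]] <-
      0.03 + 0.035 * (1 - cos(2 * pi * (ph - sf))) / 2
    landmarks[[paste0(s, ".toe.vertical")]] <-
      0.02 + 0.060 * (1 - cos(2 * pi * (ph - sf - 0.1))) / 2
  }
  landmarks[["pelvis.sacrum.AP"]] <- sacrum_ap
  landmarks[["pelvis.sacrum.ML"]] <- 0.015 * sin(2 * pi * phi)
  landmarks[["pelvis.sacrum.vertical"]] <- 0.92 + 0.015 * cos(4 * pi * phi)

  # per-stride angle offset/scale varies smoothly, interpolated across
  # stride midpoints so signals stay continuous at stride boundaries
  mid_phi <- seq_len(K) - 0.5
  angles <- list()
  for (c_i in seq_len(nrow(chans))) {
    ch <- chans[c_i, ]
    ph <- phis[[ch$side]]
    if (K > 1) {
      o <- stats::approx(mid_phi, ang_off[, c_i], ph, rule = 2)$y
      m <- stats::approx(mid_phi, ang_scl[, c_i], ph, rule = 2)$y
    } else {
      o <- rep(ang_off[1, c_i], n)
      m <- rep(ang_scl[1, c_i], n)
    }
    angles[[ch$channel]] <- o + m *
      joint_angle_template(ch$joint, ch$plane, ph %% 1,
                           cf$template_coefficients)
  }

  # mirror onto the walkway for return passes
  if (direction < 0) {
    for (nm in grep("\\.AP$", names(landmarks), value = TRUE)) {
      landmarks[[nm]] <- 10 - landmarks[[nm]]
    }
    for (nm in grep("\\.ML$", names(landmarks), value = TRUE)) {
      landmarks[[nm]] <- -landmarks[[nm]]
    }
  }

  trial_id <- sprintf("%s_s%d_p%02d", subject_id, session, pass)
  trial <- structure(list(
    trial_id = trial_id, subject_id = subject_id, session = session,
    pass = pass, task = cf$task, sampling_rate = fs,
    leg_length = cf$leg_length, dominant_side = dom,
    progression_sign = direction, n_samples = n,
    angles = angles, landmarks = landmarks
  ), class = "motion_trial")

  # ground-truth events (continuous 0-based sample units)
  phi_of <- function(x) stats::approx(knot_phi, knot_t, x)$y
  ev <- list()
  add_ev <- function(side, type, ph) {
    tt <- phi_of(ph)
    keep <- !is.na(tt) & tt * fs >= 1 & tt * fs <= n - 2
    if (any(keep)) {
      data.frame(trial_id = trial_id, subject_id = subject_id,
                 session = session, pass = pass, side = side, type = type,
                 phi = ph[keep], time_s = tt[keep], sample = tt[keep] * fs,
                 stringsAsFactors = FALSE)
    }
  }
  ev[[1]] <- add_ev(dom, "IC", 0:K)
  ev[[2]] <- add_ev(dom, "TO", (-1:K) + sf)
  ev[[3]] <- add_ev(other, "IC", (-1:K) + off)
  ev[[4]] <- add_ev(other, "TO", (-1:K) + off + sf - 1)
  events <- do.call(rbind, ev)

  strides <- data.frame(
    trial_id = trial_id, subject_id = subject_id, session = session,
    pass = pass, task = cf$task, stride = seq_len(K),
    stride_time = T_k, stride_length = L_k, gait_speed = v_k,
    stance_fraction = sf, contra_offset = off, step_width = W,
    stance_time = sf * T_k, swing_time = (1 - sf) * T_k,
    dls1_time = (off + sf - 1) * T_k, dls2_time = (sf - off) * T_k,
    sls_time = (1 - sf) * T_k, step_time = (1 - off) * T_k,
    cadence = 120 / T_k,
    step_length = sess$stride_length * (1 - cos(2 * pi * off)) / 4,
    stringsAsFactors = FALSE)

  list(trial = trial, events = events, strides = strides)
}

#' Simulate a subject-by-session matrix from the cohort variance hierarchy
#'
#' Draws the subject/session levels of the generator's additive Gaussian
#' hierarchy directly, without signal synthesis: each subject has a true
#' mean `mean + N(0, sd_subject^2)` and each session measurement adds an
#' independent `N(0, sd_session^2)` error. Used to validate the SEM
#' estimator at scale.
#'
#' @param n_subjects Number of subjects.
#' @param sd_subject Between-subject SD (units of the variable).
#' @param sd_session Between-session (measurement error) SD.
#' @param mean Population mean.
#' @param n_sessions Number of sessions (default 2).
#' @param seed Optional integer seed.
#' @return Matrix `n_subjects x n_sessions`.
#' @export
simulate_session_matrix <- function(n_subjects, sd_subject, sd_session,
                                    mean = 0, n_sessions = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subj <- mean + stats::rnorm(n_subjects, 0, sd_subject)
  err <- matrix(stats::rnorm(n_subjects * n_sessions, 0, sd_session),
                n_subjects, n_sessions)
  subj + err
}
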