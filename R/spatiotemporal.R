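# Spatiotemporal gait parameters per stride from event indices and
# landmark trajectories.

#' Spatiotemporal parameters for each stride of a trial
#'
#' Computes, for every segmented stride of the analysis side:
#' temporal parameters from the event indices (stride, stance, swing,
#' double- and single-limb support, and step times; cadence as
#' `120 / stride_time`, i.e. steps per minute assuming step symmetry),
#' and spatial parameters from the progression-aligned landmark
#' trajectories (stride length from heel fore-aft advance between
#' consecutive initial contacts; step length as ipsilateral minus
#' contralateral heel fore-aft position at ipsilateral initial contact;
#' step width as absolute heel mediolateral separation at the same
#' instant; gait speed as sacrum fore-aft displacement over the stride
#' divided by stride time). Speed and length parameters are additionally
#' normalized by leg length (`*_ll` columns, dimensionless multiples of
#' leg length per second or leg lengths).
#'
#' Time-partition identities hold exactly on every stride:
#' `stride_time == stance_time + swing_time` and
#' `stance_time == dls1_time + sls_time + dls2_time`.
#'
#' @param trial A `motion_trial`.
#' @param strides Output of [segment_strides()] for the dominant side.
#' @param leg_length Leg length in meters (default from the trial).
#' @return Data frame, one row per stride, with columns `stride`,
#'   `stride_time`, `stance_time`, `swing_time`, `dls1_time`, `dls2_time`,
#'   `sls_time`, `step_time`, `stride_length`, `step_length`,
#'   `step_width`, `gait_speed`, `cadence`, `gait_speed_ll`,
#'   `stride_length_ll`, `step_length_ll`.
#' @export
compute_stp <- function(trial, strides, leg_length = trial$leg_length) {
  stopifnot(inherits(trial, "motion_trial"))
  fs <- trial$sampling_rate
  dom <- trial$dominant_side
  other <- if (dom == "L") "R" else "L"
  sgn <- trial$progression_sign
  val <- function(ch, idx0) trial$landmarks[[ch]][idx0 + 1]

  heel_i <- paste0(dom, ".heel.AP")
  heel_c <- paste0(other, ".heel.AP")
  heel_i_ml <- paste0(dom, ".heel.ML")
  heel_c_ml <- paste0(other, ".heel.ML")
  need <- c(heel_i, heel_c, heel_i_ml, heel_c_ml, "pelvis.sacrum.AP")
  miss <- setdiff(need, names(trial$landmarks))
  if (length(miss)) stop("missing landmark channel(s): ",
                         paste(miss, collapse = ", "))

  st <- strides
  stride_time <- (st$ic_end - st$ic_start) / fs
  stance_time <- (st$to - st$ic_start) / fs
  swing_time <- stride_time - stance_time
  dls1_time <- (st$contra_to - st$ic_start) / fs
  dls2_time <- (st$to - st$contra_ic) / fs
  sls_time <- stance_time - dls1_time - dls2_time
  step_time <- (st$ic_end - st$contra_ic) / fs

  stride_length <- abs(val(heel_i, st$ic_end) - val(heel_i, st$ic_start))
  step_length <- sgn * (val(heel_i, st$ic_start) - val(heel_c, st$ic_start))
  step_width <- abs(val(heel_i_ml, st$ic_start) - val(heel_c_ml, st$ic_start))
  gait_speed <- sgn * (val("pelvis.sacrum.AP", st$ic_end) -
                         val("pelvis.sacrum.AP", st$ic_start)) / stride_time

  data.frame(
    stride = st$stride,
    stride_time = stride_time, stance_time = stance_time,
    swing_time = swing_time, dls1_time = dls1_time, dls2_time = dls2_time,
    sls_time = sls_time, step_time = step_time,
    stride_length = stride_length, step_length = step_length,
    step_width = step_width, gait_speed = gait_speed,
    cadence = 120 / stride_time,
    gait_speed_ll = gait_speed / leg_length,
    stride_length_ll = stride_length / leg_length,
    step_length_ll = step_length / leg_length)
}

#' Names of the spatiotemporal parameters
#'
#' @return Character vector of the 15 spatiotemporal parameter names
#'   produced by [compute_stp()].
#' @export
stp_variables <- function() {
  c("gait_speed", "gait_speed_ll", "cadence", "stride_time", "stance_time",
    "dls1_time", "dls2_time", "sls_time", "swing_time", "stride_length",
    "stride_length_ll", "step_time", "step_length", "step_length_ll",
    "step_width")
}

#' Units of the spatiotemporal parameters
#'
#' @return Named character vector mapping each spatiotemporal parameter to
#'   its unit. Leg-length-normalized variables are reported as
#'   dimensionless multiples of leg length (per second for speed).
#' @export
stp_units <- function() {
  c(gait_speed = "m/s", gait_speed_ll = "LL/s", cadence = "steps/min",
    stride_time = "s", stance_time = "s", dls1_time = "s", dls2_time = "s",
    sls_time = "s", swing_time = "s", stride_length = "m",
    stride_length_ll = "LL", step_time = "s", step_length = "m",
    step_length_ll = "LL", step_width = "m")
}
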