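# Coordinate-based gait event detection (heel/toe position relative to the
# sacrum), stride segmentation, and time normalization to the gait cycle.
# Sample indices are 0-based throughout: time_s = index / sampling_rate.

#' Local maxima of a signal with refractory suppression
#'
#' Finds interior local maxima (`x[i] > x[i-1]` and `x[i] >= x[i+1]`; ties
#' broken by the earliest index) and then suppresses maxima closer together
#' than a refractory window, keeping the larger of each offending pair.
#'
#' @param x Numeric signal.
#' @param refractory_frac Refractory window as a fraction of the median
#'   inter-peak interval (default 0.4); `0` disables suppression.
#' @return Integer vector of 0-based sample indices.
#' @keywords internal
find_local_maxima <- function(x, refractory_frac = 0.4) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  pk <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  # collapse flat-top plateaus to their earliest sample
  if (length(pk) > 1) pk <- pk[c(TRUE, diff(pk) > 1 | diff(x[pk]) != 0)]
  if (length(pk) > 2 && refractory_frac > 0) {
    win <- refractory_frac * stats::median(diff(pk))
    repeat {
      gaps <- diff(pk)
      j <- which(gaps < win)
      if (length(j) == 0) break
      j <- j[1]
      drop <- if (x[pk[j + 1]] > x[pk[j]]) j else j + 1
      pk <- pk[-drop]
    }
  }
  as.integer(pk - 1L)
}

#' Coordinate-based gait event detection from landmark signals
#'
#' Implements the coordinate-based variant of heel/toe-referenced event
#' detection: initial contact (IC) occurs at local maxima of the
#' progression-aligned heel-minus-sacrum fore-aft position, and toe-off
#' (TO) at local minima of the toe-minus-sacrum fore-aft position.
#' Detection is invariant to translating all fore-aft channels by a
#' constant, since only differences to the sacrum are used.
#'
#' @param heel_ap,toe_ap,sacrum_ap Fore-aft (anterior-posterior) position
#'   signals in meters, all the same length.
#' @param progression_sign `+1` if the subject walks towards +AP, `-1` for
#'   the return direction; `NULL` to infer from the net sacrum
#'   displacement.
#' @param refractory_frac Passed to [find_local_maxima()].
#' @return List with `ic` and `to`, 0-based sample indices in temporal
#'   order, and the `progression_sign` used.
#' @examples
#' t <- (0:299) / 60
#' s <- sin(2 * pi * t)             # heel - sacrum, 1 s stride
#' ev <- detect_events_cb(s, -s, rep(0, 300), progression_sign = 1)
#' ev$ic                            # 15, 75, 135, ...
#' @export
detect_events_cb <- function(heel_ap, toe_ap, sacrum_ap,
                             progression_sign = NULL,
                             refractory_frac = 0.4) {
  n <- length(sacrum_ap)
  if (length(heel_ap) != n || length(toe_ap) != n) {
    stop("heel, toe and sacrum AP signals must have equal length")
  }
  if (is.null(progression_sign)) {
    d <- sacrum_ap[n] - sacrum_ap[1]
    progression_sign <- if (d >= 0) 1 else -1
  }
  ic <- find_local_maxima(progression_sign * (heel_ap - sacrum_ap),
                          refractory_frac)
  to <- find_local_maxima(-progression_sign * (toe_ap - sacrum_ap),
                          refractory_frac)
  if (length(ic) < 2) {
    stop("insufficient strides: fewer than 2 initial contacts detected")
  }
  list(ic = ic, to = to, progression_sign = progression_sign)
}

#' Zero-lag low-pass Butterworth filter
#'
#' 4th-order zero-lag low-pass filtering (2nd-order Butterworth applied
#' forward and backward), the standard conditioning step for gait
#' kinematics; 6 Hz cutoff by default.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz.
#' @return Filtered signal, same length.
#' @export
lowpass_filter <- function(x, fs, cutoff = 6) {
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect gait events for one side of a motion trial
#'
#' @param trial A `motion_trial`.
#' @param side `"L"` or `"R"`.
#' @param filter_cutoff Low-pass cutoff in Hz applied to the landmark
#'   channels before detection, or `NULL` for no filtering (appropriate
#'   for noise-free synthetic data).
#' @param refractory_frac Passed to [find_local_maxima()].
#' @return Object of class `gait_events`: list with `side`, `ic`, `to`
#'   (0-based sample indices), `fs`.
#' @export
detect_gait_events <- function(trial, side, filter_cutoff = NULL,
                               refractory_frac = 0.4) {
  stopifnot(inherits(trial, "motion_trial"), side %in% c("L", "R"))
  need <- c(paste0(side, ".heel.AP"), paste0(side, ".toe.AP"),
            "pelvis.sacrum.AP")
  miss <- setdiff(need, names(trial$landmarks))
  if (length(miss)) {
    stop("missing landmark channel(s): ", paste(miss, collapse = ", "))
  }
  ch <- lapply(need, function(nm) trial$landmarks[[nm]])
  if (!is.null(filter_cutoff)) {
    ch <- lapply(ch, lowpass_filter, fs = trial$sampling_rate,
                 cutoff = filter_cutoff)
  }
  ev <- detect_events_cb(ch[[1]], ch[[2]], ch[[3]],
                         progression_sign = trial$progression_sign,
                         refractory_frac = refractory_frac)
  structure(list(side = side, ic = ev$ic, to = ev$to,
                 fs = trial$sampling_rate,
                 progression_sign = ev$progression_sign),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> side %s: %d IC, %d TO @ %g Hz\n",
              x$side, length(x$ic), length(x$to), x$fs))
  invisible(x)
}

#' Segment strides from bilateral gait events
#'
#' One stride per consecutive pair of ipsilateral initial contacts. Each
#' stride window keeps the ipsilateral toe-off and the contralateral
#' toe-off and initial contact falling strictly inside it; windows missing
#' any required event are discarded with a reason. Automated quality rules
#' additionally drop strides whose stride time deviates more than 40% from
#' the trial median or whose stance fraction lies outside (0.4, 0.8).
#'
#' @param ipsi_events,contra_events `gait_events` for the analysis and the
#'   opposite side.
#' @param fs Sampling rate (Hz); taken from `ipsi_events` if omitted.
#' @param quality Apply the stride-time / stance-fraction quality rules
#'   (default `TRUE`).
#' @return Data frame with one row per retained stride: `stride`,
#'   `ic_start`, `ic_end`, `to`, `contra_ic`, `contra_to` (0-based sample
#'   indices), `stride_time`, `stance_fraction`. Discarded candidate
#'   windows are recorded in `attr(, "exclusions")` with reasons.
#' @export
segment_strides <- function(ipsi_events, contra_events, fs = ipsi_events$fs,
                            quality = TRUE) {
  ic <- ipsi_events$ic
  to <- ipsi_events$to
  cic <- contra_events$ic
  cto <- contra_events$to
  if (is.unsorted(ic, strictly = TRUE) || is.unsorted(to, strictly = TRUE)) {
    stop("event indices must be strictly increasing")
  }

  rows <- list()
  excl <- list()
  note <- function(k, a, b, reason) {
    excl[[length(excl) + 1]] <<- data.frame(
      stride = k, ic_start = a, ic_end = b, reason = reason,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(length(ic) - 1)) {
    a <- ic[k]; b <- ic[k + 1]
    to_in <- to[to > a & to < b]
    cic_in <- cic[cic > a & cic < b]
    cto_in <- cto[cto > a & cto < b]
    if (length(to_in) != 1) { note(k, a, b, "ipsilateral TO missing or multiple"); next }
    if (length(cic_in) != 1) { note(k, a, b, "contralateral IC missing or multiple"); next }
    if (length(cto_in) != 1) { note(k, a, b, "contralateral TO missing or multiple"); next }
    if (!(cto_in < cic_in && cic_in < to_in)) {
      note(k, a, b, "events out of order within stride"); next
    }
    rows[[length(rows) + 1]] <- data.frame(
      stride = k, ic_start = a, ic_end = b, to = to_in,
      contra_ic = cic_in, contra_to = cto_in,
      stride_time = (b - a) / fs,
      stance_fraction = (to_in - a) / (b - a))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stride = integer(), ic_start = integer(), ic_end = integer(),
               to = integer(), contra_ic = integer(), contra_to = integer(),
               stride_time = numeric(), stance_fraction = numeric())

  if (quality && nrow(out)) {
    med <- stats::median(out$stride_time)
    bad_t <- abs(out$stride_time - med) > 0.4 * med
    bad_s <- out$stance_fraction <= 0.4 | out$stance_fraction >= 0.8
    for (k in which(bad_t)) {
      note(out$stride[k], out$ic_start[k], out$ic_end[k],
           "stride time deviates >40% from trial median")
    }
    for (k in which(bad_s & !bad_t)) {
      note(out$stride[k], out$ic_start[k], out$ic_end[k],
           "stance fraction outside (0.4, 0.8)")
    }
    out <- out[!(bad_t | bad_s), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(stride = integer(), ic_start = integer(), ic_end = integer(),
               reason = character())
  out
}

#' Time-normalize a signal window to the gait cycle
#'
#' Linear interpolation of one stride window onto `n_points` equally
#' spaced phases spanning the two bounding initial contacts (0-100% of the
#' gait cycle); window endpoints are preserved exactly.
#'
#' @param x Full signal vector.
#' @param start_idx,end_idx 0-based sample indices of the bounding
#'   initial contacts (inclusive).
#' @param n_points Number of output points (default 101).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, start_idx, end_idx, n_points = 101) {
  if (end_idx - start_idx < 1) {
    stop("stride window must span at least 2 samples")
  }
  if (end_idx + 1 > length(x) || start_idx < 0) {
    stop("stride window outside signal range")
  }
  idx <- start_idx:end_idx
  stats::approx(idx, x[idx + 1], xout = seq(start_idx, end_idx,
                                            length.out = n_points))$y
}

#' Time-normalized stride curves for one trial side
#'
#' Builds, for every retained stride, the 101-point normalized curve of
#' each requested channel, plus the within-stride phases of the
#' ipsilateral toe-off and the contralateral events needed for phase
#' windows.
#'
#' @param trial A `motion_trial`.
#' @param strides Output of [segment_strides()].
#' @param channels Character vector of angle-channel names (default: all
#'   nine joint/plane channels of the trial's dominant side).
#' @param n_points Points per normalized curve (default 101).
#' @return Object of class `stride_set`: list with `curves` (named list of
#'   strides x `n_points` matrices) and `phases` (data frame with
#'   `stride`, `stance_fraction`, `contra_ic_phase`, `contra_to_phase`).
#' @export
normalize_strides <- function(trial, strides, channels = NULL,
                              n_points = 101) {
  stopifnot(inherits(trial, "motion_trial"))
  if (is.null(channels)) {
    channels <- grep(paste0("^", trial$dominant_side, "\\."),
                     names(trial$angles), value = TRUE)
  }
  miss <- setdiff(channels, names(trial$angles))
  if (length(miss)) stop("unknown angle channel(s): ",
                         paste(miss, collapse = ", "))
  curves <- lapply(channels, function(ch) {
    m <- t(vapply(seq_len(nrow(strides)), function(k)
      time_normalize(trial$angles[[ch]], strides$ic_start[k],
                     strides$ic_end[k], n_points),
      numeric(n_points)))
    if (nrow(strides) == 0) m <- matrix(numeric(0), 0, n_points)
    m
  })
  names(curves) <- channels
  span <- strides$ic_end - strides$ic_start
  phases <- data.frame(
    stride = strides$stride,
    stance_fraction = strides$stance_fraction,
    contra_ic_phase = (strides$contra_ic - strides$ic_start) / span,
    contra_to_phase = (strides$contra_to - strides$ic_start) / span)
  structure(list(curves = curves, phases = phases, n_points = n_points),
            class = "stride_set")
}

#' @export
print.stride_set <- function(x, ...) {
  cat(sprintf("<stride_set> %d strides x %d points, %d channels\n",
              nrow(x$phases), x$n_points, length(x$curves)))
  invisible(x)
}
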