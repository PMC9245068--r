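#' Default Fourier coefficients for joint-angle gait-cycle templates
#'
#' Returns, for every (joint, plane) combination, the coefficients of a
#' truncated Fourier series describing one gait cycle of that joint angle,
#' degrees as a function of gait-cycle phase (0 = ipsilateral initial
#' contact, 1 = next ipsilateral initial contact). The default sets were
#' fitted to reproduce the qualitative shape and range-of-motion magnitudes
#' of healthy adult walking (hip/knee/ankle in sagittal, frontal and
#' transverse planes), e.g. a knee sagittal swing-flexion peak near 64
#' degrees at roughly 73% of the cycle and a hip sagittal range of motion
#' near 46 degrees.
#'
#' Sign convention: flexion/dorsiflexion, adduction, inversion/varus and
#' internal rotation are positive; their opposites are negative.
#'
#' @return A named list, one element per `"<joint>.<plane>"`, each a list
#'   with `a0` (constant term, degrees) and a data frame `harmonics` with
#'   columns `harmonic`, `amplitude` (degrees) and `phase` (radians).
#' @seealso [joint_angle_template()]
#' @export
default_template_coefficients <- function() {
  mk <- function(a0, amplitude, phase) {
    list(a0 = a0,
         harmonics = data.frame(harmonic = seq_along(amplitude),
                                amplitude = amplitude, phase = phase))
  }
  list(
    hip.sagittal = mk(7.326082,
      c(23.712796, 4.152481, 1.279149, 0.117070),
      c(1.694707, -1.712431, -1.215462, -2.748799)),
    knee.sagittal = mk(22.067203,
      c(21.165636, 16.726443, 4.011867, 0.161529),
      c(-3.085447, -1.136176, -0.018755, -2.658760)),
    ankle.sagittal = mk(-3.033105,
      c(10.588155, 8.983923, 5.748898, 2.448763),
      c(-0.223899, 2.708446, -1.809250, 0.673350)),
    hip.frontal = mk(3.015814,
      c(3.540119, 1.459414, 0.630025, 0.507422),
      c(0.462072, -1.217323, -0.645333, -2.175982)),
    knee.frontal = mk(-0.648469,
      c(2.718678, 1.923877, 1.302298, 0.505634),
      c(2.361636, -2.324976, -0.210757, 1.930330)),
    ankle.frontal = mk(1.728787,
      c(5.768945, 1.386423, 2.027924, 1.363709),
      c(-3.022782, -0.173855, 0.716240, 1.264812)),
    hip.transverse = mk(-0.075994,
      c(5.242063, 1.062110, 0.216076, 0.125127),
      c(0.722035, -1.289652, -1.601746, -2.319900)),
    knee.transverse = mk(-8.607378,
      c(0.626410, 3.724509, 3.292063, 2.112624),
      c(-1.324854, 1.259418, 3.072552, -0.798992)),
    ankle.transverse = mk(-2.416904,
      c(9.107107, 1.526250, 1.412897, 1.179512),
      c(0.440911, 2.636887, 0.217670, -2.860878))
  )
}

#' Evaluate a joint-angle template at given gait-cycle phases
#'
#' Evaluates the truncated Fourier series
#' \deqn{\theta(\phi) = a_0 + \sum_j A_j \sin(2\pi j \phi + p_j)}
#' for one joint/plane at the requested phases. The series is periodic by
#' construction, so `joint_angle_template(j, p, 0) ==
#' joint_angle_template(j, p, 1)`.
#'
#' @param joint One of `"hip"`, `"knee"`, `"ankle"`.
#' @param plane One of `"sagittal"`, `"frontal"`, `"transverse"`.
#' @param gait_phase Numeric vector of phases in `[0, 1]` (0 = initial
#'   contact). Values outside `[0, 1]` are wrapped.
#' @param coefficients Coefficient set as produced by
#'   [default_template_coefficients()]; defaults to the built-in templates.
#' @return Numeric vector of joint angles in degrees.
#' @examples
#' joint_angle_template("knee", "sagittal", seq(0, 1, by = 0.01))
#' @export
joint_angle_template <- function(joint, plane, gait_phase,
                                 coefficients = default_template_coefficients()) {
  key <- paste(joint, plane, sep = ".")
  if (!key %in% names(coefficients)) {
    stop("unknown joint/plane combination: '", key, "'", call. = FALSE)
  }
  cf <- coefficients[[key]]
  stopifnot(is.numeric(gait_phase), all(is.finite(cf$harmonics$amplitude)),
            all(is.finite(cf$harmonics$phase)))
  phi <- gait_phase %% 1
  out <- rep(cf$a0, length(phi))
  for (j in seq_len(nrow(cf$harmonics))) {
    out <- out + cf$harmonics$amplitude[j] *
      sin(2 * pi * cf$harmonics$harmonic[j] * phi + cf$harmonics$phase[j])
  }
  out
}
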