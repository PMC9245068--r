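# Absolute reliability between two measurement sessions: full-curve RMSD
# on ensemble-averaged gait curves, and standard error of measurement
# (SEM) of discrete variables via repeated-measures ANOVA.

#' Ensemble-average a set of stride curves
#'
#' Pointwise mean across a subject-session's stride curves.
#'
#' @param curves Matrix strides x points (each row one normalized stride).
#' @return Numeric vector: the mean curve.
#' @export
ensemble_average <- function(curves) {
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1)
  if (nrow(curves) < 1) stop("ensemble average needs at least one stride")
  colMeans(curves)
}

#' Root-mean-square difference between two normalized curves
#'
#' @param curve1,curve2 Numeric vectors of equal length (typically the two
#'   sessions' ensemble-average curves, 101 points).
#' @return RMSD in the units of the curves (degrees for joint angles).
#' @export
rmsd_between_sessions <- function(curve1, curve2) {
  if (length(curve1) != length(curve2)) {
    stop("curves must have equal length (", length(curve1), " vs ",
         length(curve2), ")")
  }
  sqrt(mean((curve1 - curve2)^2))
}

#' Standard error of measurement from a subjects x sessions ANOVA
#'
#' SEM = sqrt(MS_error) of the two-way subjects-by-sessions
#' repeated-measures ANOVA with one observation per cell, where MS_error
#' is the subject-by-session interaction mean square
#' \deqn{MS_e = \sum_{ij} (x_{ij} - \bar x_{i.} - \bar x_{.j} + \bar
#'   x_{..})^2 / ((n-1)(k-1)).}
#' This captures both random error and leaves systematic session shifts to
#' the session main effect, so a uniform between-day offset contributes
#' zero. For two sessions it equals `sd(d)/sqrt(2)` with `d` the
#' per-subject session difference (see [sem_from_differences()]).
#'
#' @param mat Numeric matrix, subjects in rows, sessions in columns; at
#'   least 2 rows and 2 columns, no missing cells.
#' @return SEM in the units of the measurements.
#' @examples
#' m <- cbind(c(10, 20, 30), c(12, 22, 32))
#' sem_anova(m)   # 0: a uniform +2 shift is purely systematic
#' @export
sem_anova <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 sessions")
  if (anyNA(mat)) stop("matrix contains missing cells")
  res <- mat - rowMeans(mat) - rep(colMeans(mat), each = n) + mean(mat)
  sqrt(sum(res^2) / ((n - 1) * (k - 1)))
}

#' SEM from per-subject session differences (two sessions)
#'
#' Closed form of [sem_anova()] for exactly two sessions:
#' `sd(session2 - session1) / sqrt(2)`.
#'
#' @param mat Numeric matrix with exactly 2 columns.
#' @return SEM.
#' @export
sem_from_differences <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 2) stop("difference form requires exactly 2 sessions")
  stats::sd(mat[, 2] - mat[, 1]) / sqrt(2)
}

#' SEM as a percentage of the grand mean
#'
#' `100 * SEM / |grand mean|`, with the grand mean taken as the average of
#' the two session means. Undefined (NA, with a warning) when the grand
#' mean is zero. Reported to one decimal in printed tables; this function
#' returns full precision.
#'
#' @param sem SEM of the variable.
#' @param session_means Numeric vector of the session means.
#' @return SEM%.
#' @examples
#' sem_percent(2.92, c(109.5, 111.95))  # 2.637...
#' @export
sem_percent <- function(sem, session_means) {
  gm <- mean(session_means)
  if (gm == 0) {
    warning("grand mean is zero; SEM% undefined")
    return(NA_real_)
  }
  100 * sem / abs(gm)
}

#' ICC(3,1) and the ICC-based SEM cross-check
#'
#' Two-way mixed, consistency, single-measure intraclass correlation from
#' the same subjects x sessions ANOVA decomposition as [sem_anova()]:
#' `ICC = (MS_subject - MS_error) / (MS_subject + (k-1) MS_error)`, and
#' `SEM_icc = SD * sqrt(1 - ICC)` with `SD^2 = (MS_subject + (k-1)
#' MS_error)/k`, the variance base matching the ICC decomposition. Under
#' this matching decomposition `SEM_icc` equals [sem_anova()]
#' algebraically.
#'
#' @param mat Numeric matrix, subjects x sessions.
#' @return List with `icc`, `sem_icc`, `ms_subject`, `ms_error`. For
#'   degenerate zero-variance input the ICC is `NA`.
#' @export
icc_cross_check <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 sessions")
  ms_subj <- k * sum((rowMeans(mat) - mean(mat))^2) / (n - 1)
  res <- mat - rowMeans(mat) - rep(colMeans(mat), each = n) + mean(mat)
  ms_err <- sum(res^2) / ((n - 1) * (k - 1))
  denom <- ms_subj + (k - 1) * ms_err
  if (denom == 0) {
    return(list(icc = NA_real_, sem_icc = NA_real_,
                ms_subject = ms_subj, ms_error = ms_err))
  }
  icc <- (ms_subj - ms_err) / denom
  sd_pooled <- sqrt(denom / k)
  list(icc = icc, sem_icc = sd_pooled * sqrt(1 - icc),
       ms_subject = ms_subj, ms_error = ms_err)
}

#' Classify a kinematic measurement error magnitude
#'
#' Conventional interpretation bands for joint-angle measurement error:
#' below 2 degrees is good, between 2 and 5 degrees acceptable, above 5
#' degrees cause for concern.
#'
#' @param err Numeric vector of errors in degrees (SEM or RMSD).
#' @return Character vector of band labels.
#' @export
classify_error <- function(err) {
  ifelse(err < 2, "good (<2 deg)",
         ifelse(err <= 5, "acceptable (2-5 deg)", "concern (>5 deg)"))
}
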