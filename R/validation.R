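# Validation against generator ground truth: event-detection fidelity and
# recovery of the injected between-session measurement error.

#' Compare detected gait events with generator ground truth
#'
#' Runs coordinate-based detection on every trial of a synthetic cohort
#' and matches each ground-truth event (initial contact and toe-off, both
#' sides) to the nearest detected event of the same type and side.
#'
#' @param cohort A `gait_cohort` from [generate_cohort()].
#' @param filter_cutoff Optional low-pass cutoff (Hz); `NULL` for none.
#' @return List with `n_events`, `n_within_1` (events matched within one
#'   sample), `hit_rate` (percent), and `max_abs_error` (samples).
#' @export
event_detection_fidelity <- function(cohort, filter_cutoff = NULL) {
  stopifnot(inherits(cohort, "gait_cohort"))
  gt <- cohort$ground_truth$events
  errs <- numeric(0)
  for (tr in cohort$trials) {
    for (side in c("L", "R")) {
      det <- detect_gait_events(tr, side, filter_cutoff)
      for (type in c("IC", "TO")) {
        truth <- gt$sample[gt$trial_id == tr$trial_id & gt$side == side &
                             gt$type == type]
        found <- if (type == "IC") det$ic else det$to
        if (length(truth) == 0) next
        errs <- c(errs, vapply(truth, function(s)
          min(abs(found - s)), numeric(1)))
      }
    }
  }
  list(n_events = length(errs),
       n_within_1 = sum(errs <= 1),
       hit_rate = 100 * mean(errs <= 1),
       max_abs_error = max(errs))
}

#' Monte-Carlo recovery of the SEM estimator
#'
#' Repeatedly simulates subject-by-session matrices from the cohort
#' variance hierarchy with a known between-session error SD and applies
#' [sem_anova()]; reports the mean estimate per injected SD.
#'
#' @param sigmas Vector of injected between-session error SDs.
#' @param n_subjects Subjects per simulated cohort (default 21).
#' @param n_cohorts Monte-Carlo replicates per SD (default 200).
#' @param sd_subject Between-subject SD of the simulated variable.
#' @param seed Base seed; each replicate uses its own derived stream.
#' @return Data frame with `sigma`, `mean_sem`, `sd_sem`,
#'   `relative_bias_pct`.
#' @export
sem_recovery <- function(sigmas = c(0.5, 1, 3, 5), n_subjects = 21,
                         n_cohorts = 200, sd_subject = 3, seed = 1) {
  rows <- lapply(sigmas, function(sg) {
    ests <- vapply(seq_len(n_cohorts), function(r) {
      m <- simulate_session_matrix(
        n_subjects, sd_subject = sd_subject, sd_session = sg,
        seed = stream_seed(seed, "semrec", sg * 1000, r))
      sem_anova(m)
    }, numeric(1))
    data.frame(sigma = sg, mean_sem = mean(ests), sd_sem = stats::sd(ests),
               relative_bias_pct = 100 * (mean(ests) - sg) / sg)
  })
  do.call(rbind, rows)
}
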