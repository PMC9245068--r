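# Trial CSV dialect: a commented key:value header block followed by one
# row per sample; angle columns `<side>.<joint>.<plane>.deg`, landmark
# columns `<side>.<landmark>.<axis>.m` / `pelvis.sacrum.<axis>.m`, and a
# `time` column in seconds.

required_angle_cols <- function() {
  paste0(angle_channels()$channel, ".deg")
}

required_landmark_cols <- function() {
  g <- expand.grid(side = c("L", "R"), lm = c("heel", "toe"),
                   axis = c("AP", "ML", "vertical"), stringsAsFactors = FALSE)
  c(paste(g$side, g$lm, g$axis, "m", sep = "."),
    paste("pelvis.sacrum", c("AP", "ML", "vertical"), "m", sep = "."))
}

#' Write a motion trial to the trial CSV dialect
#'
#' @param trial A `motion_trial`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_trial()] for the dialect definition; `write(read(file))`
#'   is byte-identical for files produced by this writer.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "motion_trial"))
  hdr <- c(subject_id = trial$subject_id, session = trial$session,
           task = trial$task, pass = trial$pass,
           sampling_rate = trial$sampling_rate,
           leg_length = trial$leg_length,
           dominant_side = trial$dominant_side,
           progression_sign = trial$progression_sign)
  n <- trial$n_samples
  # canonical column order, so write(read(file)) is byte-identical
  ang <- trial$angles[sub("\\.deg$", "", required_angle_cols())]
  lm <- trial$landmarks[sub("\\.m$", "", required_landmark_cols())]
  cols <- c(
    list(time = (seq_len(n) - 1) / trial$sampling_rate),
    stats::setNames(ang, required_angle_cols()),
    stats::setNames(lm, required_landmark_cols()))
  if (!is.null(trial$extra)) cols <- c(cols, trial$extra)

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), unname(hdr)), con)
  writeLines(paste(names(cols), collapse = ","), con)
  body <- do.call(paste, c(lapply(cols, function(x) sprintf("%.10g", x)),
                           sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a motion trial from the trial CSV dialect
#'
#' Parses the commented `# key: value` header block (subject, session,
#' task, sampling rate, leg length, dominant side, progression sign) and
#' the per-sample channel columns. All mandatory angle and landmark
#' channels must be present; unknown columns are preserved (and written
#' back by [write_trial()]) with a warning. The time column must advance
#' monotonically at the stated sampling rate.
#'
#' @param path Path to a trial CSV file.
#' @return A `motion_trial`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 50)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  hdr <- list()
  for (h in hdr_lines) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    hdr[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  need_hdr <- c("subject_id", "session", "task", "sampling_rate",
                "leg_length", "dominant_side", "progression_sign")
  miss <- setdiff(need_hdr, names(hdr))
  if (length(miss)) stop("trial header missing field(s): ",
                         paste(miss, collapse = ", "))

  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing mandatory column: time")
  if (any(diff(df$time) <= 0)) stop("non-monotone time column in ", path)

  need_cols <- c(required_angle_cols(), required_landmark_cols())
  miss <- setdiff(need_cols, names(df))
  if (length(miss)) {
    stop("schema error: missing mandatory channel column(s): ",
         paste(miss, collapse = ", "))
  }
  known <- c("time", need_cols)
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            " (preserved on write)")
  }

  angles <- lapply(required_angle_cols(), function(cc) df[[cc]])
  names(angles) <- sub("\\.deg$", "", required_angle_cols())
  landmarks <- lapply(required_landmark_cols(), function(cc) df[[cc]])
  names(landmarks) <- sub("\\.m$", "", required_landmark_cols())

  fs <- as.numeric(hdr$sampling_rate)
  structure(list(
    trial_id = sprintf("%s_s%s_p%02d", hdr$subject_id,
                       hdr$session, as.integer(hdr$pass %||% 1)),
    subject_id = hdr$subject_id,
    session = as.integer(hdr$session),
    pass = as.integer(hdr$pass %||% 1),
    task = hdr$task,
    sampling_rate = fs,
    leg_length = as.numeric(hdr$leg_length),
    dominant_side = hdr$dominant_side,
    progression_sign = as.numeric(hdr$progression_sign),
    n_samples = nrow(df),
    angles = angles, landmarks = landmarks,
    extra = if (length(extra)) df[extra] else NULL
  ), class = "motion_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.motion_trial <- function(x, ...) {
  cat(sprintf("<motion_trial> %s: %s session %d pass %d (%s), %d samples @ %g Hz, dir %+d\n",
              x$trial_id, x$subject_id, x$session, x$pass, x$task,
              x$n_samples, x$sampling_rate, x$progression_sign))
  invisible(x)
}

#' Write a full cohort to a directory of trial CSVs
#'
#' One CSV per trial plus `ground_truth_strides.csv`,
#' `ground_truth_events.csv` and `ground_truth_sessions.csv`.
#'
#' @param cohort A `gait_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in cohort$trials) {
    write_trial(tr, file.path(dir, paste0(tr$trial_id, ".csv")))
  }
  gt <- cohort$ground_truth
  utils::write.csv(gt$strides, file.path(dir, "ground_truth_strides.csv"),
                   row.names = FALSE)
  utils::write.csv(gt$events, file.path(dir, "ground_truth_events.csv"),
                   row.names = FALSE)
  utils::write.csv(gt$sessions, file.path(dir, "ground_truth_sessions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Build a cohort configuration from a YAML or JSON document
#'
#' The document's top-level keys mirror the arguments of
#' [cohort_config()] (e.g. `task`, `n_subjects`, `stp_means`,
#' `var_between_session`, `seed`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    warning("ignoring unknown config field(s): ",
            paste(unknown, collapse = ", "))
    doc <- doc[intersect(names(doc), known)]
  }
  do.call(cohort_config, doc)
}

#' Read a trial from a C3D motion-capture file (optional feature)
#'
#' C3D interchange support is an optional adapter and is not available in
#' this build; calling this function raises a clear error. Use the trial
#' CSV dialect ([read_trial()]) instead; the core pipeline does not
#' depend on C3D input.
#'
#' @param path Path to a C3D file.
#' @param label_map Named mapping from C3D point labels to the required
#'   channel names.
#' @export
read_c3d <- function(path, label_map = NULL) {
  stop("optional C3D support is not available in this installation; ",
       "convert the recording to the trial CSV dialect (see ?read_trial)",
       call. = FALSE)
}
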