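# Pipeline: detect -> segment -> normalize -> extract -> reliability.

#' Run the per-trial analysis over a set of trials
#'
#' For each trial: detects bilateral gait events, segments strides on the
#' dominant (analysis) side, time-normalizes the dominant-side angle
#' channels, and extracts the discrete kinematic variables and
#' spatiotemporal parameters per stride.
#'
#' @param trials List of `motion_trial` objects (e.g.
#'   `generate_cohort(...)$trials`).
#' @param registry Variable registry (default [kinematic_registry()]).
#' @param filter_cutoff Optional low-pass cutoff (Hz) applied before
#'   detection; `NULL` (default) for no filtering.
#' @param refractory_frac Peak-suppression window, see
#'   [find_local_maxima()].
#' @return List of class `cohort_analysis`:
#'   \describe{
#'     \item{features}{data frame, one row per retained stride, with trial
#'       metadata, all registry variables (degrees) and all spatiotemporal
#'       parameters;}
#'     \item{curves}{list per angle channel: `meta` (stride bookkeeping)
#'       and `mat` (strides x 101 normalized curves);}
#'     \item{events}{data frame of all detected events (0-based sample
#'       indices and seconds);}
#'     \item{exclusions}{data frame of dropped stride windows with
#'       reasons.}
#'   }
#' @export
analyze_cohort <- function(trials, registry = kinematic_registry(),
                           filter_cutoff = NULL, refractory_frac = 0.4) {
  feat_rows <- list()
  ev_rows <- list()
  excl_rows <- list()
  curve_meta <- list()
  curve_mats <- NULL

  for (tr in trials) {
    dom <- tr$dominant_side
    other <- if (dom == "L") "R" else "L"
    ev_i <- detect_gait_events(tr, dom, filter_cutoff, refractory_frac)
    ev_c <- detect_gait_events(tr, other, filter_cutoff, refractory_frac)

    for (e in list(ev_i, ev_c)) {
      for (type in c("ic", "to")) {
        idx <- e[[type]]
        if (length(idx)) {
          ev_rows[[length(ev_rows) + 1]] <- data.frame(
            trial_id = tr$trial_id, side = e$side,
            type = toupper(type), sample = idx, time_s = idx / e$fs,
            stringsAsFactors = FALSE)
        }
      }
    }

    st <- segment_strides(ev_i, ev_c, fs = tr$sampling_rate)
    ex <- attr(st, "exclusions")
    if (nrow(ex)) {
      ex$trial_id <- tr$trial_id
      excl_rows[[length(excl_rows) + 1]] <- ex
    }
    if (nrow(st) == 0) next

    ns <- normalize_strides(tr, st)
    ft <- feature_table(ns, registry, side = dom)
    fx <- attr(ft, "exclusions")
    if (nrow(fx)) {
      fx$trial_id <- tr$trial_id
      fx$ic_start <- NA
      fx$ic_end <- NA
      excl_rows[[length(excl_rows) + 1]] <-
        fx[, c("stride", "ic_start", "ic_end", "reason", "trial_id")]
    }
    if (nrow(ft) == 0) next
    stp <- compute_stp(tr, st)
    merged <- merge(ft, stp, by = "stride", sort = TRUE)
    meta <- data.frame(
      trial_id = tr$trial_id, subject = tr$subject_id,
      session = tr$session, task = tr$task, pass = tr$pass,
      stride = merged$stride, stringsAsFactors = FALSE)
    feat_rows[[length(feat_rows) + 1]] <-
      cbind(meta, merged[, setdiff(names(merged), "stride"), drop = FALSE])

    keep <- ns$phases$stride %in% ft$stride
    curve_meta[[length(curve_meta) + 1]] <- meta
    if (is.null(curve_mats)) {
      curve_mats <- lapply(ns$curves, function(m) m[keep, , drop = FALSE])
      names(curve_mats) <- sub("^[LR]\\.", "", names(ns$curves))
    } else {
      for (ch in names(ns$curves)) {
        key <- sub("^[LR]\\.", "", ch)
        curve_mats[[key]] <- rbind(curve_mats[[key]],
                                   ns$curves[[ch]][keep, , drop = FALSE])
      }
    }
  }

  features <- if (length(feat_rows)) do.call(rbind, feat_rows) else NULL
  meta_all <- if (length(curve_meta)) do.call(rbind, curve_meta) else NULL
  structure(list(
    features = features,
    curves = list(meta = meta_all, mats = curve_mats),
    events = if (length(ev_rows)) do.call(rbind, ev_rows) else NULL,
    exclusions = if (length(excl_rows)) do.call(rbind, excl_rows) else
      data.frame()
  ), class = "cohort_analysis")
}

# Earliest-n stride matching: per subject, truncate both sessions to the
# smaller session's stride count, in (session, pass, stride) order.
# Returns a logical keep vector over rows of `meta`.
match_stride_counts <- function(meta) {
  keep <- rep(FALSE, nrow(meta))
  for (s in unique(meta$subject)) {
    i1 <- which(meta$subject == s & meta$session == 1)
    i2 <- which(meta$subject == s & meta$session == 2)
    if (length(i1) == 0 || length(i2) == 0) next
    i1 <- i1[order(meta$pass[i1], meta$stride[i1])]
    i2 <- i2[order(meta$pass[i2], meta$stride[i2])]
    m <- min(length(i1), length(i2))
    keep[c(i1[seq_len(m)], i2[seq_len(m)])] <- TRUE
  }
  keep
}

#' Subject-by-session matrix of a variable's session means
#'
#' Averages per-stride values within subject and session (the
#' subject-session mean is the unit of the reliability analysis), after
#' matching stride counts between the two sessions by earliest-n
#' truncation. Subjects lacking either session are excluded.
#'
#' @param features Per-stride feature data frame from [analyze_cohort()].
#' @param variable Column name to analyze.
#' @return Matrix subjects x 2 with rownames the subject ids, and
#'   `attr(, "strides_per_cell")` the matched stride count per subject.
#' @export
session_matrix <- function(features, variable) {
  if (!variable %in% names(features)) {
    stop("unknown variable: ", variable)
  }
  ok <- !is.na(features[[variable]])
  f <- features[ok, , drop = FALSE]
  keep <- match_stride_counts(f)
  f <- f[keep, , drop = FALSE]
  subs <- sort(unique(f$subject))
  m <- matrix(NA_real_, length(subs), 2,
              dimnames = list(subs, c("session1", "session2")))
  cnt <- stats::setNames(integer(length(subs)), subs)
  for (s in subs) {
    for (j in 1:2) {
      v <- f[[variable]][f$subject == s & f$session == j]
      m[s, j] <- mean(v)
    }
    cnt[s] <- sum(f$subject == s & f$session == 1)
  }
  drop <- apply(m, 1, anyNA)
  m <- m[!drop, , drop = FALSE]
  attr(m, "strides_per_cell") <- cnt[!drop]
  m
}

#' Assemble the between-session reliability report
#'
#' Produces the full absolute-reliability summary for one task's cohort
#' analysis: per discrete kinematic variable the across-subject session
#' means and SDs, SEM (with ICC(3,1) cross-check) and an error band; per
#' spatiotemporal parameter additionally SEM%; and per joint/plane the
#' cohort-mean full-curve RMSD between the two sessions'
#' ensemble-averaged curves (stride counts matched between sessions
#' before averaging).
#'
#' @param analysis A `cohort_analysis` from [analyze_cohort()].
#' @param registry Variable registry used for the kinematic table.
#' @return Object of class `reliability_report` with data frames
#'   `kinematic`, `stp`, `rmsd`, plus `exclusions` and `task`.
#' @export
build_report <- function(analysis, registry = kinematic_registry()) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  f <- analysis$features
  if (is.null(f) || nrow(f) == 0) stop("analysis contains no strides")
  task <- f$task[1]

  summarize_var <- function(variable) {
    m <- session_matrix(f, variable)
    if (nrow(m) < 2) {
      stop("fewer than 2 subjects with both sessions for ", variable)
    }
    icc <- icc_cross_check(m)
    data.frame(
      variable = variable,
      n_subjects = nrow(m),
      session1_mean = mean(m[, 1]), session1_sd = stats::sd(m[, 1]),
      session2_mean = mean(m[, 2]), session2_sd = stats::sd(m[, 2]),
      sem = sem_anova(m),
      icc = icc$icc,
      stringsAsFactors = FALSE)
  }

  kin <- do.call(rbind, lapply(registry$name, summarize_var))
  kin <- cbind(registry[, c("joint", "plane")], kin)
  kin$band <- classify_error(kin$sem)

  stp <- do.call(rbind, lapply(stp_variables(), summarize_var))
  stp$unit <- stp_units()[stp$variable]
  stp$sem_pct <- mapply(function(sem, m1, m2) sem_percent(sem, c(m1, m2)),
                        stp$sem, stp$session1_mean, stp$session2_mean)

  # full-curve RMSD per joint/plane: subject-session ensemble averages on
  # matched strides, RMSD per subject, cohort mean
  meta <- analysis$curves$meta
  keep <- match_stride_counts(meta)
  rmsd_rows <- list()
  for (ch in names(analysis$curves$mats)) {
    mat <- analysis$curves$mats[[ch]]
    per_subj <- c()
    for (s in unique(meta$subject)) {
      i1 <- which(keep & meta$subject == s & meta$session == 1)
      i2 <- which(keep & meta$subject == s & meta$session == 2)
      if (length(i1) == 0 || length(i2) == 0) next
      per_subj <- c(per_subj, rmsd_between_sessions(
        ensemble_average(mat[i1, , drop = FALSE]),
        ensemble_average(mat[i2, , drop = FALSE])))
    }
    parts <- strsplit(ch, ".", fixed = TRUE)[[1]]
    rmsd_rows[[length(rmsd_rows) + 1]] <- data.frame(
      joint = parts[1], plane = parts[2], n_subjects = length(per_subj),
      rmsd = mean(per_subj), stringsAsFactors = FALSE)
  }
  rmsd <- do.call(rbind, rmsd_rows)
  rmsd$band <- classify_error(rmsd$rmsd)

  structure(list(task = task, kinematic = kin, stp = stp, rmsd = rmsd,
                 exclusions = analysis$exclusions),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, digits = 2, ...) {
  cat(sprintf("<reliability_report> task %s\n", x$task))
  cat(sprintf("  kinematic SEM: %d variables, range %.2f-%.2f deg\n",
              nrow(x$kinematic), min(x$kinematic$sem), max(x$kinematic$sem)))
  cat(sprintf("  full-curve RMSD: %d joint/plane curves, range %.2f-%.2f deg\n",
              nrow(x$rmsd), min(x$rmsd$rmsd), max(x$rmsd$rmsd)))
  cat(sprintf("  spatiotemporal SEM%%: range %.1f-%.1f%%\n",
              min(x$stp$sem_pct, na.rm = TRUE),
              max(x$stp$sem_pct, na.rm = TRUE)))
  cat(sprintf("  excluded stride windows: %d\n",
              if (is.null(x$exclusions)) 0L else nrow(x$exclusions)))
  invisible(x)
}

#' Run the full pipeline from a cohort configuration or trial directory
#'
#' Generates (or reads) the trials, runs detection, segmentation,
#' normalization, feature extraction and the reliability analysis, and
#' optionally writes the events table, the per-stride feature table and
#' the reliability report to disk.
#'
#' @param config A [cohort_config()], a `gait_cohort`, or a path to a
#'   directory of trial CSV files (see [read_trial()]).
#' @param out Optional output directory for artifacts.
#' @param filter_cutoff Optional low-pass cutoff in Hz (`NULL`: off).
#' @param registry Variable registry.
#' @param format Output format for the report, `"csv"`, `"json"` or both.
#' @return The `reliability_report` (invisibly if `out` is given); the
#'   intermediate analysis is attached as `attr(, "analysis")`.
#' @export
run_pipeline <- function(config, out = NULL, filter_cutoff = NULL,
                         registry = kinematic_registry(),
                         format = c("csv", "json")) {
  if (inherits(config, "cohort_config")) {
    cohort <- generate_cohort(config)
    trials <- cohort$trials
  } else if (inherits(config, "gait_cohort")) {
    trials <- config$trials
  } else if (is.character(config) && length(config) == 1 &&
             dir.exists(config)) {
    files <- list.files(config, pattern = "\\.csv$", full.names = TRUE)
    files <- files[!grepl("^ground_truth", basename(files))]
    if (length(files) == 0) stop("no trial CSV files in ", config)
    trials <- lapply(files, read_trial)
  } else {
    stop("config must be a cohort_config, a gait_cohort, or a directory")
  }

  analysis <- analyze_cohort(trials, registry, filter_cutoff)
  report <- build_report(analysis, registry)
  attr(report, "analysis") <- analysis

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    format <- match.arg(format, several.ok = TRUE)
    utils::write.csv(analysis$events, file.path(out, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$features, file.path(out, "features.csv"),
                     row.names = FALSE)
    if (nrow(analysis$exclusions)) {
      utils::write.csv(analysis$exclusions,
                       file.path(out, "excluded_strides.csv"),
                       row.names = FALSE)
    }
    write_report(report, out, format)
    return(invisible(report))
  }
  report
}

#' Write a reliability report to disk
#'
#' Emits one CSV per table analog (kinematic per plane, spatiotemporal,
#' RMSD) and/or a single JSON bundle.
#'
#' @param report A `reliability_report`.
#' @param dir Output directory.
#' @param format `"csv"`, `"json"` or both.
#' @export
write_report <- function(report, dir, format = c("csv", "json")) {
  stopifnot(inherits(report, "reliability_report"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- tolower(report$task)
  round_df <- function(df, cols, digits) {
    df[cols] <- lapply(df[cols], round, digits = digits)
    df
  }
  if ("csv" %in% format) {
    kin <- round_df(report$kinematic,
                    c("session1_mean", "session1_sd", "session2_mean",
                      "session2_sd", "sem"), 2)
    for (pl in unique(kin$plane)) {
      utils::write.csv(kin[kin$plane == pl, , drop = FALSE],
                       file.path(dir, sprintf("kinematic_%s_%s.csv", pl, tag)),
                       row.names = FALSE)
    }
    stp <- round_df(report$stp,
                    c("session1_mean", "session1_sd", "session2_mean",
                      "session2_sd"), 2)
    stp$sem <- round(stp$sem, 2)
    stp$sem_pct <- round(stp$sem_pct, 1)
    utils::write.csv(stp, file.path(dir, sprintf("spatiotemporal_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(round_df(report$rmsd, "rmsd", 2),
                     file.path(dir, sprintf("rmsd_%s.csv", tag)),
                     row.names = FALSE)
  }
  if ("json" %in% format) {
    jsonlite::write_json(
      list(task = report$task, kinematic = report$kinematic,
           stp = report$stp, rmsd = report$rmsd),
      file.path(dir, sprintf("report_%s.json", tag)),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
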