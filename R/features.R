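# Discrete kinematic variables extracted per stride from the 101-point
# normalized curves: windowed extrema, values at named phase points, and
# full-cycle range of motion.

#' Phase windows of one gait cycle
#'
#' Derives every phase interval used by the discrete-variable registry from
#' a stride's event phases (fractions of the gait cycle): stance `[0, TO]`,
#' swing `[TO, 1]`, first and second halves of stance (ST1/ST2 split at
#' mid-stance, the midpoint of `[0, TO]`), the double and single limb
#' support intervals (DLS1 `[0, contralateral TO]`, SLS, DLS2
#' `[contralateral IC, TO]`), the stance-to-swing transition window
#' `[mid-stance, TO + 0.2 * swing length]`, and the mid-stance and
#' mid-swing points. By construction the DLS1, SLS and DLS2 lengths sum
#' exactly to the stance length.
#'
#' @param stance_fraction Ipsilateral toe-off phase in (0, 1).
#' @param contra_ic_phase,contra_to_phase Contralateral initial-contact and
#'   toe-off phases; must satisfy
#'   `0 < contra_to < contra_ic < stance_fraction < 1`.
#' @return List of class `phase_windows`: two-element numeric vectors for
#'   each interval plus scalar `midstance` and `midswing` points.
#' @examples
#' pw <- phase_windows(0.60, 0.50, 0.12)
#' pw$dls1; pw$midstance
#' @export
phase_windows <- function(stance_fraction, contra_ic_phase,
                          contra_to_phase) {
  to <- stance_fraction
  cic <- contra_ic_phase
  cto <- contra_to_phase
  if (!(is.finite(to) && is.finite(cic) && is.finite(cto))) {
    stop("event phases must be finite")
  }
  if (!(0 < cto && cto < cic && cic < to && to < 1)) {
    stop(sprintf(paste0("event phases out of order: need 0 < contra TO ",
                        "(%.3f) < contra IC (%.3f) < TO (%.3f) < 1"),
                 cto, cic, to))
  }
  mid_st <- to / 2
  structure(list(
    stance = c(0, to),
    swing = c(to, 1),
    full = c(0, 1),
    st1 = c(0, mid_st),
    st2 = c(mid_st, to),
    dls1 = c(0, cto),
    sls = c(cto, cic),
    dls2 = c(cic, to),
    stsw = c(mid_st, to + 0.2 * (1 - to)),
    midstance = mid_st,
    midswing = (to + 1) / 2,
    ic = 0
  ), class = "phase_windows")
}

#' Registry of discrete kinematic variables
#'
#' One specification per discrete variable reported for walking
#' kinematics: 12 sagittal, 11 frontal and 9 transverse-plane variables
#' across hip, knee and ankle (32 in total). Each row names the joint,
#' plane, reducer (`max`, `min`, `value_at_point`, `range`) and the phase
#' window or point it applies to. Maxima in the positive convention
#' (flexion, adduction, inversion/varus, internal rotation) use `max`;
#' extrema in the opposite direction (`MaxExt*`, `MaxAbd*`, `MaxEv*`,
#' `MaxExtRot*`, `MaxPlantarflexion`) report the signed minimum of the
#' curve — no absolute value is taken.
#'
#' The ankle frontal-plane `MaxExt_Swing` entry is unusual terminology
#' retained from reported results tables (values near zero degrees); it is
#' implemented as the signed minimum (eversion-direction extremum) over
#' swing.
#'
#' @return Data frame with columns `name`, `joint`, `plane`, `reducer`,
#'   `window`.
#' @export
kinematic_registry <- function() {
  spec <- function(name, joint, plane, reducer, window) {
    data.frame(name = name, joint = joint, plane = plane,
               reducer = reducer, window = window,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    # sagittal (12)
    spec("Hip_Sagittal_RoM",               "hip",   "sagittal", "range", "full"),
    spec("Hip_Sagittal_MaxFlex_Stance",    "hip",   "sagittal", "max",   "stance"),
    spec("Hip_Sagittal_MaxFlex_Swing",     "hip",   "sagittal", "max",   "swing"),
    spec("Hip_Sagittal_MaxExt_Stance",     "hip",   "sagittal", "min",   "stance"),
    spec("Knee_Sagittal_RoM",              "knee",  "sagittal", "range", "full"),
    spec("Knee_Sagittal_MaxFlex_ST1",      "knee",  "sagittal", "max",   "st1"),
    spec("Knee_Sagittal_MaxFlex_Swing",    "knee",  "sagittal", "max",   "swing"),
    spec("Knee_Sagittal_MaxExt_Stance",    "knee",  "sagittal", "min",   "stance"),
    spec("Ankle_Sagittal_RoM",             "ankle", "sagittal", "range", "full"),
    spec("Ankle_Sagittal_InitialContact",  "ankle", "sagittal", "value_at_point", "ic"),
    spec("Ankle_Sagittal_MaxDorsiflexion_ST2", "ankle", "sagittal", "max", "st2"),
    spec("Ankle_Sagittal_MaxPlantarflexion_STSW", "ankle", "sagittal", "min", "stsw"),
    # frontal (11)
    spec("Hip_Frontal_RoM",                "hip",   "frontal", "range", "full"),
    spec("Hip_Frontal_MaxAdd_DLS1",        "hip",   "frontal", "max",   "dls1"),
    spec("Hip_Frontal_MaxAbd_Swing",       "hip",   "frontal", "min",   "swing"),
    spec("Knee_Frontal_RoM",               "knee",  "frontal", "range", "full"),
    spec("Knee_Frontal_MidStance",         "knee",  "frontal", "value_at_point", "midstance"),
    spec("Knee_Frontal_MaxVarus_Swing",    "knee",  "frontal", "max",   "swing"),
    spec("Ankle_Frontal_RoM",              "ankle", "frontal", "range", "full"),
    spec("Ankle_Frontal_InitialContact",   "ankle", "frontal", "value_at_point", "ic"),
    spec("Ankle_Frontal_MaxInv_Swing",     "ankle", "frontal", "max",   "swing"),
    spec("Ankle_Frontal_MaxEv_ST1",        "ankle", "frontal", "min",   "st1"),
    spec("Ankle_Frontal_MaxExt_Swing",     "ankle", "frontal", "min",   "swing"),
    # transverse (9)
    spec("Hip_Transverse_RoM",             "hip",   "transverse", "range", "full"),
    spec("Hip_Transverse_MaxIntRot_ST1",   "hip",   "transverse", "max",   "st1"),
    spec("Hip_Transverse_MaxExtRot_ST2",   "hip",   "transverse", "min",   "st2"),
    spec("Knee_Transverse_RoM",            "knee",  "transverse", "range", "full"),
    spec("Knee_Transverse_MidStance",      "knee",  "transverse", "value_at_point", "midstance"),
    spec("Knee_Transverse_MidSwing",       "knee",  "transverse", "value_at_point", "midswing"),
    spec("Ankle_Transverse_RoM",           "ankle", "transverse", "range", "full"),
    spec("Ankle_Transverse_MaxIntRot_ST1", "ankle", "transverse", "max",   "st1"),
    spec("Ankle_Transverse_MaxExtRot_Swing", "ankle", "transverse", "min", "swing")
  )
  rownames(out) <- NULL
  out
}

#' Extract one discrete variable from a normalized stride curve
#'
#' Applies the spec's reducer over the curve samples whose phase lies in
#' the referenced window (phase grid `0, 0.01, ..., 1`; both window
#' endpoints included). `value_at_point` takes the curve sample nearest
#' the named phase point; `range` is max minus min over the full cycle.
#' Signed conventions hold: a `min` reducer returns the signed minimum
#' even when the whole curve is positive.
#'
#' @param curve Numeric vector, the 101-point normalized stride curve.
#' @param spec One row of [kinematic_registry()] (or a list with `name`,
#'   `reducer`, `window`).
#' @param windows A [phase_windows()] object for the stride.
#' @return Scalar value in degrees.
#' @export
extract_discrete <- function(curve, spec, windows) {
  n <- length(curve)
  if (n < 2) stop("curve must have at least 2 points")
  ph <- seq(0, 1, length.out = n)
  w <- windows[[spec$window]]
  if (is.null(w)) stop("unknown phase window '", spec$window,
                       "' for variable ", spec$name)
  if (spec$reducer == "value_at_point") {
    return(curve[which.min(abs(ph - w[1]))])
  }
  if (spec$reducer == "range") {
    return(max(curve) - min(curve))
  }
  keep <- ph >= w[1] & ph <= w[2]
  if (!any(keep)) stop("empty phase window [", w[1], ", ", w[2],
                       "] for variable ", spec$name)
  switch(spec$reducer,
         max = max(curve[keep]),
         min = min(curve[keep]),
         stop("unknown reducer '", spec$reducer, "'"))
}

#' Per-stride table of all discrete kinematic variables
#'
#' Applies [extract_discrete()] for every registry entry to every stride
#' of a normalized stride set (analysis side only). Strides whose event
#' phases cannot form valid phase windows are skipped and reported in
#' `attr(, "exclusions")`.
#'
#' @param stride_set Output of [normalize_strides()] for the dominant
#'   side.
#' @param registry Data frame of variable specs
#'   (default [kinematic_registry()]).
#' @param side Side prefix of the curve channels (default: inferred from
#'   the first channel name).
#' @return Data frame, one row per stride, one column per registry
#'   variable (degrees), plus a `stride` column.
#' @export
feature_table <- function(stride_set, registry = kinematic_registry(),
                          side = NULL) {
  stopifnot(inherits(stride_set, "stride_set"))
  if (is.null(side)) side <- sub("\\..*$", "", names(stride_set$curves)[1])
  ph <- stride_set$phases
  rows <- list()
  excl <- list()
  for (k in seq_len(nrow(ph))) {
    w <- tryCatch(
      phase_windows(ph$stance_fraction[k], ph$contra_ic_phase[k],
                    ph$contra_to_phase[k]),
      error = function(e) e)
    if (inherits(w, "error")) {
      excl[[length(excl) + 1]] <- data.frame(
        stride = ph$stride[k], reason = conditionMessage(w))
      next
    }
    vals <- vapply(seq_len(nrow(registry)), function(r) {
      sp <- registry[r, ]
      ch <- paste(side, sp$joint, sp$plane, sep = ".")
      if (!ch %in% names(stride_set$curves)) {
        stop("stride set lacks channel ", ch)
      }
      extract_discrete(stride_set$curves[[ch]][k, ], sp, w)
    }, numeric(1))
    rows[[length(rows) + 1]] <-
      cbind(data.frame(stride = ph$stride[k]),
            as.data.frame(as.list(stats::setNames(vals, registry$name))))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(c(list(stride = integer()),
                    stats::setNames(rep(list(numeric()), nrow(registry)),
                                    registry$name)))
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(stride = integer(), reason = character())
  out
}
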