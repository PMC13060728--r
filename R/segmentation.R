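# Trial bookkeeping: gate arrival, success scoring, the ordered exclusion
# filters, the four-phase / sixteen-mini-phase segmentation, and hooked-path
# detection.

PHASE_LABELS <- c("initial_preparation", "approaching_first_row",
                  "approaching_second_row", "approaching_gate")

# per-frame phase labels with the monotone rule: once a later phase has
# opened, brief z dips never re-open an earlier one
phase_of_frames <- function(t, z, layout, cue_time_s = 2) {
  n <- length(t)
  stage <- integer(n)
  cur <- 1L
  for (i in seq_len(n)) {
    if (cur == 1L && (t[i] >= cue_time_s || z[i] >= layout$row1_z)) cur <- 2L
    if (cur == 2L && z[i] >= layout$row1_z) cur <- 3L
    if (cur == 3L && z[i] >= layout$row2_z) cur <- 4L
    stage[i] <- cur
  }
  PHASE_LABELS[stage]
}

#' Segment a trial into the four task phases
#'
#' Initial preparation runs while t < `cue_time` and z is short of the first
#' row; approaching first row from the cue until the first-row line;
#' approaching second row between the two row lines; approaching gate
#' beyond the second row. Boundaries fall on the first frame satisfying the
#' successor's condition, and the labelling is monotone: brief backward z
#' dips do not re-open a closed phase.
#'
#' @param frames Frame table with t and head_z (or a data.frame with t, z).
#' @param layout An `sw_scene`.
#' @param cue_time_s Gate-cue time, seconds.
#' @return data.frame of class phases: label, t_start, t_end, contiguous
#'   and ordered. If the trial ends before reaching the first row the list
#'   is partial and carries attribute `incomplete = TRUE`.
#' @export
segment_phases <- function(frames, layout, cue_time_s = 2) {
  z <- frames$head_z %||% frames$z
  t <- frames$t
  lab <- phase_of_frames(t, z, layout, cue_time_s)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  dt <- stats::median(diff(t))
  out <- data.frame(label = r$values, t_start = t[starts],
                    t_end = c(t[starts[-1]], tail(t, 1) + dt),
                    stringsAsFactors = FALSE)
  if (!"approaching_second_row" %in% out$label)
    attr(out, "incomplete") <- TRUE
  out
}

#' Split phases into 16 mini-phases
#'
#' Each of the four phases is cut into four equal-duration quarters labelled
#' start/early/middle/late.
#'
#' @param phases Output of [segment_phases()] containing all four phases.
#' @return data.frame: phase, quarter, label ("phase.quarter"), t_start,
#'   t_end; 16 rows whose quarters concatenate exactly to the phase spans.
#' @export
mini_phases <- function(phases) {
  missing <- setdiff(PHASE_LABELS, phases$label)
  if (length(missing))
    stopf("cannot build mini-phases; missing phase(s): %s",
          paste(missing, collapse = ", "))
  qlab <- c("start", "early", "middle", "late")
  out <- do.call(rbind, lapply(seq_len(nrow(phases)), function(i) {
    br <- seq(phases$t_start[i], phases$t_end[i], length.out = 5)
    data.frame(phase = phases$label[i], quarter = qlab,
               label = paste(phases$label[i], qlab, sep = "."),
               t_start = br[1:4], t_end = br[2:5],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detect gate arrival
#'
#' Arrival is the first time the head's (x, z) enters a gate's arrival box
#' (gate width, 0.3 m deep, at the far wall). A foil-box entry shorter than
#' `passthrough_s` on the way to the target counts as a pass-through, not an
#' arrival (hooked paths may skirt the foil gate).
#'
#' @param head Head series (t, x, z or head_x/head_z).
#' @param layout An `sw_scene`.
#' @param condition One condition row (for the target side).
#' @param box_depth_m Arrival box depth.
#' @param passthrough_s Maximum dwell treated as pass-through.
#' @return List: `reached` ("target"/"foil"/"none"), `t_arrival` (NA when
#'   never reached).
#' @export
detect_gate_arrival <- function(head, layout, condition, box_depth_m = 0.3,
                                passthrough_s = 0.25) {
  x <- head$head_x %||% head$x
  z <- head$head_z %||% head$z
  t <- head$t
  if (!length(t)) stopf("empty trajectory")
  gz <- layout$room_length_z
  tgt_x <- if (condition$gate_side == "left") -1.25 else 1.25
  gate_hw <- 0.45
  in_box <- function(cx) abs(x - cx) <= gate_hw & z >= gz - box_depth_m
  tin <- in_box(tgt_x)
  fin <- in_box(-tgt_x)
  t_t <- if (any(tin)) t[which(tin)[1]] else NA_real_
  t_f <- if (any(fin)) t[which(fin)[1]] else NA_real_
  if (is.na(t_t) && is.na(t_f))
    return(list(reached = "none", t_arrival = NA_real_))
  if (!is.na(t_f) && (is.na(t_t) || t_f < t_t)) {
    # how long did the foil visit last?
    r <- rle(fin)
    first_run <- which(r$values)[1]
    dwell <- r$lengths[first_run] * stats::median(diff(t))
    if (!is.na(t_t) && dwell < passthrough_s)
      return(list(reached = "target", t_arrival = t_t))
    return(list(reached = "foil", t_arrival = t_f))
  }
  list(reached = "target", t_arrival = t_t)
}

#' Score trial success
#'
#' Success means reaching the target gate no later than the deadline plus a
#' grace period.
#'
#' @param t_arrival Arrival time, seconds (NA if never arrived).
#' @param deadline_s Trial deadline (> 0).
#' @param grace_s Grace period (default 1 s).
#' @param reached Which gate was reached ("target"/"foil"/"none").
#' @return Logical.
#' @export
assess_success <- function(t_arrival, deadline_s, grace_s = 1,
                           reached = "target") {
  if (!is_scalar_num(deadline_s) || deadline_s <= 0)
    stopf("deadline_s must be > 0")
  !is.na(t_arrival) && reached == "target" && t_arrival <= deadline_s + grace_s
}

#' Two-stage trial exclusion filter
#'
#' Stage 1 removes overlong trials (duration above `max_duration_s`) before
#' any statistics; stage 2 removes wrong-gate trials, which are retained for
#' success/duration statistics but excluded from gaze analyses. The ledger
#' records counts and fractions per reason.
#'
#' @param outcomes data.frame with at least `duration_s` and `reached`.
#' @param max_duration_s Stage-1 cutoff (16 s).
#' @return List: `performance` (stage-1 survivors), `gaze` (stage-2
#'   survivors), `ledger` (counts and fractions per exclusion reason).
#' @export
filter_trials <- function(outcomes, max_duration_s = 16) {
  if (!nrow(outcomes))
    return(list(performance = outcomes, gaze = outcomes,
                ledger = list(total = 0L, overlong = 0L, wrong_gate = 0L,
                              overlong_fraction = NA_real_,
                              wrong_gate_fraction = NA_real_)))
  overlong <- !is.na(outcomes$duration_s) & outcomes$duration_s > max_duration_s
  perf <- outcomes[!overlong, , drop = FALSE]
  wrong <- perf$reached != "target"
  gaze <- perf[!wrong, , drop = FALSE]
  list(performance = perf, gaze = gaze,
       ledger = list(total = nrow(outcomes),
                     overlong = sum(overlong),
                     wrong_gate = sum(wrong),
                     overlong_fraction = mean(overlong),
                     wrong_gate_fraction = if (nrow(perf)) mean(wrong) else NA_real_))
}

#' Detect a hooked trajectory
#'
#' A path is hooked when the mean lateral position over the bench zone lies
#' on the side opposite the target gate and the trajectory crosses the
#' midline after the bench zone. A mean of exactly zero counts as the
#' target side (direct).
#'
#' @param head Head series (t, x, z or head_x/head_z).
#' @param layout An `sw_scene` (supplies the bench zone).
#' @param condition One condition row.
#' @return Logical.
#' @export
detect_hooked <- function(head, layout, condition) {
  x <- head$head_x %||% head$x
  z <- head$head_z %||% head$z
  if (max(z) < layout$row2_z) stopf("trajectory must reach the second row")
  s <- if (condition$gate_side == "right") 1 else -1
  zone <- layout$bench_zone
  inz <- z >= zone[1] & z <= zone[2]
  if (!any(inz)) return(FALSE)
  mx <- mean(x[inz])
  if (mx == 0 || sign(mx) == s) return(FALSE)
  late <- which(z > zone[2])
  length(late) > 1 && any(diff(sign(x[late])) != 0)
}
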