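# Whole-trial simulation and trial-log disk format.

TRIAL_SCHEMA_VERSION <- "1.0"

FRAME_COLS <- c("t", "head_x", "head_y", "head_z",
                "eyeL_ox", "eyeL_oy", "eyeL_oz", "eyeL_dx", "eyeL_dy", "eyeL_dz",
                "eyeR_ox", "eyeR_oy", "eyeR_oz", "eyeR_dx", "eyeR_dy", "eyeR_dz",
                "pupil_mm", "valid")

#' Default per-phase cognitive-load profile for the pupil generator
#'
#' Load rises through the two navigation phases and relaxes in the final
#' approach, mirroring the phase structure of the task.
#' @return Named numeric vector, one load level per phase.
#' @export
default_pupil_load <- function() {
  c(initial_preparation = 0.8, approaching_first_row = 1.4,
    approaching_second_row = 1.8, approaching_gate = 0.6)
}

#' Simulate one complete trial
#'
#' Chains the generators: participant trajectory, walker rows (with gap
#' phases aligned so the participant crosses each row at its drawn gap
#' fraction), binocular gaze with ground-truth labels, and the pupil
#' signal. All randomness derives from `seed`.
#'
#' @param condition One row of [enumerate_conditions()].
#' @param layout `sw_scene` (default scene if omitted).
#' @param policy [default_policy()].
#' @param schedule [default_gaze_schedule()].
#' @param event_params [default_event_params()].
#' @param pupil_load Named per-phase load vector, [default_pupil_load()].
#' @param seed Integer seed.
#' @param fs Frame rate, Hz.
#' @return An `sw_trial`: list with `condition`, `layout`
#'   (condition-resolved), `frames` (the on-disk frame table), `walker_tracks`,
#'   `truth` (per-frame event label, target id, and trial-level path class /
#'   crossing times), and `meta`.
#' @export
simulate_trial <- function(condition, layout = build_default_scene(),
                           policy = default_policy(),
                           schedule = default_gaze_schedule(),
                           event_params = default_event_params(),
                           pupil_load = default_pupil_load(),
                           seed = 1, fs = 80) {
  seeds <- derive_seeds(seed, 3)
  part <- simulate_participant(policy, layout, condition, seeds[1], fs = fs)
  head <- part$head
  duration <- tail(head$t, 1)
  cx <- vapply(c("row1", "row2"), function(k) {
    tc <- part$crossing_times[[k]]
    if (is.na(tc)) NA_real_ else head$x[which.min(abs(head$t - tc))]
  }, numeric(1))
  ph <- align_row_phase(layout, condition, as.list(part$crossing_times),
                        as.list(cx), part$gap_fractions)
  tracks <- simulate_walkers(layout, condition, duration, phase = ph, fs = fs)
  rlayout <- assign_gate_roles(layout, condition)
  gz <- simulate_gaze(head, rlayout, tracks, schedule, event_params,
                      seed = seeds[2])
  phase <- phase_of_frames(head$t, head$z, layout, cue_time_s = 2)
  loadv <- unname(pupil_load[phase])
  pupil <- simulate_pupil(head$t, loadv, seed = seeds[3])

  frames <- data.frame(t = head$t, head_x = head$x, head_y = head$y,
                       head_z = head$z)
  frames <- cbind(frames, gz$eyes)
  frames$pupil_mm <- pupil
  frames$valid <- TRUE

  structure(list(
    condition = condition,
    layout = rlayout,
    frames = frames,
    walker_tracks = tracks,
    truth = list(frames = gz$truth, path_class = part$path_class,
                 crossing_times = part$crossing_times,
                 gap_fractions = part$gap_fractions),
    meta = list(seed = seed, fs = fs, cue_time_s = 2,
                deadline_s = condition$deadline_s, t_move = part$t_move,
                schema_version = TRIAL_SCHEMA_VERSION)),
    class = "sw_trial")
}

#' @export
print.sw_trial <- function(x, ...) {
  cat(sprintf("<sw_trial> %s gate, %s, %.1f s, %d frames (%s path)\n",
              x$condition$gate_side, x$condition$row_directions,
              tail(x$frames$t, 1), nrow(x$frames), x$truth$path_class))
  invisible(x)
}

#' Write / read a trial log
#'
#' A trial log on disk is a directory holding `header.json` (condition and
#' metadata), `layout.yaml`, `frames.csv` (the fixed frame-table columns),
#' `walkers.csv` (long walker-track table), and, for synthetic trials,
#' `truth.csv` plus truth metadata in the header. Real-data logs without a
#' truth block read back with `truth = NULL`.
#'
#' @param trial An `sw_trial`.
#' @param dir Directory to create/read.
#' @return `read_trial_log()` returns an `sw_trial`.
#' @export
write_trial_log <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(schema_version = TRIAL_SCHEMA_VERSION,
                 condition = as.list(trial$condition),
                 meta = trial$meta)
  if (!is.null(trial$truth)) {
    header$truth_meta <- list(path_class = trial$truth$path_class,
                              crossing_times = as.list(trial$truth$crossing_times),
                              gap_fractions = as.list(trial$truth$gap_fractions))
  }
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_scene(trial$layout, file.path(dir, "layout.yaml"))
  data.table::fwrite(trial$frames, file.path(dir, "frames.csv"))
  wt <- data.table::rbindlist(lapply(trial$walker_tracks, function(w) {
    data.frame(agent_id = w$agent_id, row = w$row, direction = w$direction,
               speed_mps = w$speed_mps, spacing_m = w$spacing_m,
               t = w$positions$t, x = w$positions$x, z = w$positions$z,
               in_room = w$positions$in_room)
  }))
  data.table::fwrite(wt, file.path(dir, "walkers.csv"))
  if (!is.null(trial$truth))
    data.table::fwrite(trial$truth$frames, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(dir) {
  hpath <- file.path(dir, "header.json")
  if (!file.exists(hpath)) stopf("not a trial log (missing header.json): %s", dir)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (is.null(header$schema_version) ||
      header$schema_version != TRIAL_SCHEMA_VERSION)
    stopf("trial log schema_version mismatch in %s: expected %s, found %s",
          dir, TRIAL_SCHEMA_VERSION, header$schema_version %||% "<missing>")
  layout <- read_scene(file.path(dir, "layout.yaml"))
  frames <- as.data.frame(data.table::fread(file.path(dir, "frames.csv")))
  missing <- setdiff(FRAME_COLS, names(frames))
  if (length(missing))
    stopf("frames.csv in %s is missing column(s): %s", dir,
          paste(missing, collapse = ", "))
  wt <- as.data.frame(data.table::fread(file.path(dir, "walkers.csv")))
  need <- c("agent_id", "row", "direction", "speed_mps", "spacing_m",
            "t", "x", "z", "in_room")
  if (!all(need %in% names(wt)))
    stopf("walkers.csv in %s is missing column(s): %s", dir,
          paste(setdiff(need, names(wt)), collapse = ", "))
  tracks <- lapply(split(wt, wt$agent_id), function(d) {
    d <- d[order(d$t), ]
    dir1 <- if (d$direction[1] == "left_to_right") 1 else -1
    list(agent_id = d$agent_id[1], row = d$row[1], direction = d$direction[1],
         speed_mps = d$speed_mps[1], spacing_m = d$spacing_m[1],
         facing = c(x = dir1, z = 0),
         positions = data.frame(t = d$t, x = d$x, z = d$z,
                                in_room = as.logical(d$in_room)))
  })
  names(tracks) <- NULL
  truth <- NULL
  tpath <- file.path(dir, "truth.csv")
  if (file.exists(tpath) && !is.null(header$truth_meta)) {
    tf <- as.data.frame(data.table::fread(tpath))
    truth <- list(frames = tf,
                  path_class = header$truth_meta$path_class,
                  crossing_times = unlist(header$truth_meta$crossing_times),
                  gap_fractions = unlist(header$truth_meta$gap_fractions))
  }
  cond <- as.data.frame(header$condition, stringsAsFactors = FALSE)
  structure(list(condition = cond, layout = layout, frames = frames,
                 walker_tracks = tracks, truth = truth, meta = header$meta),
            class = "sw_trial")
}
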