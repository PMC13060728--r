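# Walker-row kinematics: single-file agents at fixed z, constant speed,
# equal spacing, entering and exiting through the side walls.

#' Simulate the two walker rows of a trial
#'
#' Each row is a single-file train of agents at a fixed z line, all moving at
#' the same speed with equal spacing. Rows move in opposite directions as set
#' by the condition (`row1_from_left` means row 1 travels left to right).
#' The row is fully populated at t = 0 and new agents keep entering so a
#' crossable gap always exists. Tracks are exact linear kinematics; an
#' `in_room` flag marks frames where the agent is between the side walls.
#'
#' @param layout An `sw_scene`.
#' @param condition One condition row (needs `row_directions`).
#' @param duration Trial duration in seconds (> 0).
#' @param spacing_m Gap between consecutive walkers along x (default 2.5 m).
#' @param speed_mps Walking speed (default 1.3 m/s).
#' @param fs Frame rate, Hz.
#' @param phase Named numeric `c(row1 = , row2 = )`, each in
#'   `[0, spacing_m)`: shifts the whole train along its travel direction.
#'   Used to align a gap with the participant's crossing.
#' @return List of walker tracks; each track is a list with `agent_id`,
#'   `row`, `direction` ("left_to_right"/"right_to_left"), `speed_mps`,
#'   `facing` (unit x direction of travel), and `positions`
#'   (data.frame t, x, z, in_room).
#' @export
simulate_walkers <- function(layout, condition, duration,
                             spacing_m = 2.5, speed_mps = 1.3, fs = 80,
                             phase = c(row1 = 0, row2 = 0)) {
  if (!is_scalar_num(duration) || duration <= 0) stopf("duration must be > 0")
  if (!is_scalar_num(spacing_m) || spacing_m <= 0) stopf("spacing_m must be > 0")
  if (!is_scalar_num(speed_mps) || speed_mps <= 0) stopf("speed_mps must be > 0")
  half_w <- layout$room_width_x / 2
  t <- seq(0, duration, by = 1 / fs)
  row1_dir <- if (condition$row_directions == "row1_from_left") 1 else -1
  tracks <- list()
  for (row in 1:2) {
    dir <- if (row == 1) row1_dir else -row1_dir
    zl <- if (row == 1) layout$row1_z else layout$row2_z
    ph <- unname(phase[paste0("row", row)]) %||% 0
    ph <- ph %% spacing_m
    n_walk <- ceiling((2 * half_w + speed_mps * duration) / spacing_m) + 2L
    for (k in seq_len(n_walk) - 1L) {
      # walker 0 starts at the exit wall (shifted by phase); higher k trail behind
      x <- dir * (half_w + ph - k * spacing_m + speed_mps * t)
      tracks[[length(tracks) + 1L]] <- list(
        agent_id = sprintf("r%d_w%02d", row, k),
        row = row,
        direction = if (dir == 1) "left_to_right" else "right_to_left",
        speed_mps = speed_mps,
        spacing_m = spacing_m,
        facing = c(x = dir, z = 0),
        positions = data.frame(t = t, x = x, z = zl,
                               in_room = abs(x) <= half_w))
    }
  }
  tracks
}

# walker collider boxes at a given time (only agents inside the room)
walker_boxes_at <- function(tracks, time) {
  rows <- lapply(tracks, function(w) {
    i <- which.min(abs(w$positions$t - time))
    x <- w$positions$x[i]
    if (abs(x) > max(abs(w$positions$x[w$positions$in_room]), Inf) &&
        !w$positions$in_room[i]) return(NULL)
    if (!w$positions$in_room[i]) return(NULL)
    data.frame(id = w$agent_id,
               kind = paste0("walker_row", w$row),
               x = x, y = 0.9, z = w$positions$z[1],
               hx = 0.2, hy = 0.9, hz = 0.15,
               fx = w$facing[["x"]], fz = 0, side = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
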