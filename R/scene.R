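# Virtual train-station scene: geometry, colliders, object registry.
#
# Coordinate convention: right-handed, y up, x lateral (midline x = 0,
# positive x toward the right gate), z depth from the start line (0) to the
# far wall. All positions in meters, times in seconds.

SCENE_SCHEMA_VERSION <- "1.0"

OBJECT_KINDS <- c("walker_row1", "walker_row2", "sitter", "stander", "bench",
                  "gate_target", "gate_foil", "gate_indicator", "timer",
                  "wall", "other")

#' Build the default train-station layout
#'
#' Constructs the static scene: a 5 x 6 m waiting room with the start line at
#' (0, 0), two walker-row lines at z = 1.4 and z = 4.7, a gate-indicator sign
#' at z = 1.7, two standers at z = 3 near the side walls, a back-to-back
#' bench block (with sitter slots on both sides) centred on the midline, a
#' timer board on the far wall, and two exit gates at z = 6. Every object
#' carries an axis-aligned box collider so that gaze rays can be attributed
#' to it.
#'
#' @param overrides Named list of scalar field overrides. Known keys:
#'   `room_width_x`, `room_length_z`, `row1_z`, `row2_z`, `gate_indicator_z`,
#'   `standers_z`. Unknown keys are a configuration error.
#' @return An object of class `sw_scene`: a list with the room extents, key
#'   z-lines, gate positions, the bench zone used by path-shape analyses, and
#'   an `objects` data.frame registry (one row per collider: id, kind,
#'   centre position, half extents, facing vector, and the sitter side for
#'   sitter slots).
#' @examples
#' sc <- build_default_scene()
#' sc$row1_z   # 1.4
#' @export
build_default_scene <- function(overrides = list()) {
  fields <- list(room_width_x = 5, room_length_z = 6,
                 row1_z = 1.4, row2_z = 4.7,
                 gate_indicator_z = 1.7, standers_z = 3)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stopf("scene overrides must be named")
    unknown <- setdiff(names(overrides), names(fields))
    if (length(unknown))
      stopf("unknown scene field(s): %s", paste(unknown, collapse = ", "))
    fields[names(overrides)] <- overrides
  }
  for (nm in names(fields))
    if (!is_scalar_num(fields[[nm]]) || fields[[nm]] <= 0)
      stopf("scene field '%s' must be a positive number", nm)

  sc <- fields
  sc$start_position <- c(x = 0, z = 0)
  half_w <- sc$room_width_x / 2
  gz <- sc$room_length_z
  sc$gate_positions <- data.frame(id = c("gate_left", "gate_right"),
                                  x = c(-1.25, 1.25), z = c(gz, gz))
  sc$bench_zone <- c(2.0, 4.1)
  sc$schema_version <- SCENE_SCHEMA_VERSION

  obj <- function(id, kind, x, y, z, hx, hy, hz, fx = NA_real_, fz = NA_real_,
                  side = NA_character_) {
    data.frame(id = id, kind = kind, x = x, y = y, z = z,
               hx = hx, hy = hy, hz = hz, fx = fx, fz = fz,
               side = side, stringsAsFactors = FALSE)
  }
  # bench block 1.2 x 2.4 m centred at (0, 3.05): two back-to-back halves;
  # sitter slots extend 0.3 m beyond each bench edge (leg room)
  bench_c <- 3.05
  objects <- rbind(
    obj("wall_left",  "wall", -half_w - 0.05, 1.5, gz / 2, 0.05, 1.5, gz / 2),
    obj("wall_right", "wall",  half_w + 0.05, 1.5, gz / 2, 0.05, 1.5, gz / 2),
    obj("wall_far",   "wall", 0, 1.5, gz + 0.10, half_w, 1.5, 0.05),
    obj("wall_near",  "wall", 0, 1.5, -0.10, half_w, 1.5, 0.05),
    obj("bench_west", "bench", -0.3, 0.45, bench_c, 0.3, 0.45, 1.2),
    obj("bench_east", "bench",  0.3, 0.45, bench_c, 0.3, 0.45, 1.2),
    obj("sitter_left_1",  "sitter", -0.75, 0.8, bench_c - 0.6, 0.2, 0.8, 0.25,
        fx = -1, fz = 0, side = "left"),
    obj("sitter_left_2",  "sitter", -0.75, 0.8, bench_c + 0.6, 0.2, 0.8, 0.25,
        fx = -1, fz = 0, side = "left"),
    obj("sitter_right_1", "sitter",  0.75, 0.8, bench_c - 0.6, 0.2, 0.8, 0.25,
        fx = 1, fz = 0, side = "right"),
    obj("sitter_right_2", "sitter",  0.75, 0.8, bench_c + 0.6, 0.2, 0.8, 0.25,
        fx = 1, fz = 0, side = "right"),
    obj("stander_left",  "stander", -half_w + 0.3, 0.9, sc$standers_z,
        0.2, 0.9, 0.2, fx = -1, fz = 0),
    obj("stander_right", "stander",  half_w - 0.3, 0.9, sc$standers_z,
        0.2, 0.9, 0.2, fx = 1, fz = 0),
    obj("map_board", "other", -half_w - 0.02, 1.6, sc$standers_z,
        0.02, 0.5, 0.6),
    obj("ticket_kiosk", "other", half_w - 0.05, 1.2, sc$standers_z,
        0.15, 1.2, 0.3),
    obj("gate_indicator", "gate_indicator", 0, 2.3, sc$gate_indicator_z,
        0.5, 0.25, 0.05),
    obj("timer", "timer", 0, 2.5, gz, 0.4, 0.2, 0.06),
    # default roles: left gate labelled target; assign_gate_roles() flips
    obj("gate_left",  "gate_target", -1.25, 1.1, gz, 0.45, 1.1, 0.15),
    obj("gate_right", "gate_foil",    1.25, 1.1, gz, 0.45, 1.1, 0.15)
  )
  sc$objects <- objects
  class(sc) <- "sw_scene"
  validate_scene(sc)
  sc
}

validate_scene <- function(sc) {
  with(sc, {
    if (!(row1_z < gate_indicator_z && gate_indicator_z < standers_z &&
          standers_z < row2_z && row2_z < room_length_z))
      stopf("scene z-line ordering violated: need row1 < indicator < standers < row2 < far wall")
  })
  if (anyDuplicated(sc$objects$id))
    stopf("duplicate object ids in registry")
  if (any(sc$objects$hx <= 0 | sc$objects$hy <= 0 | sc$objects$hz <= 0))
    stopf("collider extents must be strictly positive")
  bad <- !object_kind_known(sc$objects$kind)
  if (any(bad)) stopf("unknown object kind: %s", sc$objects$kind[bad][1])
  invisible(sc)
}

object_kind_known <- function(kind) kind %in% OBJECT_KINDS

#' Assign gate roles for a trial condition
#'
#' Relabels the two exit-gate colliders as `gate_target` / `gate_foil`
#' according to the condition's gate side, and drops sitter slots that are
#' unoccupied under the condition's sitter placement (`both`, `gate_side`,
#' or `opposite`).
#'
#' @param layout An `sw_scene`.
#' @param condition One row of [enumerate_conditions()].
#' @return The layout with a condition-resolved object registry.
#' @export
assign_gate_roles <- function(layout, condition) {
  ob <- layout$objects
  tg <- if (condition$gate_side == "left") "gate_left" else "gate_right"
  ob$kind[ob$id %in% c("gate_left", "gate_right")] <- "gate_foil"
  ob$kind[ob$id == tg] <- "gate_target"
  sp <- condition$sitter_position %||% "both"
  if (sp != "both") {
    keep_side <- if (sp == "gate_side") condition$gate_side else
      setdiff(c("left", "right"), condition$gate_side)
    drop <- ob$kind == "sitter" & !is.na(ob$side) & ob$side != keep_side
    ob <- ob[!drop, , drop = FALSE]
  }
  layout$objects <- ob
  layout
}

#' Serialize / restore a scene layout
#'
#' Writes the layout as a YAML document with explicit units and a
#' `schema_version` field, or reads one back.
#'
#' @param layout An `sw_scene`.
#' @param path File path.
#' @return `read_scene()` returns an `sw_scene`.
#' @export
write_scene <- function(layout, path) {
  doc <- unclass(layout)
  doc$units <- list(length = "meters", time = "seconds")
  doc$gate_positions <- as.list(doc$gate_positions)
  doc$objects <- as.list(doc$objects)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version) || doc$schema_version != SCENE_SCHEMA_VERSION)
    stopf("scene schema_version mismatch: expected %s, found %s",
          SCENE_SCHEMA_VERSION, doc$schema_version %||% "<missing>")
  doc$units <- NULL
  doc$gate_positions <- as.data.frame(doc$gate_positions,
                                      stringsAsFactors = FALSE)
  doc$objects <- as.data.frame(lapply(doc$objects, unlist),
                               stringsAsFactors = FALSE)
  doc$start_position <- unlist(doc$start_position)
  doc$bench_zone <- unlist(doc$bench_zone)
  sc <- structure(doc, class = "sw_scene")
  validate_scene(sc)
  sc
}

#' @export
print.sw_scene <- function(x, ...) {
  cat(sprintf("<sw_scene> %.1f x %.1f m room, rows at z = %.2f / %.2f, %d objects\n",
              x$room_width_x, x$room_length_z, x$row1_z, x$row2_z,
              nrow(x$objects)))
  invisible(x)
}
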