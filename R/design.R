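# Factorial trial designs and randomized session plans.

#' Enumerate the factorial condition grid for one experiment
#'
#' Experiment 1 crosses 2 target-gate sides x 2 walker-row directions x 3
#' sitter placements at a fixed 12-s deadline. Experiment 2 crosses 2 gate
#' sides x 2 row directions x 3 deadlines (8, 10, 12 s) with sitters always
#' on both sides. Each grid has 12 distinct conditions.
#'
#' @param experiment 1 or 2.
#' @return A data.frame with one row per condition and columns `experiment`,
#'   `gate_side` ("left"/"right"), `row_directions` ("row1_from_left" means
#'   row 1 enters from the left wall and row 2 from the right),
#'   `sitter_position` ("both"/"gate_side"/"opposite"), `deadline_s`.
#' @export
enumerate_conditions <- function(experiment) {
  if (!experiment %in% c(1, 2)) stopf("unknown experiment id: %s", experiment)
  if (experiment == 1) {
    g <- expand.grid(gate_side = c("left", "right"),
                     row_directions = c("row1_from_left", "row1_from_right"),
                     sitter_position = c("both", "gate_side", "opposite"),
                     stringsAsFactors = FALSE)
    g$deadline_s <- 12
  } else {
    g <- expand.grid(gate_side = c("left", "right"),
                     row_directions = c("row1_from_left", "row1_from_right"),
                     deadline_s = c(8, 10, 12),
                     stringsAsFactors = FALSE)
    g$sitter_position <- "both"
  }
  g <- g[, c("gate_side", "row_directions", "sitter_position", "deadline_s")]
  g$experiment <- experiment
  g[, c("experiment", "gate_side", "row_directions", "sitter_position",
        "deadline_s")]
}

#' Generate a randomized session plan
#'
#' Repeats each condition `reps` times and applies a seeded random
#' permutation, mirroring a fully randomized presentation order. The result
#' is a pure function of `(conditions, reps, seed)`.
#'
#' @param conditions Condition grid from [enumerate_conditions()].
#' @param reps Repetitions per condition (>= 1).
#' @param seed Integer seed for the permutation.
#' @param participant_id Optional label stored with the design.
#' @return A list of class `sw_session` with `participant_id`, `seed`, and
#'   `ordered_trials` (a data.frame with a `trial` index column).
#' @export
generate_session_design <- function(conditions, reps, seed,
                                    participant_id = "P00") {
  if (!is.data.frame(conditions) || nrow(conditions) == 0)
    stopf("conditions must be a non-empty data.frame")
  if (!is_scalar_num(reps) || reps < 1) stopf("reps must be >= 1")
  reps <- as.integer(reps)
  idx <- rep(seq_len(nrow(conditions)), times = reps)
  ord <- withr::with_seed(seed, sample(idx))
  trials <- conditions[ord, , drop = FALSE]
  rownames(trials) <- NULL
  trials$trial <- seq_len(nrow(trials))
  structure(list(participant_id = participant_id, seed = seed,
                 ordered_trials = trials),
            class = "sw_session")
}

#' @export
print.sw_session <- function(x, ...) {
  cat(sprintf("<sw_session> %s: %d trials (seed %d)\n", x$participant_id,
              nrow(x$ordered_trials), x$seed))
  invisible(x)
}
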