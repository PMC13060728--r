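# Participant locomotion generator: a parametric head trajectory with a
# configurable mid-room velocity dip, lateral swerve around the bench block,
# and an optional "hooked" variant that first heads for the wrong gate.

#' Default participant locomotion policy
#'
#' Parameters of the closed-form trajectory generator. `base_speed_mps` is
#' the forward (z) speed away from the dip; `dip_depth` is the fractional
#' speed reduction at `dip_center_z` (Gaussian profile of width
#' `dip_width_z`); `hook_probability` is the chance of a hooked trial;
#' `gap_offset_bias` shifts the crossing position within an inter-walker gap
#' (0 = mid-gap, negative = closer to the rear-facing agent);
#' `reaction_delay_s` is the pause after the 2-s gate cue before moving.
#'
#' @param ... Overrides of the defaults.
#' @return A list of class `sw_policy`.
#' @export
default_policy <- function(...) {
  pol <- list(base_speed_mps = 0.9, dip_depth = 0.45,
              dip_center_z = 3.05, dip_width_z = 0.6,
              hook_probability = 0.04, gap_offset_bias = 0,
              gap_noise_sd = 0.08, reaction_delay_s = 0.4,
              lateral_offset_m = 1.0, clearance_m = 0.1,
              head_height_m = 1.6)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(pol))
  if (length(unknown)) stopf("unknown policy field(s): %s",
                             paste(unknown, collapse = ", "))
  pol[names(dots)] <- dots
  validate_policy(pol)
  structure(pol, class = "sw_policy")
}

validate_policy <- function(p) {
  if (p$base_speed_mps <= 0) stopf("base_speed_mps must be > 0")
  for (f in c("dip_depth", "hook_probability"))
    if (p[[f]] < 0 || p[[f]] > 1) stopf("%s must lie in [0, 1]", f)
  if (abs(p$gap_offset_bias) > 0.5) stopf("gap_offset_bias must lie in [-0.5, 0.5]")
  invisible(p)
}

# z-speed law: v(z) = base * (1 - dip * exp(-(z - c)^2 / (2 w^2)))
policy_speed_at_z <- function(policy, z) {
  policy$base_speed_mps *
    (1 - policy$dip_depth *
       exp(-(z - policy$dip_center_z)^2 / (2 * policy$dip_width_z^2)))
}

# lateral profile x(z): swerve to the passing side before the bench block,
# hold through it, then blend to the gate; hooked paths hold the wrong side
# and cross the midline only after the bench block.
path_x_of_z <- function(z, side, hooked, lateral, gate_x) {
  s <- if (side == "right") 1 else -1
  hold <- if (hooked) -s * lateral else s * lateral
  x <- hold * smoothstep((z - 0.6) / 1.2)
  late <- z > 4.3
  x[late] <- hold + (s * gate_x - hold) * smoothstep((z[late] - 4.3) / 1.7)
  x
}

#' Simulate a participant head trajectory
#'
#' Generates the head-position series for one trial under a locomotion
#' policy: the participant stands at the start until the gate cue (2 s) plus
#' a reaction delay, then walks forward following the policy's z-speed law
#' (optionally dipping between the rows) along a smooth lateral path around
#' the bench block toward the target gate. With probability
#' `hook_probability` the trial is "hooked": the path first holds the
#' non-target side and crosses the midline late, after the bench block.
#'
#' @param policy An `sw_policy` from [default_policy()].
#' @param layout An `sw_scene`.
#' @param condition One condition row (needs `gate_side`).
#' @param seed Integer seed (hook draw and gap-fraction noise).
#' @param fs Frame rate, Hz.
#' @param cue_time_s Gate-cue reveal time (2 s).
#' @param max_duration_s Hard cap on simulated time.
#' @return A list with `head` (data.frame t, x, y, z), `path_class`
#'   ("direct"/"hooked"), `crossing_times` (named c(row1, row2): first frame
#'   at/over each row line), `gap_fractions` (target crossing position in
#'   each row's gap, in `[0, 1]`, drawn from `0.5 + gap_offset_bias` plus
#'   noise), and `t_move` (movement onset).
#' @export
simulate_participant <- function(policy, layout, condition, seed, fs = 80,
                                 cue_time_s = 2, max_duration_s = 20) {
  validate_policy(policy)
  draws <- withr::with_seed(seed, list(
    hooked = runif(1) < policy$hook_probability,
    gap_noise = rnorm(2, 0, policy$gap_noise_sd)))
  hooked <- draws$hooked
  gap_fractions <- pmin(pmax(0.5 + policy$gap_offset_bias + draws$gap_noise,
                             0.1), 0.9)
  names(gap_fractions) <- c("row1", "row2")

  dt <- 1 / fs
  t_move <- cue_time_s + policy$reaction_delay_s
  zs <- 0
  z <- 0
  # integrate dz/dt = v(z) until the far wall
  while (tail(zs, 1) < layout$room_length_z &&
         length(zs) < (max_duration_s - t_move) * fs) {
    z <- z + policy_speed_at_z(policy, z) * dt
    zs <- c(zs, z)
  }
  n_wait <- round(t_move * fs)
  z_all <- c(rep(0, n_wait), zs)
  t_all <- (seq_along(z_all) - 1) * dt
  gate_x <- abs(layout$gate_positions$x[1])
  x_all <- path_x_of_z(z_all, condition$gate_side, hooked,
                       policy$lateral_offset_m, gate_x)
  head <- data.frame(t = t_all, x = x_all, y = policy$head_height_m, z = z_all)

  cross <- c(row1 = t_all[match(TRUE, z_all >= layout$row1_z)],
             row2 = t_all[match(TRUE, z_all >= layout$row2_z)])
  feasible <- tail(z_all, 1) >= layout$row2_z
  list(head = head,
       path_class = if (hooked) "hooked" else "direct",
       crossing_times = cross,
       gap_fractions = gap_fractions,
       t_move = t_move,
       failed = !feasible)
}

# phase offset (per row) putting the rear-facing walker d_rear = f * spacing
# downstream of the participant at the crossing time
align_row_phase <- function(layout, condition, crossing_times, crossing_x,
                            gap_fractions, spacing_m = 2.5, speed_mps = 1.3) {
  half_w <- layout$room_width_x / 2
  row1_dir <- if (condition$row_directions == "row1_from_left") 1 else -1
  ph <- c(row1 = 0, row2 = 0)
  for (row in 1:2) {
    key <- paste0("row", row)
    tc <- crossing_times[[key]]
    if (is.na(tc)) next
    dir <- if (row == 1) row1_dir else -row1_dir
    f <- gap_fractions[[key]]
    xp <- crossing_x[[key]]
    # walker k=0 sits at dir*(half_w + phase + v t); solve for phase putting
    # some walker at xp + dir * f * spacing at t = tc
    ph[key] <- (dir * xp + f * spacing_m - half_w - speed_mps * tc) %% spacing_m
  }
  ph
}
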