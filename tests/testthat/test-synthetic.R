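test_that("walker rows move at the configured speed and spacing", {
  sc <- std_scene()
  tracks <- simulate_walkers(sc, cond1(), duration = 3)
  expect_gt(length(tracks), 0)
  for (w in tracks[c(1, 5, length(tracks))]) {
    v <- diff(w$positions$x) / diff(w$positions$t)
    expect_equal(abs(v), rep(1.3, length(v)), tolerance = 1e-6)
    expect_equal(unique(w$positions$z),
                 if (w$row == 1) sc$row1_z else sc$row2_z)
  }
  # spacing at an arbitrary shared frame
  r1 <- Filter(function(w) w$row == 1, tracks)
  xs <- sort(vapply(r1, function(w) w$positions$x[100], numeric(1)))
  expect_equal(diff(xs), rep(2.5, length(xs) - 1), tolerance = 1e-6)
  # rows run in opposite directions
  dirs <- vapply(tracks, function(w) w$facing[["x"]] * w$row, numeric(1))
  expect_setequal(sign(unique(dirs)), c(1, -1))
  expect_error(simulate_walkers(sc, cond1(), duration = 3, speed_mps = 0),
               "speed")
  expect_error(simulate_walkers(sc, cond1(), duration = -1), "duration")
})

test_that("ballistic participants move monotonically at constant speed", {
  pol <- default_policy(dip_depth = 0, hook_probability = 0)
  p <- simulate_participant(pol, std_scene(), cond1(), seed = 1)
  moving <- p$head$z > 0.2 & p$head$z < 5.8
  expect_true(all(diff(p$head$z) >= 0))
  vz <- diff(p$head$z) / diff(p$head$t)
  expect_equal(vz[moving[-1]], rep(pol$base_speed_mps, sum(moving[-1])),
               tolerance = 1e-6)
  expect_equal(p$path_class, "direct")
})

test_that("the velocity dip follows the policy's closed-form speed law", {
  pol <- default_policy(dip_depth = 0.5, hook_probability = 0)
  p <- simulate_participant(pol, std_scene(), cond1(), seed = 1)
  vz <- diff(p$head$z) / diff(p$head$t)
  zmid <- (p$head$z[-1] + p$head$z[-nrow(p$head)]) / 2
  at_dip <- abs(zmid - pol$dip_center_z) < 0.05
  expect_equal(mean(vz[at_dip]), 0.5 * pol$base_speed_mps, tolerance = 0.02)
})

test_that("forced hooks produce wrong-side paths that cross the midline late", {
  pol <- default_policy(hook_probability = 1)
  sc <- std_scene()
  cond <- cond1()  # left gate
  p <- simulate_participant(pol, sc, cond, seed = 3)
  expect_equal(p$path_class, "hooked")
  inz <- p$head$z >= 2.0 & p$head$z <= 4.1
  expect_gt(mean(p$head$x[inz]), 0)        # opposite the left target gate
  expect_true(detect_hooked(p$head, sc, cond))
})

test_that("participant trajectories are deterministic and collision-free", {
  p1 <- simulate_participant(default_policy(), std_scene(), cond1(), seed = 9)
  p2 <- simulate_participant(default_policy(), std_scene(), cond1(), seed = 9)
  expect_identical(p1, p2)
  # no frame inside any static collider; clearance to every walker
  tr <- simulate_trial(cond1(4), seed = 21)
  ob <- tr$layout$objects
  # walls bound the room and gates are open doorways the participant
  # walks through; solidity applies to furniture and people
  ob <- ob[!ob$kind %in% c("wall", "gate_target", "gate_foil"), ]
  h <- tr$frames
  for (i in seq_len(nrow(ob))) {
    inside <- abs(h$head_x - ob$x[i]) < ob$hx[i] &
      abs(h$head_y - ob$y[i]) < ob$hy[i] &
      abs(h$head_z - ob$z[i]) < ob$hz[i]
    expect_false(any(inside), label = paste("head inside", ob$id[i]))
  }
  dmin <- Inf
  for (w in tr$walker_tracks) {
    ok <- w$positions$in_room
    d <- sqrt((h$head_x[ok] - w$positions$x[ok])^2 +
                (h$head_z[ok] - w$positions$z[ok])^2)
    dmin <- min(dmin, d)
  }
  expect_gte(dmin, default_policy()$clearance_m)
})

test_that("noise-free gaze at the gate indicator verges on the sign", {
  sc <- std_scene()
  rl <- assign_gate_roles(sc, cond1())
  head <- data.frame(t = seq(0, 2, by = 1 / FS), x = 0, y = 1.6, z = 0)
  sched <- list(initial_preparation = data.frame(kind = "gate_indicator",
                                                 weight = 1),
                approaching_first_row = data.frame(kind = "gate_indicator",
                                                   weight = 1))
  gz <- simulate_gaze(head, rl, list(), schedule = sched,
                      event_params = default_event_params(noise_deg = 0,
                                                          ep_jitter_deg = 0),
                      seed = 1)
  fix <- gz$truth$event == "fixation"
  sign_pos <- with(rl$objects[rl$objects$id == "gate_indicator", ],
                   c(x, y, z))
  i <- which(fix)[5]
  gp <- intersect_gaze_rays(
    c(gz$eyes$eyeL_ox[i], gz$eyes$eyeL_oy[i], gz$eyes$eyeL_oz[i]),
    c(gz$eyes$eyeL_dx[i], gz$eyes$eyeL_dy[i], gz$eyes$eyeL_dz[i]),
    c(gz$eyes$eyeR_ox[i], gz$eyes$eyeR_oy[i], gz$eyes$eyeR_oz[i]),
    c(gz$eyes$eyeR_dx[i], gz$eyes$eyeR_dy[i], gz$eyes$eyeR_dz[i]))
  expect_lt(vnorm_test(gp$point - sign_pos), 1e-3)
})

test_that("pursuit tracks the walker's velocity", {
  st <- stationary_stream(
    duration = 20, noise_deg = 0, seed = 2,
    ep = default_event_params(noise_deg = 0, ep_jitter_deg = 0,
                              pursuit_mean_s = 1.5),
    schedule = list(initial_preparation = data.frame(kind = "walker_row2",
                                                     weight = 1),
                    approaching_first_row = data.frame(kind = "walker_row2",
                                                       weight = 1)))
  pur <- st$truth$event == "pursuit"
  runs <- rle(pur)
  ends <- cumsum(runs$lengths); starts <- c(1, head(ends, -1) + 1)
  long <- which(runs$values & runs$lengths > 20)
  expect_gt(length(long), 0)
  for (r in long[1:min(3, length(long))]) {
    i <- starts[r]:ends[r]
    vx <- diff(st$gaze_point[i, 1]) / diff(st$frames$t[i])
    expect_equal(abs(mean(vx)), 1.3, tolerance = 0.05 * 1.3)
  }
})

test_that("gaze streams are reproducible under a fixed seed", {
  a <- stationary_stream(duration = 5, seed = 7)
  b <- stationary_stream(duration = 5, seed = 7)
  expect_identical(a$frames, b$frames)
  head <- data.frame(t = a$frames$t, x = 0, y = 1.6, z = 0)
  expect_error(simulate_gaze(head, a$layout, a$tracks,
                             schedule = list(), seed = 1),
               "empty target pool")
})

test_that("episode sampling matches the configured pool multinomially", {
  sched <- list(
    initial_preparation = data.frame(kind = "gate_indicator", weight = 1),
    approaching_first_row = data.frame(
      kind = c("gate_indicator", "timer", "gate_target", "other"),
      weight = c(0.4, 0.3, 0.2, 0.1)))
  st <- stationary_stream(duration = 150, seed = 11, schedule = sched)
  expect_gt(nrow(st$frames), 10000)
  tr <- st$truth[st$truth$event == "fixation" & st$truth$t > 2.5, ]
  runs <- rle(tr$target_id)
  kind <- swgaze:::target_kind_of(runs$values, st$layout)
  obs <- table(factor(kind, levels = c("gate_indicator", "timer",
                                       "gate_target", "other")))
  p <- suppressWarnings(stats::chisq.test(obs,
                                          p = c(0.4, 0.3, 0.2, 0.1)))$p.value
  expect_gt(p, 0.01)
})

test_that("pupil signals are positive, seeded, and load-scaled", {
  t <- seq(0, 60, by = 1 / FS)
  flat <- simulate_pupil(t, 0, lf_amp_mm = 0, noise_sd_mm = 0, seed = 1)
  expect_equal(flat, rep(3.5, length(t)))
  expect_error(simulate_pupil(t, -1), "non-negative")
  a <- simulate_pupil(t, 1.5, seed = 4)
  expect_identical(a, simulate_pupil(t, 1.5, seed = 4))
  expect_true(all(a > 0))
  # doubling load doubles high-band power (packets occupy disjoint slots)
  bp <- function(x) {
    s <- stats::spec.pgram(stats::ts(x, frequency = FS), plot = FALSE,
                           taper = 0, detrend = TRUE)
    sum(s$spec[s$freq >= 1.5 & s$freq <= 6.5])
  }
  p1 <- simulate_pupil(t, 1, noise_sd_mm = 0, seed = 2)
  p2 <- simulate_pupil(t, 2, noise_sd_mm = 0, seed = 2)
  expect_equal(bp(p2) / bp(p1), 2, tolerance = 0.1)
})

test_that("trial logs round-trip through disk", {
  tr <- simulate_trial(cond1(2), seed = 5)
  dir <- withr::local_tempdir()
  write_trial_log(tr, dir)
  tr2 <- read_trial_log(dir)
  expect_equal(tr2$frames, tr$frames, tolerance = 1e-9)
  expect_equal(tr2$condition$gate_side, tr$condition$gate_side)
  expect_equal(tr2$truth$frames$event, tr$truth$frames$event)
  expect_equal(tr2$truth$path_class, tr$truth$path_class)
  expect_equal(sort(vapply(tr2$walker_tracks, `[[`, "", "agent_id")),
               sort(vapply(tr$walker_tracks, `[[`, "", "agent_id")))
  w2 <- tr2$walker_tracks[[1]]
  w1 <- Filter(function(w) w$agent_id == w2$agent_id, tr$walker_tracks)[[1]]
  expect_equal(w2$positions$x, w1$positions$x, tolerance = 1e-9)
  # real-data mode: a log without the truth block reads with truth = NULL
  file.remove(file.path(dir, "truth.csv"))
  hd <- jsonlite::read_json(file.path(dir, "header.json"))
  hd$truth_meta <- NULL
  jsonlite::write_json(hd, file.path(dir, "header.json"), auto_unbox = TRUE)
  tr3 <- read_trial_log(dir)
  expect_null(tr3$truth)
  # schema and column validation
  hd$schema_version <- "9.9"
  jsonlite::write_json(hd, file.path(dir, "header.json"), auto_unbox = TRUE)
  expect_error(read_trial_log(dir), "schema_version")
  jsonlite::write_json(list(schema_version = "1.0"),
                       file.path(dir, "header.json"), auto_unbox = TRUE)
  fr <- data.table::fread(file.path(dir, "frames.csv"))
  fr$pupil_mm <- NULL
  data.table::fwrite(fr, file.path(dir, "frames.csv"))
  expect_error(read_trial_log(dir), "pupil_mm")
})
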