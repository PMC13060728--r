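test_that("the attention map follows the phase taxonomy", {
  m <- default_attention_map()
  expect_equal(label_attention("walker_row2", "approaching_first_row", m),
               "global")
  expect_equal(label_attention("gate_indicator", "initial_preparation", m),
               "task_related")
  expect_equal(label_attention("none", "approaching_second_row", m),
               "miscellaneous")
  expect_equal(label_attention("walker_row1", "approaching_second_row", m),
               "local")
  # the timer is an information source in every phase
  for (ph in unique(m$phase))
    expect_equal(label_attention("timer", ph, m), "task_related")
  expect_error(label_attention("timer", "warmup", m), "unknown phase")
})

test_that("allocation proportions sum to one per segment", {
  seg <- data.frame(label = c("a", "b", "c"), t_start = c(0, 1, 2),
                    t_end = c(1, 2, 3))
  t <- seq(0, 2.99, by = 0.01)
  withr::with_seed(4, {
    attn <- sample(c("local", "global", "task_related", "miscellaneous"),
                   length(t), replace = TRUE)
  })
  al <- gaze_allocation(t, attn, seg)
  expect_equal(al$local + al$global + al$task_related + al$miscellaneous,
               rep(1, 3), tolerance = 1e-12)
  # a pure segment and an empty one
  attn2 <- rep("task_related", length(t))
  al2 <- gaze_allocation(t, attn2, seg)
  expect_equal(al2$task_related, rep(1, 3))
  al3 <- gaze_allocation(t[t < 1], attn[t < 1], seg)
  expect_equal(al3$segment, "a")
})

test_that("GTE is zero for deterministic chains and missing when degenerate", {
  expect_error(gte(1:10, window = 1), "window")
  one_state <- gte(rep(3L, 200), window = 80)
  expect_true(all(is.na(one_state$windows$gte)))
  expect_true(is.na(one_state$mean))
  alternating <- gte(rep(c(1L, 2L), 100), window = 80)
  expect_equal(alternating$windows$gte, rep(0, nrow(alternating$windows)),
               tolerance = 1e-12)
  expect_equal(alternating$mean, 0)
})

test_that("GTE of a fair two-state chain matches the hand-computed entropy", {
  withr::with_seed(17, {
    s <- sample(c(1L, 2L), 4000, replace = TRUE)
  })
  g <- gte(s, window = length(s))   # one window spanning the sequence
  # independent hand computation from the empirical transition counts
  n11 <- n12 <- n21 <- n22 <- 0
  for (i in 1:(length(s) - 1)) {
    if (s[i] == 1 && s[i + 1] == 1) n11 <- n11 + 1
    if (s[i] == 1 && s[i + 1] == 2) n12 <- n12 + 1
    if (s[i] == 2 && s[i + 1] == 1) n21 <- n21 + 1
    if (s[i] == 2 && s[i + 1] == 2) n22 <- n22 + 1
  }
  p1 <- (n11 + n12) / (length(s) - 1)
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  manual <- (p1 * h(n11 / (n11 + n12)) + (1 - p1) * h(n21 / (n21 + n22))) /
    log2(2)
  expect_equal(g$windows$gte[1], manual, tolerance = 1e-12)
  expect_gt(g$windows$gte[1], 0.99)   # fair coin: near-maximal entropy
  # NA states are dropped, not fabricated
  s_na <- s; s_na[seq(1, 4000, by = 7)] <- NA
  expect_false(is.na(gte(s_na, window = length(s))$windows$gte[1]))
})

test_that("the K coefficient is a z-score contrast with the stated sign", {
  pairs <- data.frame(d = c(0.3, 0.1), a = c(2, 10), t_mid = c(1, 2))
  k <- k_coefficient(pairs)
  # hand substitution: both terms are +/- 1/sqrt(2) scaled z-scores
  zd <- (pairs$d - mean(pairs$d)) / stats::sd(pairs$d)
  za <- (pairs$a - mean(pairs$a)) / stats::sd(pairs$a)
  expect_equal(k$k, zd - za, tolerance = 1e-12)
  expect_gt(k$k[1], 0)    # long fixation, small saccade: focal
  expect_lt(k$k[2], 0)
  expect_equal(mean(k$k), 0, tolerance = 1e-9)
  withr::with_seed(23, {
    big <- data.frame(d = stats::rlnorm(200, -1.5, 0.5),
                      a = stats::rlnorm(200, 1.5, 0.7),
                      t_mid = stats::runif(200, 0, 8))
  })
  kb <- k_coefficient(big)
  expect_equal(mean(kb$k), 0, tolerance = 1e-9)
  # invariance under affine rescaling of all durations or amplitudes
  k_scaled <- k_coefficient(transform(big, d = 1000 * d + 3))
  expect_equal(k_scaled$k, kb$k, tolerance = 1e-9)
  # degenerate spreads are flagged, not zeroed
  expect_true(k_coefficient(data.frame(d = c(1, 1), a = c(2, 2)))$degenerate)
  expect_true(k_coefficient(data.frame(d = 1, a = 2))$degenerate)
})

test_that("gap crossings are measured along the row axis", {
  sc <- std_scene()
  tracks <- simulate_walkers(sc, cond1(), duration = 6)
  # crossing row 1 exactly mid-gap: pick the time/place from the tracks
  r1 <- Filter(function(w) w$row == 1, tracks)
  tc <- 3.0
  xs <- sort(vapply(r1, function(w) {
    w$positions$x[which.min(abs(w$positions$t - tc))]
  }, numeric(1)))
  inroom <- xs[abs(xs) < 2.4]
  x_mid <- mean(inroom[1:2])
  t <- seq(0, 6, by = 1 / FS)
  head <- data.frame(t = t, x = x_mid, z = 1.4 * t / tc)
  g <- gap_crossing(head, tracks, sc)
  row1 <- g[g$row == 1, ]
  expect_equal(row1$t_cross, tc, tolerance = 1 / FS)
  expect_equal(row1$d_rear, 1.25, tolerance = 0.03)
  expect_equal(row1$d_front, 1.25, tolerance = 0.03)
  expect_equal(row1$gap_fraction, 0.5, tolerance = 0.02)
  # a trajectory that never reaches row 2 reports the reason
  head2 <- data.frame(t = t, x = 0, z = pmin(1.4 * t / tc, 2))
  g2 <- gap_crossing(head2, tracks, sc)
  expect_true(is.na(g2$gap_fraction[g2$row == 2]))
  expect_equal(g2$reason[g2$row == 2], "row not crossed")
})

test_that("midline distance averages |x| over the bench zone", {
  t <- seq(0, 10, by = 0.0125)
  z <- seq(0, 6, length.out = length(t))
  expect_equal(distance_from_midline(data.frame(t = t, x = 0.8, z = z)),
               0.8, tolerance = 1e-12)
  # piecewise: half the zone at 0.6, half at 1.0
  x <- ifelse(z < 3.05, 0.6, 1.0)
  inz <- z >= 2.0 & z <= 4.1
  manual <- mean(abs(x[inz]))
  expect_equal(distance_from_midline(data.frame(t = t, x = x, z = z)),
               manual)
  expect_equal(manual, 0.8, tolerance = 0.01)
  # |x| symmetry
  expect_equal(distance_from_midline(data.frame(t = t, x = -x, z = z)),
               manual)
})

test_that("speed profiles are flat for constant motion with empty bins NA", {
  t <- seq(0, 6, by = 1 / FS)
  head <- data.frame(t = t, x = 0, z = 0.8 * t)
  sp <- speed_profile(head)
  filled <- !is.na(sp$mean_speed)
  expect_equal(sp$mean_speed[filled], rep(0.8, sum(filled)),
               tolerance = 1e-9)
  expect_true(all(is.na(sp$mean_speed[sp$z_mid > 4.9])))  # never reached
  expect_true(all(sp$n[sp$z_mid > 4.9] == 0))
  expect_error(speed_profile(head[1, ]), "2 frames")
  # the simulated dip shows up at its configured depth
  pol <- default_policy(dip_depth = 0.5, hook_probability = 0)
  p <- simulate_participant(pol, std_scene(), cond1(), seed = 2)
  spd <- speed_profile(p$head[p$head$t > p$t_move, ])
  at_dip <- which.min(abs(spd$z_mid - pol$dip_center_z))
  expect_equal(spd$mean_speed[at_dip], 0.5 * pol$base_speed_mps,
               tolerance = 0.08)
})

test_that("gaze-movement alignment uses the stated sign convention", {
  n <- 161
  t <- (0:(n - 1)) / FS
  fr <- data.frame(t = t, head_x = 0, head_z = t,     # heading +z at 1 m/s
                   eyeL_dx = 0, eyeL_dy = 0, eyeL_dz = 1,
                   eyeR_dx = 0, eyeR_dy = 0, eyeR_dz = 1)
  mid <- 30:130
  al <- gaze_movement_alignment(fr)
  expect_equal(al$angle_deg[mid], rep(0, length(mid)), tolerance = 1e-6)
  fr$eyeL_dx <- fr$eyeR_dx <- 1; fr$eyeL_dz <- fr$eyeR_dz <- 0
  expect_equal(gaze_movement_alignment(fr)$angle_deg[mid],
               rep(90, length(mid)), tolerance = 1e-6)    # right of heading
  fr$eyeL_dx <- fr$eyeR_dx <- 0; fr$eyeL_dz <- fr$eyeR_dz <- -1
  expect_equal(abs(gaze_movement_alignment(fr)$angle_deg[mid]),
               rep(180, length(mid)), tolerance = 1e-6)   # look backward
  # stationary frames are flagged but still reported
  fr2 <- fr; fr2$head_z <- 0
  al2 <- gaze_movement_alignment(fr2)
  expect_true(all(al2$stationary))
  expect_true(all(is.finite(al2$angle_deg)))
})

test_that("gaze density maps are normalized kernels over the points", {
  g1 <- gaze_density_grid(data.frame(x = 0.5, z = 3))
  expect_equal(sum(g1$density), 1, tolerance = 1e-9)
  peak <- arrayInd(which.max(g1$density), dim(g1$density))
  expect_equal(g1$x_mid[peak[1]], 0.5, tolerance = 0.1)
  expect_equal(g1$z_mid[peak[2]], 3, tolerance = 0.1)
  # two equal clusters carry equal mass
  pts <- data.frame(x = c(rep(-1.5, 50), rep(1.5, 50)),
                    z = c(rep(1.5, 50), rep(4.5, 50)))
  g2 <- gaze_density_grid(pts)
  left <- sum(g2$density[g2$x_mid < 0, ])
  expect_equal(left, 0.5, tolerance = 0.01)
  expect_error(gaze_density_grid(pts, bin_m = 0), "bin_m")
})

test_that("the pupillary activity index responds to its guards", {
  t <- seq(0, 30, by = 1 / FS)
  expect_error(lhipa(rep(3.5, 100), fs = -1), "fs")
  const <- lhipa(rep(3.5, length(t)), FS)
  expect_true(const$status %in% c("degenerate", "too_short"))
  expect_true(is.na(const$value))
  p <- simulate_pupil(t, 2, seed = 3)
  r1 <- lhipa(p, FS); r2 <- lhipa(p, FS)
  expect_identical(r1, r2)
  expect_equal(r1$status, "ok")
  # short gaps are interpolated; long gaps reject the window
  p_gap <- p; p_gap[100:110] <- NA     # 0.14 s
  expect_equal(lhipa(p_gap, FS)$status, "ok")
  p_bad <- p; p_bad[100:130] <- NA     # 0.39 s
  expect_equal(lhipa(p_bad, FS)$status, "gap_rejected")
  expect_equal(lhipa(p[1:40], FS)$status, "too_short")
})

test_that("wavelet details match the frozen reference decomposition", {
  # reference values computed with an independent DWT implementation
  # (periodized sym16) for x = sin(2*pi*3*t), t = (0:255)/80
  x <- sin(2 * pi * 3 * (0:255) / 80)
  d1 <- dwt_detail(x, 1)
  d4 <- dwt_detail(x, 4)
  expect_equal(length(d1), 128)
  expect_equal(length(d4), 16)
  expect_equal(d1[1:3], c(0.019758828032575056, -0.013870455234433744,
                          0.009887039693396606), tolerance = 1e-10)
  expect_equal(d4[1:3], c(3.2901166941158184, -2.1169408653227193,
                          -0.069992266373796297), tolerance = 1e-8)
  # one analysis step conserves energy (orthonormal filter bank)
  a <- swgaze:::dwt_step(x, swgaze:::SYM16_DEC_LO)
  d <- swgaze:::dwt_step(x, swgaze:::SYM16_DEC_HI)
  expect_equal(sum(a^2) + sum(d^2), sum(x^2), tolerance = 1e-9)
  expect_error(dwt_detail(x, 0), "positive integer")
  expect_error(dwt_detail(x[1:4], 6), "too short")
})
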