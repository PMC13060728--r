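test_that("vergence intersection matches exact and degenerate cases", {
  # both eyes aimed at the gate-indicator point
  tgt <- c(0, 1.5, 1.7)
  oL <- c(-0.0315, 1.6, 0); oR <- c(0.0315, 1.6, 0)
  gp <- intersect_gaze_rays(oL, (tgt - oL) / sqrt(sum((tgt - oL)^2)),
                            oR, (tgt - oR) / sqrt(sum((tgt - oR)^2)))
  expect_equal(gp$point, tgt, tolerance = 1e-9)
  expect_lt(gp$quality, 1e-9)
  expect_equal(gp$method, "vergence")
  # parallel forward rays degrade to the collider fallback
  par <- intersect_gaze_rays(oL, c(0, 0, 1), oR, c(0, 0, 1))
  expect_equal(par$method, "collider_fallback")
  expect_true(all(is.na(par$point)))
  expect_error(intersect_gaze_rays(oL, c(0, 0, 0), oR, c(0, 0, 1)),
               "zero")
})

test_that("vergence equals brute-force segment-distance minimization", {
  withr::with_seed(31, {
    for (i in 1:200) {
      o1 <- runif(3, -2, 2); o2 <- runif(3, -2, 2)
      d1 <- drop(random_unit(1)); d2 <- drop(random_unit(1))
      # near-parallel rays have a flat distance valley with no unique
      # argmin; those frames use the collider fallback instead
      if (abs(sum(d1 * d2)) > 0.98) next
      gp <- intersect_gaze_rays(o1, d1, o2, d2)
      bf <- brute_force_ray_midpoint(o1, d1, o2, d2)
      expect_lt(sqrt(sum((gp$point - bf)^2)), 1e-3)
    }
  })
})

test_that("collider casting returns the nearest hit along the ray", {
  conds <- enumerate_conditions(1)
  # right gate target with sitters opposite: clear line of sight to the gate
  cond <- conds[conds$gate_side == "right" &
                  conds$sitter_position == "opposite", ][1, ]
  sc <- assign_gate_roles(std_scene(), cond)
  tgt <- sc$objects[sc$objects$id == "gate_right", ]
  origin <- c(0, 1.6, 0)
  dir <- c(tgt$x, tgt$y, tgt$z) - origin
  dir <- dir / sqrt(sum(dir^2))
  hit <- cast_to_colliders(origin, dir, sc)
  expect_equal(hit$id, "gate_right")
  expect_equal(hit$kind, "gate_target")
  # ray into the ceiling void misses everything
  expect_null(cast_to_colliders(origin, c(0, 1, 0.05), sc))
  # ray through two boxes: analytic nearest hit equals 1 mm ray marching
  dir2 <- c(0.12, -0.01, 1); dir2 <- dir2 / sqrt(sum(dir2^2))
  hit2 <- cast_to_colliders(origin, dir2, sc)
  steps <- seq(0, 8, by = 0.001)
  march <- origin[1] + steps * 0   # placeholder to keep dims clear
  first_id <- NA_character_
  for (s in steps) {
    p <- origin + s * dir2
    inside <- abs(p[1] - sc$objects$x) <= sc$objects$hx &
      abs(p[2] - sc$objects$y) <= sc$objects$hy &
      abs(p[3] - sc$objects$z) <= sc$objects$hz
    if (any(inside)) { first_id <- sc$objects$id[which(inside)[1]]; break }
  }
  expect_equal(hit2$id, first_id)
  expect_equal(hit2$distance, s, tolerance = 2e-3)
})

test_that("gaze attribution snaps, falls back, and breaks ties by volume", {
  sc <- assign_gate_roles(std_scene(), cond1())
  tracks <- simulate_walkers(sc, cond1(), duration = 1)
  w <- tracks[[2]]
  # vergence point inside a walker box at t = 0.5
  i <- which.min(abs(w$positions$t - 0.5))
  pt <- c(w$positions$x[i], 0.9, w$positions$z[i])
  id <- attribute_gaze(pt, c(0, 1.6, 0), c(0, 0, 1), sc, tracks, 0.5)
  expect_equal(id, w$agent_id)
  # vergence point in open space: the cyclopean ray decides (timer board)
  timer <- sc$objects[sc$objects$id == "timer", ]
  dirv <- c(timer$x, timer$y, timer$z) - c(0, 1.6, 0)
  dirv <- dirv / sqrt(sum(dirv^2))
  id2 <- attribute_gaze(c(0, 1.2, 3.0), c(0, 1.6, 0), dirv, sc)
  expect_equal(id2, "timer")
  # equidistant bench vs sitter: the smaller collider wins
  bench <- sc$objects[sc$objects$id == "bench_west", ]
  sit <- sc$objects[sc$objects$id == "sitter_left_1", ]
  gap_mid <- c(mean(c(bench$x - bench$hx, sit$x + sit$hx)), 0.6, sit$z)
  d_b <- swgaze:::point_box_distance(gap_mid, bench)
  d_s <- swgaze:::point_box_distance(gap_mid, sit)
  expect_equal(d_b, d_s, tolerance = 1e-12)
  id3 <- attribute_gaze(gap_mid, c(0, 1.6, 0), c(0, 0, 1), sc,
                        snap_radius = 0.2)
  expect_equal(id3, sit$id)
  # nothing near and the ray misses: unattributed
  expect_equal(attribute_gaze(c(NA, NA, NA), c(0, 1.6, 0), c(0, 1, 0.02), sc),
               "none")
})

test_that("grid discretization has 216 default states and clamps", {
  g <- grid_spec()
  expect_equal(g$n_states, 216)
  expect_equal(g$bins, c(6L, 12L, 3L))
  expect_error(grid_spec(c(0, 12, 3)), "positive")
  pts <- data.frame(x = 0.01, y = 1.25, z = 3.01)
  st <- discretize_gaze(pts, g)
  # independent bin search over the grid edges
  xe <- seq(g$extents$x[1], g$extents$x[2], length.out = g$bins[1] + 1)
  ze <- seq(g$extents$z[1], g$extents$z[2], length.out = g$bins[2] + 1)
  ye <- seq(g$extents$y[1], g$extents$y[2], length.out = g$bins[3] + 1)
  ix <- max(which(xe <= pts$x)); iz <- max(which(ze <= pts$z))
  iy <- max(which(ye <= pts$y))
  expect_equal(st, ix + 6 * (iz - 1) + 72 * (iy - 1))
  # out-of-extent points clamp to boundary bins
  lo <- discretize_gaze(data.frame(x = -99, y = -1, z = -2), g)
  hi <- discretize_gaze(data.frame(x = 99, y = 99, z = 99), g)
  expect_equal(lo, 1L)
  expect_equal(hi, 216L)
  expect_true(is.na(discretize_gaze(data.frame(x = NA_real_, y = 1, z = 1),
                                    g)))
  # a uniform cloud fills the bins uniformly
  withr::with_seed(8, {
    u <- data.frame(x = runif(21600, -2.5, 2.5), y = runif(21600, 0, 2.5),
                    z = runif(21600, 0, 6))
    su <- discretize_gaze(u, g)
    expect_equal(length(unique(su)), 216)
    p <- suppressWarnings(stats::chisq.test(table(su)))$p.value
    expect_gt(p, 0.001)
  })
})

test_that("angular kinematics recover constant and rotating directions", {
  n <- 81
  t <- (0:(n - 1)) / FS
  mk_frames <- function(az_deg) {
    az <- az_deg * pi / 180
    d <- cbind(sin(az), 0, cos(az))
    data.frame(t = t,
               eyeL_dx = d[, 1], eyeL_dy = d[, 2], eyeL_dz = d[, 3],
               eyeR_dx = d[, 1], eyeR_dy = d[, 2], eyeR_dz = d[, 3])
  }
  still <- angular_kinematics(mk_frames(rep(10, n)))
  expect_equal(still$speed_dps, rep(0, n), tolerance = 1e-9)
  rot <- angular_kinematics(mk_frames(10 * t))
  expect_equal(rot$speed_dps, rep(10, n), tolerance = 0.1)
  expect_error(angular_kinematics(mk_frames(rep(0, n))[1:2, ]), "3 frames")
  bad <- mk_frames(rep(0, n)); bad$t[5] <- bad$t[4]
  expect_error(angular_kinematics(bad), "increasing")
})
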