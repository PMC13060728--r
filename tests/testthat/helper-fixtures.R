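# Shared fixture builders. Everything is generated in code at test time.

FS <- 80

std_scene <- function() build_default_scene()

cond1 <- function(i = 1) enumerate_conditions(1)[i, , drop = FALSE]

# gaze stream over a stationary observer at the start position: the event
# classes are well defined there (no self-motion rotation confound)
stationary_stream <- function(duration = 30, noise_deg = 0.5, seed = 5,
                              schedule = default_gaze_schedule(),
                              condition = cond1(), ep = NULL) {
  sc <- std_scene()
  rl <- assign_gate_roles(sc, condition)
  head <- data.frame(t = seq(0, duration, by = 1 / FS), x = 0, y = 1.6, z = 0)
  tracks <- simulate_walkers(sc, condition, duration)
  ep <- ep %||% default_event_params(noise_deg = noise_deg)
  gz <- simulate_gaze(head, rl, tracks, schedule = schedule,
                      event_params = ep, seed = seed)
  frames <- cbind(data.frame(t = head$t, head_x = head$x, head_y = head$y,
                             head_z = head$z), gz$eyes)
  frames$pupil_mm <- 3.5
  frames$valid <- TRUE
  list(frames = frames, truth = gz$truth, layout = rl, tracks = tracks,
       gaze_point = gz$gaze_point)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm_test <- function(v) sqrt(sum(v^2))

random_unit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# independent brute-force oracle: closest approach of two rays by nested
# grid refinement over the two non-negative ray parameters; the search
# range grows as the rays approach parallelism
brute_force_ray_midpoint <- function(o1, d1, o2, d2, lo = 0, hi = NULL,
                                     levels = 4, npts = 101) {
  if (is.null(hi))
    hi <- sqrt(sum((o1 - o2)^2)) / max(1 - abs(sum(d1 * d2)), 0.01) + 1
  s_rng <- u_rng <- c(lo, hi)
  for (l in seq_len(levels)) {
    s <- seq(s_rng[1], s_rng[2], length.out = npts)
    u <- seq(u_rng[1], u_rng[2], length.out = npts)
    p1 <- outer(s, d1)              # npts x 3 at each s
    p2 <- outer(u, d2)
    # squared distance for every (s, u) combination
    d2m <- outer(rep(1, npts), rep(1, npts))
    best <- c(Inf, 0, 0)
    for (a in 1:3) {
      x1 <- o1[a] + p1[, a]
      x2 <- o2[a] + p2[, a]
      d2m <- if (a == 1) outer(x1, x2, "-")^2 else d2m + outer(x1, x2, "-")^2
    }
    i <- arrayInd(which.min(d2m), dim(d2m))
    s_best <- s[i[1]]; u_best <- u[i[2]]
    hw <- (s_rng[2] - s_rng[1]) / (npts - 1)
    s_rng <- c(max(lo, s_best - hw), s_best + hw)
    hw <- (u_rng[2] - u_rng[1]) / (npts - 1)
    u_rng <- c(max(lo, u_best - hw), u_best + hw)
  }
  (o1 + s_best * d1 + o2 + u_best * d2) / 2
}
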