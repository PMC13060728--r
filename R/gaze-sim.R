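# Binocular gaze stream generator with ground-truth event labels.
#
# Gaze is a sequence of episodes (fixations on static objects, smooth
# pursuit of walkers) joined by saccades with minimum-jerk time courses and
# optional post-saccadic oscillations; both eyes converge exactly on the
# (noisy) gaze point, so vergence reconstruction is well posed.

#' Default phase-wise gaze target schedule
#'
#' For each trial phase, a pool of object kinds with sampling weights,
#' reflecting the task's attention taxonomy: the preparation phase dwells on
#' the gate indicator and timer, the two navigation phases track the
#' upcoming walker row (pursuit) while checking future obstacles, and the
#' final phase fixates the target gate and timer.
#'
#' @return Named list (one entry per phase) of data.frames (kind, weight).
#' @export
default_gaze_schedule <- function() {
  pool <- function(...) {
    kv <- c(...)
    data.frame(kind = names(kv), weight = unname(kv), stringsAsFactors = FALSE)
  }
  list(
    initial_preparation = pool(gate_indicator = 0.50, timer = 0.18,
                               walker_row1 = 0.15, walker_row2 = 0.07,
                               gate_target = 0.05, other = 0.05),
    approaching_first_row = pool(walker_row1 = 0.45, walker_row2 = 0.18,
                                 gate_indicator = 0.10, timer = 0.07,
                                 sitter = 0.06, bench = 0.04,
                                 gate_target = 0.05, other = 0.05),
    approaching_second_row = pool(walker_row2 = 0.42, walker_row1 = 0.08,
                                  gate_target = 0.14, gate_foil = 0.06,
                                  timer = 0.10, sitter = 0.05, bench = 0.03,
                                  other = 0.12),
    approaching_gate = pool(gate_target = 0.55, timer = 0.25, other = 0.20)
  )
}

#' Default gaze event-generation parameters
#'
#' Durations in seconds, amplitudes in degrees. `noise_deg` is the angular
#' standard deviation of a slowly drifting (Ornstein-Uhlenbeck) gaze error
#' with time constant `noise_tau_s`; `ep_jitter_deg` scatters each
#' episode's landing point across the target surface; `ipd_m` is the
#' inter-pupillary distance.
#'
#' @param ... Overrides.
#' @return Named list of parameters.
#' @export
default_event_params <- function(...) {
  p <- list(fix_meanlog = log(0.25), fix_sdlog = 0.45,
            pursuit_shape = 4, pursuit_mean_s = 0.5,
            sacc_dur_base_s = 0.02, sacc_dur_per_deg = 0.002,
            pso_prob = 0.7, pso_dur_s = 0.05, pso_freq_hz = 15,
            pso_amp_deg = 1.0,
            noise_deg = 0.5, noise_tau_s = 0.8,
            ep_jitter_deg = 1.0, ipd_m = 0.063)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stopf("unknown event parameter(s): %s",
                             paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

# pick a concrete target for a sampled kind at time `time`
resolve_target <- function(kind, objects, tracks, time) {
  if (kind %in% c("walker_row1", "walker_row2")) {
    row <- if (kind == "walker_row1") 1 else 2
    cand <- Filter(function(w) {
      i <- which.min(abs(w$positions$t - time))
      w$row == row && w$positions$in_room[i]
    }, tracks)
    if (!length(cand)) return(NULL)
    w <- cand[[sample.int(length(cand), 1)]]
    list(id = w$agent_id, moving = TRUE, track = w)
  } else {
    cand <- objects[objects$kind == kind, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    o <- cand[sample.int(nrow(cand), 1), ]
    list(id = o$id, moving = FALSE, point = c(o$x, o$y, o$z))
  }
}

# target point series for frames idx (rows of head)
target_points <- function(tgt, head, idx) {
  if (tgt$moving) {
    pos <- tgt$track$positions
    j <- findInterval(head$t[idx], pos$t, all.inside = TRUE)
    cbind(pos$x[j], 1.5, pos$z[j])
  } else {
    matrix(rep(tgt$point, each = length(idx)), ncol = 3)
  }
}

#' Simulate a binocular gaze stream over a head trajectory
#'
#' Generates per-frame left/right eye rays and ground-truth event labels.
#' Episodes alternate between fixations on static objects and smooth
#' pursuit of walkers, sampled from the phase-appropriate target pool;
#' transitions are saccades with a minimum-jerk profile and amplitude-scaled
#' duration, optionally followed by a damped post-saccadic oscillation.
#' Angular noise is an Ornstein-Uhlenbeck drift applied to the gaze point;
#' both eyes always converge on that point.
#'
#' @param head Head-position data.frame (t, x, y, z).
#' @param layout Condition-resolved `sw_scene` (see [assign_gate_roles()]).
#' @param walker_tracks From [simulate_walkers()].
#' @param schedule Phase target pools, [default_gaze_schedule()].
#' @param event_params [default_event_params()].
#' @param seed Integer seed.
#' @param cue_time_s Gate-cue time used for phase labelling.
#' @return List with `eyes` (data.frame of eye-ray columns eyeL_ox..eyeR_dz),
#'   `truth` (data.frame t, event, target_id), and `gaze_point` (the exact
#'   simulated 3D gaze point per frame).
#' @export
simulate_gaze <- function(head, layout, walker_tracks,
                          schedule = default_gaze_schedule(),
                          event_params = default_event_params(),
                          seed = 1, cue_time_s = 2) {
  n <- nrow(head)
  t <- head$t
  dt <- stats::median(diff(t))
  phase <- phase_of_frames(t, head$z, layout, cue_time_s)
  p <- event_params
  for (ph in unique(phase)) {
    pool <- schedule[[ph]]
    if (is.null(pool) || !nrow(pool)) stopf("empty target pool for phase '%s'", ph)
  }

  withr::with_seed(seed, {
    # OU angular noise (azimuth, elevation), radians
    nz <- matrix(0, n, 2)
    a <- exp(-dt / p$noise_tau_s)
    sd_st <- p$noise_deg * pi / 180
    innov <- matrix(rnorm(2 * n, 0, sd_st * sqrt(1 - a^2)), n, 2)
    nz[1, ] <- rnorm(2, 0, sd_st)
    for (i in 2:n) nz[i, ] <- a * nz[i - 1, ] + innov[i, ]

    label <- character(n)
    target_id <- character(n)
    pt <- matrix(NA_real_, n, 3)
    jit <- matrix(0, n, 2)   # per-episode angular landing offset
    i <- 1L
    prev_pt <- NULL
    while (i <= n) {
      pool <- schedule[[phase[i]]]
      tgt <- NULL
      kinds <- pool$kind
      w <- pool$weight
      while (is.null(tgt) && length(kinds)) {
        k <- sample.int(length(kinds), 1, prob = w)
        tgt <- resolve_target(kinds[k], layout$objects, walker_tracks, t[i])
        if (is.null(tgt)) { kinds <- kinds[-k]; w <- w[-k] }
      }
      if (is.null(tgt)) stopf("no resolvable gaze target at t = %.2f", t[i])
      ep_jit <- rnorm(2, 0, p$ep_jitter_deg * pi / 180)

      # saccade from previous point to the new target
      if (!is.null(prev_pt)) {
        new_pt0 <- drop(target_points(tgt, head, i))
        hp <- c(head$x[i], head$y[i], head$z[i])
        amp <- angle_between_deg(prev_pt - hp, new_pt0 - hp)
        sdur <- p$sacc_dur_base_s + p$sacc_dur_per_deg * amp
        ns <- max(1L, round(sdur / dt))
        js <- i:min(n, i + ns - 1L)
        u <- minjerk(seq_along(js) / length(js))
        pt[js, ] <- outer(1 - u, prev_pt) + outer(u, new_pt0)
        label[js] <- "saccade"
        target_id[js] <- tgt$id
        jit[js, ] <- outer(u, ep_jit)
        i <- max(js) + 1L
        # post-saccadic oscillation about the landing point
        if (i <= n && runif(1) < p$pso_prob) {
          np <- max(1L, round(p$pso_dur_s / dt))
          jp <- i:min(n, i + np - 1L)
          tau <- (seq_along(jp) - 1) * dt
          dvec <- new_pt0 - prev_pt
          dl <- vnorm(dvec)
          dirv <- if (dl > 1e-9) dvec / dl else c(1, 0, 0)
          dist <- vnorm(new_pt0 - hp)
          amp_m <- tan(p$pso_amp_deg * pi / 180) * dist
          osc <- amp_m * exp(-3 * tau / p$pso_dur_s) * sin(2 * pi * p$pso_freq_hz * tau)
          pt[jp, ] <- matrix(rep(new_pt0, each = length(jp)), ncol = 3) +
            outer(osc, dirv)
          label[jp] <- "pso"
          target_id[jp] <- tgt$id
          jit[jp, ] <- matrix(ep_jit, length(jp), 2, byrow = TRUE)
          i <- max(jp) + 1L
        }
        if (i > n) break
      }

      dur <- if (tgt$moving) rgamma(1, shape = p$pursuit_shape,
                                    rate = p$pursuit_shape / p$pursuit_mean_s)
             else rlnorm(1, p$fix_meanlog, p$fix_sdlog)
      ne <- max(2L, round(dur / dt))
      je <- i:min(n, i + ne - 1L)
      if (tgt$moving) {
        # pursuit cannot outlive the walker's presence in the room
        pos <- tgt$track$positions
        jj <- findInterval(t[je], pos$t, all.inside = TRUE)
        out <- which(!pos$in_room[jj])
        if (length(out)) je <- je[seq_len(max(1, out[1] - 1))]
      }
      pt[je, ] <- target_points(tgt, head, je)
      label[je] <- if (tgt$moving) "pursuit" else "fixation"
      target_id[je] <- tgt$id
      jit[je, ] <- matrix(ep_jit, length(je), 2, byrow = TRUE)
      prev_pt <- pt[max(je), ]
      i <- max(je) + 1L
    }

    # apply OU angular noise plus the per-episode landing offset as a
    # lateral/vertical displacement of the point
    nz <- nz + jit
    hp <- cbind(head$x, head$y, head$z)
    g <- pt - hp
    d <- sqrt(rowSums(g^2))
    az <- cbind(g[, 3], 0, -g[, 1])       # horizontal perpendicular
    az_n <- sqrt(rowSums(az^2)); az_n[az_n < 1e-9] <- 1
    az <- az / az_n
    up <- cbind(az[, 2] * g[, 3] - az[, 3] * g[, 2],
                az[, 3] * g[, 1] - az[, 1] * g[, 3],
                az[, 1] * g[, 2] - az[, 2] * g[, 1]) / d
    pt_noisy <- pt + az * (d * tan(nz[, 1])) + up * (d * tan(nz[, 2]))

    # binocular rays: origins offset +/- ipd/2 along the horizontal
    # perpendicular of the gaze azimuth, both aimed at the gaze point
    oL <- hp - az * (p$ipd_m / 2)
    oR <- hp + az * (p$ipd_m / 2)
    dL <- pt_noisy - oL; dL <- dL / sqrt(rowSums(dL^2))
    dR <- pt_noisy - oR; dR <- dR / sqrt(rowSums(dR^2))

    eyes <- data.frame(
      eyeL_ox = oL[, 1], eyeL_oy = oL[, 2], eyeL_oz = oL[, 3],
      eyeL_dx = dL[, 1], eyeL_dy = dL[, 2], eyeL_dz = dL[, 3],
      eyeR_ox = oR[, 1], eyeR_oy = oR[, 2], eyeR_oz = oR[, 3],
      eyeR_dx = dR[, 1], eyeR_dy = dR[, 2], eyeR_dz = dR[, 3])
    list(eyes = eyes,
         truth = data.frame(t = t, event = label, target_id = target_id,
                            stringsAsFactors = FALSE),
         gaze_point = pt_noisy)
  })
}

#' Simulate a pupil-diameter series
#'
#' The signal is a baseline plus a fixed low-frequency (hippus-like)
#' oscillation, a cognitive-load-driven high-frequency component, and white
#' measurement noise. High-frequency activity is bursty, as load-related
#' pupil oscillations are: time is divided into slots and load sets how
#' many slots carry a transient oscillation packet (a Gaussian-windowed
#' sinusoid in the 2.5-5 Hz band). Because packets occupy disjoint slots,
#' high-band power is proportional to the packet count, so doubling `load`
#' doubles high-band power.
#'
#' @param t Time vector, seconds (uniform sampling).
#' @param load Non-negative load level; scalar or one value per frame.
#'   With a scalar load the packet count is exactly
#'   `round(hf_burst_rate * load * duration)`; with a per-frame load each
#'   slot carries a packet with probability proportional to the local load.
#' @param baseline_mm Baseline diameter (> 0).
#' @param lf_amp_mm,lf_freq_hz Low-frequency oscillation.
#' @param hf_burst_amp_mm Peak amplitude of one oscillation packet.
#' @param hf_burst_rate Packets per second per unit load.
#' @param hf_band_hz Frequency band the packets are drawn from.
#' @param burst_sd_s Gaussian envelope s.d. of a packet.
#' @param slot_s Slot width (packets occupy disjoint slots).
#' @param noise_sd_mm White-noise standard deviation.
#' @param seed Integer seed (packet placement, frequencies, phases, noise).
#' @return Numeric vector of pupil diameters, millimetres, strictly
#'   positive.
#' @export
simulate_pupil <- function(t, load, baseline_mm = 3.5,
                           lf_amp_mm = 0.15, lf_freq_hz = 0.8,
                           hf_burst_amp_mm = 0.10, hf_burst_rate = 0.4,
                           hf_band_hz = c(2.5, 5), burst_sd_s = 0.12,
                           slot_s = 0.6,
                           noise_sd_mm = 0.01, seed = 1) {
  if (any(load < 0)) stopf("load must be non-negative")
  if (!is_scalar_num(baseline_mm) || baseline_mm <= 0)
    stopf("baseline_mm must be > 0")
  n <- length(t)
  dur <- t[n] - t[1]
  scalar_load <- length(load) == 1
  if (!scalar_load && length(load) != n)
    stopf("load must be scalar or one value per frame")
  n_slots <- max(1L, floor(dur / slot_s))
  withr::with_seed(seed, {
    ph <- runif(1, 0, 2 * pi)
    sig <- baseline_mm + lf_amp_mm * sin(2 * pi * lf_freq_hz * t + ph)
    slot_of <- pmin(floor((t - t[1]) / slot_s) + 1L, n_slots)
    if (scalar_load) {
      n_b <- min(round(hf_burst_rate * load * dur), n_slots)
      slots <- if (n_b > 0) sample.int(n_slots, n_b) else integer(0)
    } else {
      slot_load <- vapply(seq_len(n_slots),
                          function(s) mean(load[slot_of == s]), numeric(1))
      p <- pmin(hf_burst_rate * slot_load * slot_s, 1)
      slots <- which(runif(n_slots) < p)
    }
    for (s in slots) {
      tc <- t[1] + (s - 0.5) * slot_s
      f <- runif(1, hf_band_hz[1], hf_band_hz[2])
      phb <- runif(1, 0, 2 * pi)
      sig <- sig + hf_burst_amp_mm *
        exp(-(t - tc)^2 / (2 * burst_sd_s^2)) *
        sin(2 * pi * f * (t - tc) + phb)
    }
    sig <- sig + rnorm(n, 0, noise_sd_mm)
    pmax(sig, 0.1)
  })
}
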