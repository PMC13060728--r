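# Eye-movement event classification: Savitzky-Golay velocity estimation,
# I-VT fixation/saccade labelling, and a four-state Gaussian hidden Markov
# model (fixation, saccade, post-saccadic oscillation, smooth pursuit).

EVENT_TYPES <- c("fixation", "pursuit", "pso", "saccade")

#' Savitzky-Golay smoothed angular velocity
#'
#' Least-squares local-polynomial derivative estimate of gaze angles. Given
#' an azimuth/elevation matrix the result is the great-circle speed; given a
#' single series it is that series' derivative.
#'
#' @param angles Numeric vector (degrees) or two-column matrix
#'   `cbind(az_deg, el_deg)` with unwrapped azimuth.
#' @param fs Sampling rate, Hz.
#' @param window Odd filter length in frames (default 11, about 137 ms at
#'   80 Hz).
#' @param order Polynomial order (< window; default 3).
#' @return Velocity series, deg/s, same length as the input.
#' @export
sg_velocity <- function(angles, fs, window = 11, order = 3) {
  if (window %% 2 == 0) stopf("window must be odd")
  n <- if (is.matrix(angles)) nrow(angles) else length(angles)
  if (window >= n) stopf("window must be shorter than the series")
  if (order >= window) stopf("order must be smaller than window")
  deriv <- function(x) signal::sgolayfilt(x, p = order, n = window, m = 1) * fs
  if (is.matrix(angles)) {
    vaz <- deriv(angles[, 1])
    vel <- deriv(angles[, 2])
    el <- angles[, 2] * pi / 180
    sqrt((vaz * cos(el))^2 + vel^2)
  } else {
    deriv(angles)
  }
}

#' Velocity-threshold (I-VT) fixation/saccade classification
#'
#' Frames at or above the velocity threshold are saccades, the rest
#' fixations; fixation runs shorter than `min_fix_dur` are merged into the
#' surrounding saccade.
#'
#' @param velocity Angular speed series, deg/s.
#' @param fs Sampling rate, Hz.
#' @param threshold Saccade velocity threshold, deg/s (default 100; head-free
#'   VR gaze is noisier than desktop recordings).
#' @param min_fix_dur Minimum fixation duration, seconds.
#' @return Character labels ("fixation"/"saccade"), one per frame.
#' @export
ivt_classify <- function(velocity, fs, threshold = 100, min_fix_dur = 0.06) {
  if (!is_scalar_num(threshold) || threshold <= 0)
    stopf("threshold must be > 0")
  lab <- ifelse(velocity >= threshold, "saccade", "fixation")
  r <- rle(lab)
  short <- r$values == "fixation" & r$lengths < min_fix_dur * fs
  # only merge fixations sandwiched in saccades (not at the trial edges)
  interior <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
  r$values[short & interior] <- "saccade"
  inverse.rle(r)
}

# ---- Gaussian HMM --------------------------------------------------------

# log density of diagonal-covariance Gaussian, vectorized over rows
dmvnorm_diag_log <- function(x, mean, sd) {
  z <- sweep(sweep(x, 2, mean), 2, sd, "/")
  -0.5 * rowSums(z^2) - sum(log(sd)) - ncol(x) / 2 * log(2 * pi)
}

hmm_forward_backward <- function(logB, Pi, A) {
  n <- nrow(logB); k <- ncol(logB)
  logA <- log(A)
  la <- matrix(-Inf, n, k)
  la[1, ] <- log(Pi) + logB[1, ]
  for (i in 2:n) {
    m <- apply(la[i - 1, ] + logA, 2, max)
    la[i, ] <- m + log(colSums(exp(sweep(la[i - 1, ] + logA, 2, m)))) + logB[i, ]
  }
  lb <- matrix(0, n, k)
  for (i in (n - 1):1) {
    v <- sweep(logA, 2, logB[i + 1, ] + lb[i + 1, ], "+")
    m <- apply(v, 1, max)
    lb[i, ] <- m + log(rowSums(exp(v - m)))
  }
  ml <- max(la[n, ])
  loglik <- ml + log(sum(exp(la[n, ] - ml)))
  lg <- la + lb - loglik
  gamma <- exp(lg)
  list(loglik = loglik, gamma = gamma / rowSums(gamma), la = la, lb = lb,
       logA = logA)
}

hmm_viterbi <- function(logB, Pi, A) {
  n <- nrow(logB); k <- ncol(logB)
  logA <- log(A)
  delta <- log(Pi) + logB[1, ]
  psi <- matrix(0L, n, k)
  for (i in 2:n) {
    cand <- delta + logA                 # k x k: from-state rows
    psi[i, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(psi[i, ], seq_len(k))] + logB[i, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (i in (n - 1):1) path[i] <- psi[i + 1, path[i + 1]]
  path
}

#' Fit and decode a four-state gaze HMM
#'
#' Fits a hidden Markov model with diagonal-covariance Gaussian emissions on
#' gaze features (by default log angular speed and log angular acceleration)
#' by expectation-maximization, then decodes the most probable state path
#' (Viterbi). States are relabelled to eye-movement classes by mean speed:
#' slowest = fixation, fastest = saccade; of the middle two, the higher mean
#' acceleration is the post-saccadic-oscillation state and the other smooth
#' pursuit.
#'
#' Emissions are initialized from a physiological threshold partition of the
#' frames and anchored there during EM by a conjugate mean prior
#' (`mean_prior_n` pseudo-frames), so the states keep their eye-movement
#' semantics while EM refines the boundaries and learns the dynamics; the
#' transition prior is sticky-diagonal, and the PSO state is structurally
#' reachable only from the saccade state.
#'
#' @param features Numeric matrix (frames x features), finite, >= 100 rows.
#'   Use [hmm_features()] to build it from kinematics.
#' @param n_states Number of states (4).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed Integer seed (reserved; the fit is deterministic).
#' @param mean_prior_n Strength (pseudo-frames) of the emission-mean prior.
#' @param sd_floor Lower bound on emission standard deviations.
#' @return List of class `sw_hmm`: `labels` (per-frame event class),
#'   `states` (raw decoded integers), `spec` (means, sds, transition matrix,
#'   initial distribution, state -> class map), `loglik` (per EM iteration,
#'   non-decreasing), `degenerate` (zero-variance guard flag).
#' @export
hmm_fit_decode <- function(features, n_states = 4, max_iter = 100,
                           tol = 1e-5, seed = 1, mean_prior_n = 1000,
                           sd_floor = 0.1) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (!all(is.finite(features))) stopf("features must be finite")
  n <- nrow(features); k <- n_states
  if (n < 100) stopf("HMM fitting requires at least 100 frames")
  if (stats::sd(features[, 1]) < 1e-10)
    return(structure(list(labels = rep("fixation", n), states = rep(1L, n),
                          spec = NULL, loglik = NA_real_, degenerate = TRUE),
                     class = "sw_hmm"))

  # emission initialization from a physiological threshold partition
  # (saccade above 150 deg/s; PSO above 1500 deg/s^2 acceleration; pursuit
  # above 8 deg/s; fixation otherwise), with empirical per-group moments;
  # canonical signatures stand in for empty groups
  nf <- ncol(features)
  mu0 <- matrix(c(1.5, 4.0,    # fixation
                  3.3, 5.2,    # pursuit
                  4.2, 7.2,    # pso
                  5.7, 9.0),   # saccade
                nrow = 4, byrow = TRUE)[, 1:min(nf, 2), drop = FALSE]
  if (nf > 2) mu0 <- cbind(mu0, matrix(colMeans(features)[-(1:2)],
                                       4, nf - 2, byrow = TRUE))
  if (k == 4 && nf >= 2) {
    sp <- features[, 1]; ac <- features[, 2]
    z0 <- ifelse(sp > log(151), 4L,
                 ifelse(ac > log(1501), 3L, ifelse(sp > log(9), 2L, 1L)))
    mu <- mu0
    sg <- matrix(0.9, k, nf)
    for (s in 1:k) {
      sel <- z0 == s
      if (sum(sel) >= 10) {
        mu[s, ] <- colMeans(features[sel, , drop = FALSE])
        sg[s, ] <- pmax(apply(features[sel, , drop = FALSE], 2, stats::sd),
                        sd_floor)
      }
    }
  } else {
    qs <- stats::quantile(features[, 1],
                          probs = seq(0.1, 0.9, length.out = k))
    mu <- cbind(qs, matrix(rep(colMeans(features)[-1], each = k),
                           nrow = k))[, 1:nf, drop = FALSE]
    sg <- matrix(0.9, k, nf)
  }
  mu_prior <- mu
  Pi <- rep(1 / k, k)
  A <- matrix(0.4 / (k - 1), k, k); diag(A) <- 0.6
  # transition pseudocount prior: sticky diagonal, plus saccade (fastest
  # initial state, k) -> pso successor (k - 1); structural constraint: the
  # PSO state is only reachable from a saccade (or itself)
  prior <- matrix(0.5, k, k) + diag(rep(5, k))
  mask <- matrix(1, k, k)
  if (k == 4) {
    prior[k, k - 1] <- prior[k, k - 1] + 3
    mask[1:(k - 2), k - 1] <- 0
  }
  A <- A * mask; A <- A / rowSums(A)
  prior <- prior * mask

  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    logB <- vapply(1:k, function(s) dmvnorm_diag_log(features, mu[s, ], sg[s, ]),
                   numeric(n))
    fb <- hmm_forward_backward(logB, Pi, A)
    if (!is.finite(fb$loglik))
      stopf("EM diverged (non-finite likelihood) at iteration %d", it)
    loglik <- c(loglik, fb$loglik)
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol * abs(loglik[it - 1]))
      break
    g <- fb$gamma
    # xi sums for transitions
    xs <- matrix(0, k, k)
    for (i in 1:(n - 1)) {
      lm <- outer(fb$la[i, ], logB[i + 1, ] + fb$lb[i + 1, ], "+") +
        fb$logA - fb$loglik
      m <- exp(lm - max(lm))
      xs <- xs + m / sum(m)
    }
    A <- (xs + prior) * mask
    A <- A / rowSums(A)
    Pi <- g[1, ] + 1e-3
    Pi <- Pi / sum(Pi)
    for (s in 1:k) {
      w <- g[, s]
      sw <- sum(w)
      # MAP update: conjugate prior anchors each state's mean at its
      # canonical signature (prior weight = mean_prior_n pseudo-frames)
      mu[s, ] <- (colSums(features * w) + mean_prior_n * mu_prior[s, ]) /
        (sw + mean_prior_n)
      sg[s, ] <- pmax(sqrt(colSums(sweep(features, 2, mu[s, ])^2 * w) / sw),
                      sd_floor)
    }
  }
  logB <- vapply(1:k, function(s) dmvnorm_diag_log(features, mu[s, ], sg[s, ]),
                 numeric(n))
  states <- hmm_viterbi(logB, Pi, A)

  # relabel: sort by mean speed; middle two split by mean acceleration
  ord <- order(mu[, 1])
  cls <- character(k)
  cls[ord[1]] <- "fixation"
  cls[ord[k]] <- "saccade"
  mid <- ord[2:(k - 1)]
  if (length(mid) == 2) {
    acc_col <- min(2, ncol(features))
    if (mu[mid[1], acc_col] >= mu[mid[2], acc_col]) {
      cls[mid[1]] <- "pso"; cls[mid[2]] <- "pursuit"
    } else {
      cls[mid[1]] <- "pursuit"; cls[mid[2]] <- "pso"
    }
  } else cls[mid] <- "pursuit"

  structure(list(labels = cls[states], states = states,
                 spec = list(means = mu, sds = sg, transition = A,
                             initial = Pi, classes = cls),
                 loglik = loglik, degenerate = FALSE),
            class = "sw_hmm")
}

#' Build HMM emission features from angular kinematics
#'
#' Log-transformed angular speed and acceleration magnitude from the
#' central-difference kinematics (no extra smoothing: pre-smoothing blurs
#' saccade boundaries more than it suppresses slow tracker drift).
#'
#' @param kin Output of [angular_kinematics()].
#' @return Matrix with columns log_speed, log_accel.
#' @export
hmm_features <- function(kin) {
  cbind(log_speed = log(kin$speed_dps + 1),
        log_accel = log(kin$accel_dps2 + 1))
}

#' Collapse per-frame labels into event segments
#'
#' Maximal runs of one label become segments. A segment's amplitude is the
#' great-circle angle between the cyclopean gaze directions at its first and
#' last frame. Fixation-saccade pairs (fixation duration d_i, amplitude a_i
#' of the immediately following saccade) feed the K-coefficient.
#'
#' @param labels Character labels, one per frame.
#' @param frames Frame table (for timestamps and eye directions).
#' @param velocity Optional speed series for per-segment mean velocity.
#' @return data.frame: type, t_start, t_end, duration_s, amplitude_deg,
#'   mean_velocity_dps, n_frames. Segments tile the trial span.
#' @export
segment_events <- function(labels, frames, velocity = NULL) {
  n <- nrow(frames)
  if (length(labels) != n) stopf("labels and frames lengths differ")
  t <- frames$t
  dt <- stats::median(diff(t))
  dir <- cbind((frames$eyeL_dx + frames$eyeR_dx) / 2,
               (frames$eyeL_dy + frames$eyeR_dy) / 2,
               (frames$eyeL_dz + frames$eyeR_dz) / 2)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  t_end <- c(t[starts[-1]], t[n] + dt)
  amp <- vapply(seq_along(starts), function(i)
    angle_between_deg(dir[starts[i], ], dir[ends[i], ]), numeric(1))
  mv <- if (is.null(velocity)) NA_real_ else
    vapply(seq_along(starts), function(i)
      mean(velocity[starts[i]:ends[i]]), numeric(1))
  data.frame(type = r$values, t_start = t[starts], t_end = t_end,
             duration_s = t_end - t[starts], amplitude_deg = amp,
             mean_velocity_dps = mv, n_frames = r$lengths,
             stringsAsFactors = FALSE)
}

#' Fixation-saccade pairs for the K-coefficient
#'
#' @param segments From [segment_events()].
#' @return data.frame with one row per fixation immediately followed by a
#'   saccade: t_mid (fixation midpoint), d (fixation duration, s), a
#'   (saccade amplitude, deg). Fixations followed by pursuit or PSO are not
#'   paired.
#' @export
fixation_saccade_pairs <- function(segments) {
  i <- which(segments$type == "fixation")
  i <- i[i < nrow(segments) & segments$type[i + 1] == "saccade"]
  data.frame(t_mid = (segments$t_start[i] + segments$t_end[i]) / 2,
             d = segments$duration_s[i],
             a = segments$amplitude_deg[i + 1])
}

#' Event statistics per trial phase
#'
#' Segments are assigned to the phase containing their midpoint; per phase
#' and event type, reports counts and mean/median durations plus mean
#' saccade amplitude. Phases with no events of a type report a zero count
#' and NA statistics.
#'
#' @param segments From [segment_events()].
#' @param phases Phase table from [segment_phases()].
#' @return data.frame: phase, type, n, mean_duration_s, median_duration_s,
#'   mean_amplitude_deg.
#' @export
event_stats_by_phase <- function(segments, phases) {
  mid <- (segments$t_start + segments$t_end) / 2
  ph <- phases$label[findInterval(mid, phases$t_start)]
  grid <- expand.grid(phase = phases$label, type = EVENT_TYPES,
                      stringsAsFactors = FALSE)
  stats_row <- function(p, ty) {
    d <- segments[ph == p & segments$type == ty, , drop = FALSE]
    data.frame(phase = p, type = ty, n = nrow(d),
               mean_duration_s = if (nrow(d)) mean(d$duration_s) else NA_real_,
               median_duration_s = if (nrow(d)) median(d$duration_s) else NA_real_,
               mean_amplitude_deg = if (nrow(d)) mean(d$amplitude_deg) else NA_real_)
  }
  do.call(rbind, Map(stats_row, grid$phase, grid$type))
}
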