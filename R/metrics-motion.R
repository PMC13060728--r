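# Trajectory metrics: gap-crossing position, distance from midline, speed
# profiles, gaze-movement alignment, and gaze density maps.

#' Crossing position within the inter-walker gap
#'
#' At the first frame the participant reaches a row's z line, measures the
#' along-row (x) distance to the walker just passed (rear-facing, showing
#' its back) and to the oncoming walker (front-facing). The gap fraction is
#' d_rear / (d_rear + d_front): 0.5 is mid-gap, small values hug the
#' rear-facing agent.
#'
#' @param head Head series (t, x, z or head_x/head_z).
#' @param walker_tracks From [simulate_walkers()] or a read trial log.
#' @param layout An `sw_scene`.
#' @return data.frame with one row per row line: row, t_cross, d_rear,
#'   d_front, gap_fraction; NA with a `reason` when the row is never
#'   crossed or no walkers straddle the crossing point.
#' @export
gap_crossing <- function(head, walker_tracks, layout) {
  x <- head$head_x %||% head$x
  z <- head$head_z %||% head$z
  t <- head$t
  out <- lapply(1:2, function(row) {
    zl <- if (row == 1) layout$row1_z else layout$row2_z
    i <- match(TRUE, z >= zl)
    if (is.na(i))
      return(data.frame(row = row, t_cross = NA_real_, d_rear = NA_real_,
                        d_front = NA_real_, gap_fraction = NA_real_,
                        reason = "row not crossed", stringsAsFactors = FALSE))
    tc <- t[i]; xp <- x[i]
    tr <- Filter(function(w) w$row == row, walker_tracks)
    if (!length(tr))
      return(data.frame(row = row, t_cross = tc, d_rear = NA_real_,
                        d_front = NA_real_, gap_fraction = NA_real_,
                        reason = "no walkers", stringsAsFactors = FALSE))
    dir <- if (tr[[1]]$direction == "left_to_right") 1 else -1
    wx <- vapply(tr, function(w) {
      j <- findInterval(tc, w$positions$t, all.inside = TRUE)
      w$positions$x[j]
    }, numeric(1))
    along <- dir * (wx - xp)       # positive: walker already passed (rear)
    rear <- along[along > 0]
    front <- along[along < 0]
    if (!length(rear) || !length(front))
      return(data.frame(row = row, t_cross = tc, d_rear = NA_real_,
                        d_front = NA_real_, gap_fraction = NA_real_,
                        reason = "no straddling pair", stringsAsFactors = FALSE))
    d_rear <- min(rear)
    d_front <- min(-front)
    data.frame(row = row, t_cross = tc, d_rear = d_rear, d_front = d_front,
               gap_fraction = d_rear / (d_rear + d_front),
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean distance from the room midline over the bench zone
#'
#' @param head Head series.
#' @param zone z range, defaults to the layout's bench zone (2.0-4.1 m).
#' @param layout Optional `sw_scene` supplying the zone.
#' @return Mean |x| in meters over frames inside the zone (NA if none).
#' @export
distance_from_midline <- function(head, zone = NULL, layout = NULL) {
  if (is.null(zone))
    zone <- (layout %||% build_default_scene())$bench_zone
  x <- head$head_x %||% head$x
  z <- head$head_z %||% head$z
  sel <- z >= zone[1] & z <= zone[2]
  if (!any(sel)) return(NA_real_)
  mean(abs(x[sel]))
}

#' Walking-speed profile along the room depth
#'
#' Horizontal frame speeds (central differences on x, z) binned by z;
#' reports the mean and interquartile range per bin. Empty bins are
#' missing, not zero.
#'
#' @param head Head series (>= 2 frames).
#' @param z_edges Bin edges along z (default 0.25 m bins over the room).
#' @return data.frame: z_mid, mean_speed, q25, q75, n.
#' @export
speed_profile <- function(head, z_edges = seq(0, 6, by = 0.25)) {
  x <- head$head_x %||% head$x
  z <- head$head_z %||% head$z
  t <- head$t
  if (length(t) < 2) stopf("speed profile requires at least 2 frames")
  sp <- sqrt(cdiff(x, t)^2 + cdiff(z, t)^2)
  bin <- cut(z, z_edges, labels = FALSE)
  out <- data.frame(z_mid = (head(z_edges, -1) + z_edges[-1]) / 2,
                    mean_speed = NA_real_, q25 = NA_real_, q75 = NA_real_,
                    n = 0L)
  for (b in unique(bin[!is.na(bin)])) {
    s <- sp[!is.na(bin) & bin == b]
    out$mean_speed[b] <- mean(s)
    out$q25[b] <- unname(quantile(s, 0.25))
    out$q75[b] <- unname(quantile(s, 0.75))
    out$n[b] <- length(s)
  }
  out
}

#' Signed angle between movement direction and gaze direction
#'
#' Horizontal-plane angle in (-180, 180] degrees between the heading
#' (smoothed finite differences of the head path) and the cyclopean gaze
#' direction: 0 is gaze along heading, positive is gaze to the right of
#' heading, +/-180 a look backward. Frames moving slower than `speed_floor`
#' are flagged stationary but still reported (their heading is the last
#' reliable one).
#'
#' @param frames Frame table with head and eye columns.
#' @param speed_floor Stationary threshold, m/s.
#' @param smooth_frames Moving-average length for the heading estimate.
#' @return data.frame: t, angle_deg, speed_mps, stationary.
#' @export
gaze_movement_alignment <- function(frames, speed_floor = 0.15,
                                    smooth_frames = 9) {
  t <- frames$t
  x <- frames$head_x
  z <- frames$head_z
  ma <- function(v) as.numeric(stats::filter(v, rep(1 / smooth_frames,
                                                    smooth_frames),
                                             sides = 2))
  xs <- ma(x); zs <- ma(z)
  xs[is.na(xs)] <- x[is.na(xs)]; zs[is.na(zs)] <- z[is.na(zs)]
  hx <- cdiff(xs, t)
  hz <- cdiff(zs, t)
  speed <- sqrt(hx^2 + hz^2)
  stationary <- speed < speed_floor
  # carry the last reliable heading through stationary stretches
  if (any(!stationary)) {
    idx <- seq_along(t)
    good <- which(!stationary)
    nearest <- good[pmax(findInterval(idx, good), 1)]
    hx <- hx[nearest]; hz <- hz[nearest]
  } else {
    hx <- rep(0, length(t)); hz <- rep(1, length(t))
  }
  gx <- (frames$eyeL_dx + frames$eyeR_dx) / 2
  gz <- (frames$eyeL_dz + frames$eyeR_dz) / 2
  ang <- atan2(hz * gx - hx * gz, hx * gx + hz * gz) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  data.frame(t = t, angle_deg = ang, speed_mps = speed,
             stationary = stationary)
}

#' Smoothed gaze density map
#'
#' 2D (x, z) histogram of gaze points smoothed with a Gaussian kernel
#' (default s.d. 0.3 m) and normalized to total mass 1.
#'
#' @param points data.frame with x, z (NA rows dropped).
#' @param bin_m Bin size, meters.
#' @param kernel_sd_m Gaussian kernel standard deviation, meters.
#' @param layout Optional `sw_scene` for the map extent.
#' @return List: `x_mid`, `z_mid`, `density` (matrix, rows = x bins), sum 1.
#' @export
gaze_density_grid <- function(points, bin_m = 0.1, kernel_sd_m = 0.3,
                              layout = NULL) {
  if (bin_m <= 0) stopf("bin_m must be > 0")
  layout <- layout %||% build_default_scene()
  hw <- layout$room_width_x / 2
  xe <- seq(-hw, hw, by = bin_m)
  ze <- seq(0, layout$room_length_z, by = bin_m)
  ok <- !is.na(points$x) & !is.na(points$z)
  px <- pmin(pmax(points$x[ok], -hw + 1e-9), hw - 1e-9)
  pz <- pmin(pmax(points$z[ok], 1e-9), layout$room_length_z - 1e-9)
  h <- table(cut(px, xe), cut(pz, ze))
  m <- matrix(as.numeric(h), nrow = length(xe) - 1)
  # separable Gaussian smoothing
  sd_bins <- kernel_sd_m / bin_m
  half <- ceiling(3 * sd_bins)
  kern <- stats::dnorm(-half:half, sd = sd_bins)
  kern <- kern / sum(kern)
  smooth1 <- function(mat) apply(mat, 2, function(col) {
    padded <- c(rep(0, half), col, rep(0, half))
    stats::convolve(padded, rev(kern), type = "filter")
  })
  m <- smooth1(m)
  m <- t(smooth1(t(m)))
  if (sum(m) > 0) m <- m / sum(m)
  list(x_mid = (head(xe, -1) + xe[-1]) / 2,
       z_mid = (head(ze, -1) + ze[-1]) / 2,
       density = m)
}
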