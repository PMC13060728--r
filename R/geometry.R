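# 3D gaze reconstruction: vergence ray intersection, collider ray-casting,
# object attribution, and spatial discretization for entropy analysis.

#' Intersect the two eyes' gaze rays (vergence)
#'
#' Returns the midpoint of the shortest segment between the two rays,
#' restricted to non-negative ray parameters. `quality` is the length of
#' that segment (0 for exactly converging rays). Near-parallel rays (cross
#' product below 1e-9) carry no finite vergence point; the method degrades
#' to the collider fallback marker.
#'
#' @param o1,d1 Origin and unit direction of the left-eye ray.
#' @param o2,d2 Origin and unit direction of the right-eye ray.
#' @return List (class `sw_gazepoint`): `point` (xyz or NA), `quality`
#'   (meters), `method` ("vergence" or "collider_fallback").
#' @export
intersect_gaze_rays <- function(o1, d1, o2, d2) {
  if (vnorm(d1) < 1e-12 || vnorm(d2) < 1e-12)
    stopf("gaze ray direction must be non-zero")
  d1 <- d1 / vnorm(d1); d2 <- d2 / vnorm(d2)
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  if (vnorm(cr) < 1e-9) {
    return(structure(list(point = c(NA_real_, NA_real_, NA_real_),
                          quality = NA_real_, method = "collider_fallback"),
                     class = "sw_gazepoint"))
  }
  w <- o2 - o1
  b <- sum(d1 * d2)
  s <- (sum(w * d1) - b * sum(w * d2)) / (1 - b^2)
  u <- (b * sum(w * d1) - sum(w * d2)) / (1 - b^2)
  # rays, not lines: when the free optimum needs a negative parameter,
  # the constrained optimum lies on one of the two boundary edges
  if (s < 0 || u < 0) {
    cand <- list(c(0, max(0, -sum(w * d2))),       # s = 0 edge
                 c(max(0, sum(w * d1)), 0))        # u = 0 edge
    dist2 <- vapply(cand, function(p) {
      sum((o1 + p[1] * d1 - o2 - p[2] * d2)^2)
    }, numeric(1))
    p <- cand[[which.min(dist2)]]
    s <- p[1]; u <- p[2]
  }
  p1 <- o1 + s * d1
  p2 <- o2 + u * d2
  structure(list(point = (p1 + p2) / 2, quality = vnorm(p1 - p2),
                 method = "vergence"),
            class = "sw_gazepoint")
}

# axis-aligned slab test for one ray against many boxes; vectorized over rows
ray_box_hits <- function(origin, dir, boxes) {
  lo <- cbind(boxes$x - boxes$hx, boxes$y - boxes$hy, boxes$z - boxes$hz)
  hi <- cbind(boxes$x + boxes$hx, boxes$y + boxes$hy, boxes$z + boxes$hz)
  tmin <- rep(-Inf, nrow(boxes)); tmax <- rep(Inf, nrow(boxes))
  for (ax in 1:3) {
    if (abs(dir[ax]) < 1e-12) {
      miss <- origin[ax] < lo[, ax] | origin[ax] > hi[, ax]
      tmin[miss] <- Inf
    } else {
      t1 <- (lo[, ax] - origin[ax]) / dir[ax]
      t2 <- (hi[, ax] - origin[ax]) / dir[ax]
      tmin <- pmax(tmin, pmin(t1, t2))
      tmax <- pmin(tmax, pmax(t1, t2))
    }
  }
  hit <- tmin <= tmax & tmax > 0
  tpar <- ifelse(tmin > 0, tmin, tmax)   # origin inside box: exit distance
  list(hit = hit, t = tpar)
}

#' Cast a ray against scene and walker colliders
#'
#' Nearest axis-aligned-box intersection with positive ray parameter; a miss
#' is a value (`NULL`), not an error.
#'
#' @param origin,dir Ray origin and unit direction.
#' @param layout Condition-resolved `sw_scene`.
#' @param walker_tracks Optional walker track list; walkers are tested at
#'   their position at `time`.
#' @param time Frame time (required when walker tracks are given).
#' @return `NULL` on a miss, else list with `id`, `kind`, `point`
#'   (hit coordinates) and `distance`.
#' @export
cast_to_colliders <- function(origin, dir, layout, walker_tracks = NULL,
                              time = NULL) {
  if (abs(vnorm(dir) - 1) > 1e-6) dir <- normalize(dir)
  boxes <- layout$objects
  if (!is.null(walker_tracks) && length(walker_tracks)) {
    if (is.null(time)) stopf("time is required to place walker colliders")
    wb <- walker_boxes_at(walker_tracks, time)
    if (!is.null(wb)) boxes <- rbind(boxes, wb)
  }
  res <- ray_box_hits(origin, dir, boxes)
  if (!any(res$hit)) return(NULL)
  i <- which(res$hit)[which.min(res$t[res$hit])]
  list(id = boxes$id[i], kind = boxes$kind[i],
       point = origin + res$t[i] * dir, distance = res$t[i])
}

# shortest distance from a point to each axis-aligned box (0 if inside)
point_box_distance <- function(p, boxes) {
  dx <- pmax(abs(p[1] - boxes$x) - boxes$hx, 0)
  dy <- pmax(abs(p[2] - boxes$y) - boxes$hy, 0)
  dz <- pmax(abs(p[3] - boxes$z) - boxes$hz, 0)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Attribute a gaze point to a scene object
#'
#' Primary rule: the nearest object whose collider contains the vergence
#' point or lies within `snap_radius` of it; ties broken in favour of the
#' smaller collider volume. If no object is close enough (or the vergence
#' point is invalid), falls back to casting the cyclopean ray.
#'
#' @param gaze_point xyz vergence point (may contain NA).
#' @param cyclopean_origin,cyclopean_dir Fallback ray.
#' @param layout Condition-resolved `sw_scene`.
#' @param walker_tracks,time Walker states for moving colliders.
#' @param snap_radius Attribution radius around colliders, meters.
#' @return Object id (character), or `"none"`.
#' @export
attribute_gaze <- function(gaze_point, cyclopean_origin, cyclopean_dir,
                           layout, walker_tracks = NULL, time = NULL,
                           snap_radius = 0.1) {
  boxes <- layout$objects
  if (!is.null(walker_tracks) && length(walker_tracks)) {
    wb <- walker_boxes_at(walker_tracks, time)
    if (!is.null(wb)) boxes <- rbind(boxes, wb)
  }
  if (!any(is.na(gaze_point))) {
    d <- point_box_distance(gaze_point, boxes)
    ok <- d <= snap_radius
    if (any(ok)) {
      vol <- 8 * boxes$hx * boxes$hy * boxes$hz
      cand <- which(ok)
      cand <- cand[order(d[cand], vol[cand])]
      return(boxes$id[cand[1]])
    }
  }
  hit <- cast_to_colliders(cyclopean_origin, cyclopean_dir, layout,
                           walker_tracks, time)
  if (is.null(hit)) "none" else hit$id
}

#' Reconstruct and attribute gaze for every frame of a trial
#'
#' Runs vergence intersection per frame, validates the point against the
#' expanded room bounding box (room extent + 1 m), and attributes each frame
#' to a scene object (vergence-point rule with cyclopean-ray fallback, see
#' [attribute_gaze()]).
#'
#' @param trial An `sw_trial`.
#' @param snap_radius Attribution radius, meters.
#' @return data.frame: t, x, y, z (gaze point), quality, method, valid,
#'   target_id.
#' @export
attribute_frames <- function(trial, snap_radius = 0.1) {
  fr <- trial$frames
  n <- nrow(fr)
  out <- data.frame(t = fr$t, x = NA_real_, y = NA_real_, z = NA_real_,
                    quality = NA_real_, method = NA_character_,
                    valid = FALSE, target_id = "none",
                    stringsAsFactors = FALSE)
  half_w <- trial$layout$room_width_x / 2
  for (i in seq_len(n)) {
    if (!isTRUE(fr$valid[i])) next
    gp <- intersect_gaze_rays(
      c(fr$eyeL_ox[i], fr$eyeL_oy[i], fr$eyeL_oz[i]),
      c(fr$eyeL_dx[i], fr$eyeL_dy[i], fr$eyeL_dz[i]),
      c(fr$eyeR_ox[i], fr$eyeR_oy[i], fr$eyeR_oz[i]),
      c(fr$eyeR_dx[i], fr$eyeR_dy[i], fr$eyeR_dz[i]))
    co <- c((fr$eyeL_ox[i] + fr$eyeR_ox[i]) / 2,
            (fr$eyeL_oy[i] + fr$eyeR_oy[i]) / 2,
            (fr$eyeL_oz[i] + fr$eyeR_oz[i]) / 2)
    cd <- normalize(c(fr$eyeL_dx[i] + fr$eyeR_dx[i],
                      fr$eyeL_dy[i] + fr$eyeR_dy[i],
                      fr$eyeL_dz[i] + fr$eyeR_dz[i]))
    p <- gp$point
    in_box <- !any(is.na(p)) &&
      p[1] >= -half_w - 1 && p[1] <= half_w + 1 &&
      p[2] >= -1 && p[2] <= 3.5 &&
      p[3] >= -1 && p[3] <= trial$layout$room_length_z + 1
    out$method[i] <- gp$method
    out$quality[i] <- gp$quality
    if (in_box) {
      out[i, c("x", "y", "z")] <- p
      out$valid[i] <- TRUE
    } else {
      p <- c(NA_real_, NA_real_, NA_real_)
    }
    out$target_id[i] <- attribute_gaze(p, co, cd, trial$layout,
                                       trial$walker_tracks, fr$t[i],
                                       snap_radius)
  }
  out
}

#' Spatial grid specification for gaze discretization
#'
#' @param bins Integer c(n_x, n_z, n_y); default 6 x 12 x 3 (216 states).
#' @param extents List of ranges `x`, `z`, `y`; defaults to the room
#'   footprint and a 0-2.5 m height span.
#' @param layout Optional `sw_scene` supplying the room footprint.
#' @return List of class `sw_grid` with `bins`, `extents`, `n_states`.
#' @export
grid_spec <- function(bins = c(6, 12, 3), extents = NULL, layout = NULL) {
  if (length(bins) != 3 || any(bins < 1) || any(bins != round(bins)))
    stopf("bins must be three positive integers")
  if (is.null(extents)) {
    if (is.null(layout)) layout <- build_default_scene()
    hw <- layout$room_width_x / 2
    extents <- list(x = c(-hw, hw), z = c(0, layout$room_length_z),
                    y = c(0, 2.5))
  }
  structure(list(bins = as.integer(bins), extents = extents,
                 n_states = as.integer(prod(bins))),
            class = "sw_grid")
}

#' Discretize gaze points into grid states
#'
#' Maps each valid point to one of `n_states` integer states (1-based);
#' out-of-extent coordinates clamp to the boundary bins; invalid points
#' (NA coordinates) become NA.
#'
#' @param points data.frame with x, y, z (e.g. from [attribute_frames()]).
#' @param grid An `sw_grid` from [grid_spec()].
#' @return Integer state sequence in `[1, n_states]`, NA for invalid points.
#' @export
discretize_gaze <- function(points, grid = grid_spec()) {
  bin1 <- function(v, rng, nb) {
    i <- floor((v - rng[1]) / (rng[2] - rng[1]) * nb) + 1
    pmin(pmax(i, 1), nb)
  }
  ix <- bin1(points$x, grid$extents$x, grid$bins[1])
  iz <- bin1(points$z, grid$extents$z, grid$bins[2])
  iy <- bin1(points$y, grid$extents$y, grid$bins[3])
  st <- ix + grid$bins[1] * (iz - 1) + grid$bins[1] * grid$bins[2] * (iy - 1)
  as.integer(st)
}

#' Angular kinematics of the cyclopean gaze direction
#'
#' Converts per-frame cyclopean gaze directions to azimuth/elevation (with
#' azimuth unwrapping), then estimates angular velocity and acceleration by
#' central differences (one-sided at the endpoints). Speeds are great-circle
#' rates: sqrt((daz/dt * cos(el))^2 + (del/dt)^2).
#'
#' @param frames Frame table with eye-ray columns (>= 3 rows, strictly
#'   increasing t).
#' @return data.frame: t, az_deg, el_deg, speed_dps, accel_dps2.
#' @export
angular_kinematics <- function(frames) {
  if (nrow(frames) < 3) stopf("angular kinematics require at least 3 frames")
  t <- frames$t
  if (any(diff(t) <= 0)) stopf("timestamps must be strictly increasing")
  dx <- (frames$eyeL_dx + frames$eyeR_dx) / 2
  dy <- (frames$eyeL_dy + frames$eyeR_dy) / 2
  dz <- (frames$eyeL_dz + frames$eyeR_dz) / 2
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  dx <- dx / nrm; dy <- dy / nrm; dz <- dz / nrm
  az <- unwrap_rad(atan2(dx, dz)) * 180 / pi
  el <- asin(pmin(pmax(dy, -1), 1)) * 180 / pi
  vaz <- cdiff(az, t)
  vel <- cdiff(el, t)
  speed <- sqrt((vaz * cos(el * pi / 180))^2 + vel^2)
  aaz <- cdiff(vaz * cos(el * pi / 180), t)
  ael <- cdiff(vel, t)
  accel <- sqrt(aaz^2 + ael^2)
  data.frame(t = t, az_deg = az, el_deg = el,
             speed_dps = speed, accel_dps2 = accel)
}

# central differences with one-sided endpoints
cdiff <- function(x, t) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

unwrap_rad <- function(a) {
  d <- diff(a)
  jump <- cumsum(c(0, round(d / (2 * pi))))
  a - 2 * pi * jump
}
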