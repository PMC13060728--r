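# Headline gaze metrics: attention-type allocation, gaze transition entropy
# (GTE), and the ambient-focal K coefficient.

ATTENTION_LABELS <- c("local", "global", "task_related", "miscellaneous")

#' Phase-by-object attention map
#'
#' The lookup from (trial phase, object kind) to attention type. Obstacles
#' to be passed imminently are local; obstacles for a future phase are
#' global; information sources (gate indicator, timer) are task related;
#' everything unlisted — walls, decor, unattributed gaze — is miscellaneous.
#' The timer is task related in every phase (information sources take
#' precedence over the obstacle classes).
#'
#' @return data.frame: phase, kind, label; total over all phase x kind
#'   pairs.
#' @export
default_attention_map <- function() {
  rowz <- function(phase, kind, label)
    data.frame(phase = phase, kind = kind, label = label,
               stringsAsFactors = FALSE)
  m <- rbind(
    rowz("initial_preparation", "walker_row1", "local"),
    rowz("initial_preparation",
         c("walker_row2", "gate_target", "gate_foil", "stander", "sitter",
           "bench"), "global"),
    rowz("initial_preparation", c("gate_indicator", "timer"), "task_related"),
    rowz("approaching_first_row",
         c("walker_row1", "stander", "sitter", "bench"), "local"),
    rowz("approaching_first_row", c("walker_row2", "gate_target", "gate_foil"),
         "global"),
    rowz("approaching_first_row", c("gate_indicator", "timer"), "task_related"),
    rowz("approaching_second_row",
         c("walker_row1", "walker_row2", "stander", "sitter", "bench"),
         "local"),
    rowz("approaching_second_row", c("gate_target", "gate_foil"), "global"),
    rowz("approaching_second_row", "timer", "task_related"),
    rowz("approaching_gate", "gate_target", "local"),
    rowz("approaching_gate", "timer", "task_related")
  )
  # complete the map: every unlisted phase x kind pair is miscellaneous
  full <- expand.grid(phase = PHASE_LABELS, kind = c(OBJECT_KINDS, "none"),
                      stringsAsFactors = FALSE)
  full$label <- "miscellaneous"
  key <- paste(m$phase, m$kind)
  hit <- match(paste(full$phase, full$kind), key)
  full$label[!is.na(hit)] <- m$label[hit[!is.na(hit)]]
  full
}

# object kind for an attributed target id
target_kind_of <- function(target_id, layout) {
  kind <- rep("none", length(target_id))
  w1 <- grepl("^r1_w", target_id)
  w2 <- grepl("^r2_w", target_id)
  kind[w1] <- "walker_row1"
  kind[w2] <- "walker_row2"
  rest <- !(w1 | w2) & target_id != "none"
  kind[rest] <- layout$objects$kind[match(target_id[rest], layout$objects$id)]
  kind[is.na(kind)] <- "none"
  kind
}

#' Attention label for one attributed gaze target
#'
#' Pure lookup in the attention map; unattributed gaze (`"none"`) is
#' miscellaneous.
#'
#' @param kind Object kind (see `default_attention_map()`), or `"none"`.
#' @param phase Phase label.
#' @param map Attention map, [default_attention_map()].
#' @return One of local/global/task_related/miscellaneous.
#' @export
label_attention <- function(kind, phase, map = default_attention_map()) {
  if (!all(phase %in% PHASE_LABELS))
    stopf("unknown phase: %s", setdiff(phase, PHASE_LABELS)[1])
  i <- match(paste(phase, kind), paste(map$phase, map$kind))
  out <- map$label[i]
  out[is.na(out)] <- "miscellaneous"
  out
}

#' Gaze allocation proportions per segment
#'
#' Shares of the four attention types among attributed frames in each
#' temporal segment (phases or mini-phases). Proportions sum to one per
#' non-empty segment; empty segments are dropped.
#'
#' @param t Frame times.
#' @param attention Per-frame attention label.
#' @param segments data.frame with label, t_start, t_end.
#' @return data.frame: segment, local, global, task_related, miscellaneous,
#'   n_frames.
#' @export
gaze_allocation <- function(t, attention, segments) {
  out <- lapply(seq_len(nrow(segments)), function(i) {
    sel <- t >= segments$t_start[i] & t < segments$t_end[i] &
      !is.na(attention)
    if (!any(sel)) return(NULL)
    tab <- table(factor(attention[sel], levels = ATTENTION_LABELS))
    p <- as.numeric(tab) / sum(tab)
    data.frame(segment = segments$label[i],
               local = p[1], global = p[2], task_related = p[3],
               miscellaneous = p[4], n_frames = sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gaze transition entropy over rolling windows
#'
#' Within each window of `window` frames, estimates first-order transition
#' probabilities among the grid states observed there and computes the
#' conditional Shannon entropy H(next | current) =
#' -sum_i p(i) sum_j p(j|i) log2 p(j|i), normalized by log2 of the number of
#' distinct states observed in the window. Windows with fewer than two
#' distinct states (no transitions to condition on) are missing, never 0.
#'
#' @param states Integer state sequence (NA allowed; NA transitions are
#'   dropped).
#' @param window Window length in frames (default 80; >= 2).
#' @param stride Window advance in frames (default 1, rolling).
#' @return List of class `sw_gte`: `windows` (data.frame start, gte) and
#'   `mean` (mean over defined windows, NA when none).
#' @export
gte <- function(states, window = 80, stride = 1) {
  if (!is_scalar_num(window) || window < 2) stopf("window must be >= 2")
  n <- length(states)
  starts <- if (n <= window) 1L else seq(1L, n - window + 1L, by = stride)
  vals <- vapply(starts, function(s) {
    w <- states[s:min(n, s + window - 1L)]
    gte_window(w)
  }, numeric(1))
  structure(list(windows = data.frame(start = starts, gte = vals),
                 mean = if (any(!is.na(vals))) mean(vals, na.rm = TRUE)
                        else NA_real_),
            class = "sw_gte")
}

gte_window <- function(w) {
  from <- w[-length(w)]
  to <- w[-1]
  ok <- !is.na(from) & !is.na(to)
  from <- from[ok]; to <- to[ok]
  if (!length(from)) return(NA_real_)
  st <- sort(unique(c(from, to)))
  if (length(st) < 2) return(NA_real_)
  tab <- table(factor(from, levels = st), factor(to, levels = st))
  rs <- rowSums(tab)
  p_i <- rs / sum(rs)
  h <- 0
  for (i in which(rs > 0)) {
    p_ij <- tab[i, ] / rs[i]
    nz <- p_ij > 0
    h <- h - p_i[i] * sum(p_ij[nz] * log2(p_ij[nz]))
  }
  h / log2(length(st))
}

#' Mean GTE per phase
#'
#' Assigns each rolling window to the phase containing its centre frame and
#' averages the defined window values.
#'
#' @param gte_res From [gte()].
#' @param t Frame times (aligned with the state sequence).
#' @param phases Phase table.
#' @param window Window length used in [gte()].
#' @return data.frame: phase, gte (NA where no defined windows).
#' @export
gte_by_phase <- function(gte_res, t, phases, window = 80) {
  centre <- t[pmin(gte_res$windows$start + window %/% 2, length(t))]
  ph <- phases$label[findInterval(centre, phases$t_start)]
  v <- gte_res$windows$gte
  out <- data.frame(phase = phases$label, gte = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    vv <- v[ph == out$phase[i] & !is.na(v)]
    if (length(vv)) out$gte[i] <- mean(vv)
  }
  out
}

#' Ambient-focal K coefficient
#'
#' For each fixation followed immediately by a saccade, K_i is the
#' standardized fixation duration minus the standardized amplitude of that
#' saccade, with means and standard deviations taken over the trial's
#' pairs. Positive K marks focal attention (long fixations, small
#' saccades); negative K ambient scanning. By z-score construction the
#' grand mean of K over the normalization scope is zero.
#'
#' @param pairs data.frame from [fixation_saccade_pairs()] (columns d, a,
#'   optionally t_mid).
#' @param phases Optional phase table for per-phase means (pairs assigned by
#'   fixation midpoint).
#' @return List of class `sw_k`: `k` per event, `mean_by_phase` (if phases
#'   given), `mu_d`, `sd_d`, `mu_a`, `sd_a`, `degenerate` (TRUE when either
#'   spread is zero or fewer than 2 pairs; K is then missing).
#' @export
k_coefficient <- function(pairs, phases = NULL) {
  n <- nrow(pairs)
  if (n < 2 || stats::sd(pairs$d) == 0 || stats::sd(pairs$a) == 0) {
    return(structure(list(k = rep(NA_real_, n), mean_by_phase = NULL,
                          mu_d = if (n) mean(pairs$d) else NA_real_,
                          sd_d = if (n > 1) stats::sd(pairs$d) else NA_real_,
                          mu_a = if (n) mean(pairs$a) else NA_real_,
                          sd_a = if (n > 1) stats::sd(pairs$a) else NA_real_,
                          degenerate = TRUE),
                     class = "sw_k"))
  }
  k <- (pairs$d - mean(pairs$d)) / stats::sd(pairs$d) -
       (pairs$a - mean(pairs$a)) / stats::sd(pairs$a)
  mbp <- NULL
  if (!is.null(phases) && !is.null(pairs$t_mid)) {
    ph <- phases$label[findInterval(pairs$t_mid, phases$t_start)]
    mbp <- data.frame(phase = phases$label, k = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(mbp))) {
      kk <- k[ph == mbp$phase[i]]
      if (length(kk)) mbp$k[i] <- mean(kk)
    }
  }
  structure(list(k = k, mean_by_phase = mbp,
                 mu_d = mean(pairs$d), sd_d = stats::sd(pairs$d),
                 mu_a = mean(pairs$a), sd_a = stats::sd(pairs$a),
                 degenerate = FALSE),
            class = "sw_k")
}
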