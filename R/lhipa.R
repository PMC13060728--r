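# Low/high index of pupillary activity: a wavelet-based pupil-oscillation
# ratio with an inverse relationship to cognitive load.

#' Low/high index of pupillary activity
#'
#' Decomposes the pupil-diameter series with a periodized sym16 wavelet
#' transform and counts modulus maxima of the detail coefficients in a
#' low- and a high-frequency band, keeping only maxima that clear a noise
#' floor (Donoho universal threshold, with the noise scale estimated from
#' the finest-detail coefficients by MAD). The index is the ratio of the
#' low-band to the high-band maxima rate over the window: cognitive load
#' drives high-frequency pupil oscillation, so higher load gives a lower
#' index.
#'
#' Missing samples are linearly interpolated across gaps up to
#' `max_gap_s`; longer gaps reject the window. A constant series (no
#' maxima in either band) is flagged degenerate.
#'
#' @param pupil Pupil-diameter series, millimetres (NA = missing).
#' @param fs Sampling rate, Hz (> 0).
#' @param low_level,high_level Decomposition levels of the two bands. The
#'   defaults place the high band at 2.5-5 Hz and the low band at
#'   0.625-1.25 Hz for an 80 Hz stream; for other rates the levels are
#'   chosen to cover the same frequencies.
#' @param max_gap_s Longest interpolatable gap, seconds.
#' @return List of class `sw_lhipa`: `value` (the index; NA when
#'   degenerate or rejected), `low_rate`, `high_rate` (maxima per second),
#'   `status` ("ok", "degenerate", "gap_rejected", "too_short").
#' @export
lhipa <- function(pupil, fs, low_level = NULL, high_level = NULL,
                  max_gap_s = 0.2) {
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be > 0")
  res <- function(value, lo = NA_real_, hi = NA_real_, status)
    structure(list(value = value, low_rate = lo, high_rate = hi,
                   status = status), class = "sw_lhipa")
  # band levels covering ~2.5-5 Hz (high) and ~0.625-1.25 Hz (low)
  high_level <- high_level %||% max(1L, round(log2(fs / 5)))
  low_level <- low_level %||% (high_level + 2L)
  if (length(pupil) < 2^(low_level + 1))
    return(res(NA_real_, status = "too_short"))

  if (anyNA(pupil)) {
    r <- rle(is.na(pupil))
    if (any(r$values & r$lengths > max_gap_s * fs))
      return(res(NA_real_, status = "gap_rejected"))
    ok <- which(!is.na(pupil))
    if (length(ok) < 2) return(res(NA_real_, status = "gap_rejected"))
    pupil <- stats::approx(ok, pupil[ok], xout = seq_along(pupil),
                           rule = 2)$y
  }
  dur <- length(pupil) / fs
  if (stats::sd(pupil) < 1e-12)
    return(res(NA_real_, status = "degenerate"))

  cd1 <- dwt_detail(pupil, 1)
  sigma <- stats::median(abs(cd1)) / 0.6745
  count_band <- function(level) {
    cd <- dwt_detail(pupil, level)
    lam <- sigma * sqrt(2 * log(length(cd)))
    m <- abs(cd)
    n <- length(m)
    if (n < 3) return(0L)
    i <- 2:(n - 1)
    is_max <- m[i] > m[i - 1] & m[i] >= m[i + 1] & m[i] > lam
    sum(is_max)
  }
  n_lo <- count_band(low_level)
  n_hi <- count_band(high_level)
  if (n_lo == 0 && n_hi == 0) return(res(NA_real_, status = "degenerate"))
  if (n_hi == 0) return(res(NA_real_, lo = n_lo / dur, hi = 0,
                            status = "degenerate"))
  res((n_lo / dur) / (n_hi / dur), lo = n_lo / dur, hi = n_hi / dur,
      status = "ok")
}

#' LHIPA per trial phase
#'
#' Applies [lhipa()] to the pupil samples of each phase window.
#'
#' @param pupil Pupil series aligned with `t`.
#' @param t Frame times.
#' @param phases Phase table from [segment_phases()].
#' @param fs Sampling rate, Hz.
#' @return data.frame: phase, lhipa, status.
#' @export
lhipa_by_phase <- function(pupil, t, phases, fs) {
  out <- lapply(seq_len(nrow(phases)), function(i) {
    sel <- t >= phases$t_start[i] & t < phases$t_end[i]
    r <- lhipa(pupil[sel], fs)
    data.frame(phase = phases$label[i], lhipa = r$value, status = r$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
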