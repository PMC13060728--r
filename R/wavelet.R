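# Periodized discrete wavelet transform (pyramid algorithm) with the
# symlet-16 filter pair. Filter coefficients are the standard published
# constants for sym16; the periodized single-level step is
#   c_k = sum_m h[m] * x[(2k + L/2 - m) mod n]
# which halves the series length at each level.

SYM16_DEC_LO <- c(
  6.230006701220761e-06, -3.113556407621969e-06, -1.0943147929529757e-04,
  2.8078582128442894e-05, 8.523547108047095e-04, -1.084456223089688e-04,
  -3.8809122526038786e-03, 7.182119788317892e-04, 1.2666731659857348e-02,
  -3.1265171722710075e-03, -3.1051202843553064e-02, 4.869274404904607e-03,
  3.2333091610663785e-02, -6.698304907021778e-02, -3.4574228416972504e-02,
  3.9712293362064416e-01, 7.565249878756971e-01, 4.7534280601152273e-01,
  -5.4040601387606135e-02, -1.5959219218520598e-01, 3.072113906330156e-02,
  7.803785290341991e-02, -3.510275068374009e-03, -2.4952758046290123e-02,
  1.359844742484172e-03, 6.9377611308027096e-03, -2.2211647621176323e-04,
  -1.3387206066921965e-03, 3.656592483348223e-05, 1.6545679579108483e-04,
  -5.396483179315242e-06, -1.0797982104319795e-05)

SYM16_DEC_HI <- c(
  1.0797982104319795e-05, -5.396483179315242e-06, -1.6545679579108483e-04,
  3.656592483348223e-05, 1.3387206066921965e-03, -2.2211647621176323e-04,
  -6.9377611308027096e-03, 1.359844742484172e-03, 2.4952758046290123e-02,
  -3.510275068374009e-03, -7.803785290341991e-02, 3.072113906330156e-02,
  1.5959219218520598e-01, -5.4040601387606135e-02, -4.7534280601152273e-01,
  7.565249878756971e-01, -3.9712293362064416e-01, -3.4574228416972504e-02,
  6.698304907021778e-02, 3.2333091610663785e-02, -4.869274404904607e-03,
  -3.1051202843553064e-02, 3.1265171722710075e-03, 1.2666731659857348e-02,
  -7.182119788317892e-04, -3.8809122526038786e-03, 1.084456223089688e-04,
  8.523547108047095e-04, -2.8078582128442894e-05, -1.0943147929529757e-04,
  3.113556407621969e-06, 6.230006701220761e-06)

# one periodized analysis step (odd-length inputs repeat the last sample)
dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
  L <- length(filt)
  k <- 0:(n / 2 - 1)
  idx <- outer(2 * k + L / 2, 0:(L - 1), "-") %% n
  as.numeric(matrix(x[idx + 1], nrow = length(k)) %*% filt)
}

#' Detail coefficients of the periodized sym16 wavelet transform
#'
#' Runs the pyramid algorithm: the approximation is refined level by level
#' and the requested level's detail coefficients are returned.
#'
#' @param x Numeric series.
#' @param level Decomposition level (>= 1); the detail band spans
#'   approximately `fs / 2^(level+1)` to `fs / 2^level` Hz.
#' @return Detail coefficients (length about `length(x) / 2^level`).
#' @export
dwt_detail <- function(x, level) {
  if (level < 1 || level != round(level)) stopf("level must be a positive integer")
  if (length(x) < 2^level)
    stopf("series too short for level %d decomposition", level)
  a <- x
  for (l in seq_len(level - 1)) a <- dwt_step(a, SYM16_DEC_LO)
  dwt_step(a, SYM16_DEC_HI)
}
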