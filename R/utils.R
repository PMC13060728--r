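# internal helpers shared across modules

#' @importFrom stats rnorm runif rlnorm rgamma median quantile sd aggregate
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# smoothstep on [0,1], clamped outside
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# minimum-jerk position profile on [0,1]
minjerk <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  10 * u^3 - 15 * u^4 + 6 * u^5
}

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# great-circle angle between two unit vectors, degrees
angle_between_deg <- function(a, b) {
  d <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

# draw n sub-seeds (31-bit) under a parent seed without touching global RNG
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
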