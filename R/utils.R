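# Internal validation and small numeric helpers.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# angle between two arbitrary nonzero vectors, radians in [0, pi]
vec_angle <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("degenerate direction: zero-norm vector has no angle", call. = FALSE)
  }
  acos(clamp(sum(u * v) / (nu * nv), -1, 1))
}

assert_direction <- function(phi, arg = "phi") {
  if (!is.numeric(phi) || length(phi) < 1L || anyNA(phi)) {
    stop(sprintf("`%s` must be a numeric vector without NAs", arg), call. = FALSE)
  }
  if (any(phi < 0)) {
    stop(sprintf("`%s` must have nonnegative per-capita contributions", arg),
         call. = FALSE)
  }
  if (all(phi == 0)) {
    stop(sprintf("degenerate direction: `%s` has no positive contribution", arg),
         call. = FALSE)
  }
  invisible(phi)
}

assert_abundance <- function(N, arg = "N") {
  if (!is.numeric(N) || length(N) < 2L || anyNA(N)) {
    stop(sprintf("`%s` must be a numeric vector of length >= 2 without NAs", arg),
         call. = FALSE)
  }
  if (any(N <= 0)) {
    stop(sprintf("`%s` must have strictly positive biomasses", arg), call. = FALSE)
  }
  invisible(N)
}

assert_same_length <- function(a, b, what = "vectors") {
  if (length(a) != length(b)) {
    stop(sprintf("dimension error: %s have lengths %d and %d",
                 what, length(a), length(b)), call. = FALSE)
  }
  invisible(NULL)
}

#' Relative abundances of a community state
#'
#' @param N positive biomass vector.
#' @return Vector `N / sum(N)`, summing to one.
#' @examples
#' relative_abundances(c(9, 1))
#' @export
relative_abundances <- function(N) {
  assert_abundance(N)
  N / sum(N)
}

#' Wilson score interval for a binomial proportion
#'
#' Thin wrapper around [stats::prop.test()] without continuity correction,
#' which yields the Wilson score interval. Used for all mismatch-proportion
#' uncertainty in the package.
#'
#' @param x number of successes (mismatches).
#' @param n number of trials (valid sign pairs).
#' @param level confidence level, default 0.95.
#' @return Named vector with `lower` and `upper`.
#' @examples
#' wilson_interval(3, 12)
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  if (n < 1L || x < 0L || x > n) {
    stop("need 0 <= x <= n with n >= 1", call. = FALSE)
  }
  ci <- suppressWarnings(
    stats::prop.test(x, n, conf.level = level, correct = FALSE)
  )$conf.int
  c(lower = ci[1], upper = ci[2])
}
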