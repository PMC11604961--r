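# Geometric core: responses as projections, collinearity angles, mismatch
# probability, Hill diversity and its gradient, broadness, biomass-scaled
# angles. All angle arithmetic is in radians in [0, pi]; arccos arguments
# are clamped to [-1, 1] against floating-point overshoot.

#' Hill order marker for diversity-metric properties
#'
#' Marks an aggregate property as the Hill diversity of order `q` rather
#' than a linear function, for use in property lists passed to
#' [run_mismatch_experiment()] and the synthetic-data design.
#'
#' @param q Hill order, a single real >= 0. `q = 0` is richness, `q = 1`
#'   the exponential of Shannon entropy, `q = 2` Hill-Simpson.
#' @return An object of class `"hill_order"`.
#' @examples
#' hill_order(2)
#' @export
hill_order <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0) {
    stop("`q` must be a single real >= 0", call. = FALSE)
  }
  structure(list(q = q), class = "hill_order")
}

#' @rdname hill_order
#' @param x object to test.
#' @export
is_hill_order <- function(x) inherits(x, "hill_order")

#' @export
print.hill_order <- function(x, ...) {
  cat(sprintf("<hill_order q = %g>\n", x$q))
  invisible(x)
}

#' Response of a linear function to a perturbation
#'
#' The change in a linear ecosystem function f(N) = f0 + <phi, N> under a
#' displacement is the projection of the displacement onto the direction of
#' per-capita contributions: Delta f = <phi, Delta N>.
#'
#' @param phi nonnegative per-capita contribution vector (at least one
#'   positive entry).
#' @param delta signed per-species biomass displacement, same length.
#' @return Signed scalar response.
#' @examples
#' function_response(c(1, 1), c(2, -1)) # +1
#' function_response(c(0, 1), c(2, -1)) # -1: a mismatch pair
#' @export
function_response <- function(phi, delta) {
  assert_direction(phi)
  if (!is.numeric(delta) || anyNA(delta)) {
    stop("`delta` must be a numeric vector without NAs", call. = FALSE)
  }
  assert_same_length(phi, delta, "contributions and displacement")
  sum(phi * delta)
}

#' Collinearity angle between two contribution directions
#'
#' theta = arccos(<phi, psi> / (||phi|| ||psi||)). For nonnegative
#' directions the dot product is nonnegative, so theta lies in [0, pi/2].
#'
#' @param f,g nonnegative contribution vectors of equal length.
#' @return Angle in radians.
#' @examples
#' angle_between(c(1, 1), c(1, 0)) # pi/4
#' @export
angle_between <- function(f, g) {
  assert_direction(f, "f")
  assert_direction(g, "g")
  assert_same_length(f, g, "directions")
  vec_angle(f, g)
}

#' Mismatch probability from a collinearity angle
#'
#' Under unbiased, isotropic perturbations the probability that two
#' aggregate properties respond with opposite signs is theta / pi.
#'
#' @param theta angle in radians, in [0, pi].
#' @return Probability in [0, 1].
#' @examples
#' mismatch_probability(pi / 4) # 0.25
#' @export
mismatch_probability <- function(theta) {
  if (!is.numeric(theta) || anyNA(theta) || any(theta < 0) || any(theta > pi)) {
    stop("`theta` must lie in [0, pi] radians", call. = FALSE)
  }
  theta / pi
}

# unchecked columnwise Hill diversity on a relative-abundance matrix
# (species x states); used by the vectorized simulator.
hill_cols <- function(P, q) {
  if (q == 0) {
    colSums(P > 0)
  } else if (q == 1) {
    PL <- P * log(P)
    PL[P == 0] <- 0
    exp(-colSums(PL))
  } else {
    colSums(P^q)^(1 / (1 - q))
  }
}

#' Hill diversity (effective number of species)
#'
#' qD(p) = (sum p_i^q)^(1/(1-q)); the q = 1 case is the analytic Shannon
#' limit exp(-sum p_i log p_i) and q = 0 counts nonzero entries.
#'
#' @param p relative abundances: nonnegative, summing to 1 within 1e-9
#'   (renormalized internally; a larger deviation is an error). See
#'   [relative_abundances()] to convert raw biomasses.
#' @param q Hill order, a single real >= 0 (or a [hill_order()] object).
#' @return Effective number of species, between 1 and `length(p)`.
#' @examples
#' hill_diversity(rep(0.25, 4), 2)       # 4: even community
#' hill_diversity(c(0.7, 0.2, 0.1), 2)   # 1 / 0.54
#' @export
hill_diversity <- function(p, q) {
  if (is_hill_order(q)) q <- q$q
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    stop("`p` must be a numeric vector without NAs", call. = FALSE)
  }
  if (any(p < 0)) stop("relative abundances must be nonnegative", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 1e-9) {
    stop("`p` must sum to 1 (within 1e-9); use relative_abundances()",
         call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0) {
    stop("`q` must be a single real >= 0", call. = FALSE)
  }
  drop(hill_cols(matrix(p / s, ncol = 1), q))
}

#' Broadness of an ecosystem function
#'
#' The Hill-Simpson diversity of the normalized contribution vector divided
#' by richness S: broadness = 2D(phi / sum phi) / S. It is scale-invariant,
#' equals 1 iff all species contribute equally (total biomass) and 1/S for
#' a single-species function.
#'
#' @param phi nonnegative contribution vector.
#' @return Broadness in [1/S, 1].
#' @examples
#' broadness(rep(1, 10))      # 1
#' broadness(c(3, 1, 0, 0))   # 0.4
#' @export
broadness <- function(phi) {
  assert_direction(phi)
  # (sum phi)^2 / (S sum phi^2) == (1 / sum phat^2) / S with phat the
  # sum-normalized contributions; this form is exact at the endpoints
  sum(phi)^2 / (length(phi) * sum(phi^2))
}

#' Approximate collinearity cosine from broadness
#'
#' For a random choice of positive functions, cos theta is approximated by
#' sqrt(b_f * b_g) where b is each function's broadness. This is an
#' approximation: it is accurate on average over random positive
#' directions, not an identity for a particular pair.
#'
#' @param b_f,b_g broadness values in (0, 1].
#' @return Approximate cosine in (0, 1].
#' @examples
#' cos_from_broadness(1, 0.25) # 0.5
#' @export
cos_from_broadness <- function(b_f, b_g) {
  for (b in list(b_f, b_g)) {
    if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0 || b > 1) {
      stop("broadness must lie in (0, 1]", call. = FALSE)
    }
  }
  sqrt(b_f * b_g)
}

#' Broadness from the mismatch proportion with total biomass
#'
#' Inverts the mismatch law for the special pair (f, total biomass): when
#' perturbations are random and unbiased, cos(P * pi)^2 estimates the
#' broadness 2D(f)/S of the function. Valid for positive functions, whose
#' angle with total biomass cannot exceed pi/2, hence P <= 0.5.
#'
#' @param P observed mismatch proportion vs total biomass, in [0, 0.5].
#' @return Broadness estimate in [0, 1].
#' @examples
#' broadness_from_mismatch(0)    # 1
#' broadness_from_mismatch(0.25) # 0.5
#' @export
broadness_from_mismatch <- function(P) {
  if (!is.numeric(P) || anyNA(P) || any(P < 0)) {
    stop("`P` must be a proportion in [0, 0.5]", call. = FALSE)
  }
  if (any(P > 0.5)) {
    stop(paste("P > 0.5 is inconsistent with a positive function observed",
               "against total biomass (their angle is at most pi/2);",
               "check the positive-direction assumption"), call. = FALSE)
  }
  cos(P * pi)^2
}

#' Gradient direction of a Hill diversity metric
#'
#' The state-dependent gradient of qD with respect to absolute biomasses,
#' evaluated at N. For q != 1 the entries are proportional to
#' q/(1-q) (p_i^(q-1) - sum_j p_j^q); the q = 1 case uses the analytic
#' Shannon-limit gradient -e^H (log p_i + H) / sum(N). Entries for abundant
#' species can be negative, so the direction is not a positive one; this is
#' what lets function-diversity angles exceed pi/2. Richness (q = 0) has no
#' informative gradient at interior states and is rejected.
#'
#' At the uniform state (q > 0) the gradient vanishes; the zero vector is
#' returned with attribute `degenerate = TRUE` rather than normalized.
#'
#' @param N positive biomass vector.
#' @param q Hill order > 0 (or a [hill_order()] object).
#' @return The gradient vector (same length as `N`), with logical attribute
#'   `degenerate`.
#' @examples
#' g <- diversity_gradient(c(9, 1), 2)
#' sign(g) # negative for the abundant species, positive for the rare one
#' @export
diversity_gradient <- function(N, q) {
  if (is_hill_order(q)) q <- q$q
  assert_abundance(N)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0) {
    stop("`q` must be a single real >= 0", call. = FALSE)
  }
  if (q == 0) {
    stop("unsupported order: richness (q = 0) has no informative gradient",
         call. = FALSE)
  }
  Tn <- sum(N)
  p <- N / Tn
  if (q == 1) {
    H <- -sum(p * log(p))
    g <- -exp(H) * (log(p) + H) / Tn
    scale <- exp(H) / Tn
  } else {
    A <- sum(p^q)
    core <- p^(q - 1) - A
    g <- A^(q / (1 - q)) * (q / ((1 - q) * Tn)) * core
    scale <- A^(q / (1 - q)) * abs(q / ((1 - q))) / Tn
  }
  degenerate <- max(abs(g)) <= 1e-12 * max(scale, 1e-300)
  if (degenerate) g[] <- 0
  structure(g, degenerate = degenerate)
}

#' Biomass-scaled collinearity angle
#'
#' When the displacement takes the form Delta N = Lambda^alpha Delta, with
#' Lambda the diagonal matrix of pre-perturbation biomasses, the angle that
#' predicts mismatches between properties f and g becomes
#' cos theta_alpha = <phi, Lambda^(2 alpha) psi> /
#' (||Lambda^alpha phi|| ||Lambda^alpha psi||). With alpha = 0 or a uniform
#' community it reduces exactly to [angle_between()]. Arguments may be
#' contribution directions or diversity gradients (signed), so the result
#' can exceed pi/2.
#'
#' @param f,g numeric vectors (contribution directions or gradients).
#' @param N positive biomass vector, same length.
#' @param alpha biomass-scaling exponent >= 0.
#' @return Angle in radians in [0, pi].
#' @examples
#' N <- c(4, 1)
#' scaled_angle(c(1, 1), c(1, 2), N, 0) == angle_between(c(1, 1), c(1, 2))
#' @export
scaled_angle <- function(f, g, N, alpha) {
  assert_abundance(N)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("`alpha` must be a single real >= 0", call. = FALSE)
  }
  assert_same_length(f, N, "direction and community")
  assert_same_length(g, N, "direction and community")
  w <- N^alpha
  vec_angle(w * f, w * g)
}

#' Tri-state sign of an observed response
#'
#' Maps a signed response to +1 / -1, with responses within
#' `zero_tolerance` of zero mapped to 0. Pairs containing a 0 are excluded
#' from mismatch tallies throughout the package: a mismatch is defined only
#' over strictly positive/negative pairs, and silently coercing ties would
#' bias proportions.
#'
#' @param response signed numeric (vectorized).
#' @param zero_tolerance nonnegative tolerance, default 0.
#' @return Integer-valued vector in \{-1, 0, +1\} (NAs propagate).
#' @examples
#' observed_sign(c(1e-3, 0, -2))
#' @export
observed_sign <- function(response, zero_tolerance = 0) {
  if (!is.numeric(zero_tolerance) || length(zero_tolerance) != 1L ||
      is.na(zero_tolerance) || zero_tolerance < 0) {
    stop("`zero_tolerance` must be a single nonnegative number", call. = FALSE)
  }
  s <- sign(response)
  s[abs(response) <= zero_tolerance] <- 0
  s
}
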