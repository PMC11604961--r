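# Inverse inference from observed mismatch proportions: function broadness
# with Wilson-interval uncertainty, population-level response consistency
# (bias), and the biomass-scaling exponent, via simulation-built monotone
# calibration curves.

#' Estimate function broadness from mismatches with total biomass
#'
#' Point estimate cos(P * pi)^2 with P the observed mismatch proportion
#' against total biomass (or the designated broadest reference); the
#' confidence interval transforms a 95% Wilson interval for P through the
#' same map. Valid under random, unbiased perturbations and a positive
#' function, in which case P <= 0.5; an observed P > 0.5 is flagged as
#' violating the positive-direction assumption and the estimate is clamped
#' to the orthogonal limit 0.
#'
#' @param n_mismatches mismatch count.
#' @param n_pairs number of valid (nonzero-sign) shared observations; >= 1.
#' @param level confidence level, default 0.95.
#' @param min_pairs caller-set floor below which the estimate is flagged
#'   `low_confidence` (returned, never suppressed), default 10.
#' @return List with `proportion`, `estimate`, `lower`, `upper`, `n_pairs`,
#'   and flags `positive_violation`, `low_confidence`.
#' @examples
#' estimate_broadness(0, 40)   # estimate 1, lower bound < 1
#' estimate_broadness(10, 20)  # estimate 0
#' @export
estimate_broadness <- function(n_mismatches, n_pairs, level = 0.95,
                               min_pairs = 10) {
  if (n_pairs < 1L) {
    stop("insufficient data: no valid shared observations", call. = FALSE)
  }
  P <- n_mismatches / n_pairs
  ci <- wilson_interval(n_mismatches, n_pairs, level)
  # broadness is decreasing in P on [0, 1/2]
  est <- cos(clamp(P, 0, 0.5) * pi)^2
  lower <- cos(clamp(ci["upper"], 0, 0.5) * pi)^2
  upper <- cos(clamp(ci["lower"], 0, 0.5) * pi)^2
  list(proportion = P, estimate = unname(est),
       lower = unname(lower), upper = unname(upper),
       n_pairs = n_pairs,
       positive_violation = P > 0.5,
       low_confidence = n_pairs < min_pairs)
}

#' Relative deviation of an observed mismatch proportion from prediction
#'
#' (predicted - observed) / predicted. Positive values mean mismatches are
#' rarer than the unbiased-perturbation baseline theta/pi: the signature of
#' population-level response consistency.
#'
#' @param observed_P observed mismatch proportion.
#' @param predicted_P baseline prediction theta/pi; must be > 0.
#' @return Signed relative deviation (vectorized).
#' @examples
#' relative_deviation(0, 0.4) # 1: maximal consistency signal
#' @export
relative_deviation <- function(observed_P, predicted_P) {
  if (any(predicted_P <= 0)) {
    stop("undefined baseline: predicted proportion must be > 0", call. = FALSE)
  }
  (predicted_P - observed_P) / predicted_P
}

#' Build a simulation-based calibration curve
#'
#' Maps a perturbation parameter -- the biomass-scaling exponent `alpha` or
#' the response-bias parameter `mu` -- to the mean simulated mismatch
#' signal, for later monotone inversion. For `"alpha"` the signal is the
#' mismatch proportion between total biomass and the Hill metric of order
#' `q` under mu = 0; for `"mu"` it is the mean relative deviation of the
#' observed mismatch proportion from its theta/pi baseline for a pair of
#' random positive functions (alpha = 0). Raw Monte-Carlo means can
#' jitter, so the stored curve is regularized to be nondecreasing with
#' [stats::isoreg()] before inversion.
#'
#' @param parameter `"alpha"` or `"mu"`.
#' @param grid numeric grid of parameter values (nonempty, increasing).
#' @param n_communities replicate communities per grid point.
#' @param n_perturbations perturbations per community.
#' @param richness_range,sd_range community settings.
#' @param q Hill order of the diversity member (alpha curves), default 2.
#' @param contribution_sd lognormal sd of the random function pair (mu
#'   curves), default 1.
#' @param intensity_range per-perturbation intensity interval.
#' @param min_predicted mu curves only: communities whose pair has a
#'   baseline prediction below this are redrawn (the relative deviation is
#'   unstable for near-collinear pairs), default 0.05.
#' @param seed optional integer seed (stored for provenance).
#' @return Object of class `"calibration_curve"`: list with `parameter`,
#'   `grid`, `mean_raw`, `se`, `fitted` (isotonic), `response`
#'   (`"proportion"` or `"deviation"`), `settings`, `seed`.
#' @examples
#' cc <- build_calibration_curve("alpha", c(0, 0.5, 1),
#'   n_communities = 3, n_perturbations = 100,
#'   richness_range = c(30, 30), sd_range = c(1, 1), seed = 1)
#' all(diff(cc$fitted) >= 0)
#' @export
build_calibration_curve <- function(parameter = c("alpha", "mu"), grid,
                                    n_communities = 20,
                                    n_perturbations = 500,
                                    richness_range = c(20, 100),
                                    sd_range = c(0.5, 2), q = 2,
                                    contribution_sd = 1,
                                    intensity_range = c(0, 0.1),
                                    min_predicted = 0.05, seed = NULL) {
  parameter <- match.arg(parameter)
  if (!is.null(seed)) set.seed(seed)
  if (length(grid) < 1L) stop("nonempty grid required", call. = FALSE)
  if (is.unsorted(grid, strictly = FALSE)) grid <- sort(grid)
  if (n_communities < 1L) stop("replicates >= 1 required", call. = FALSE)
  means <- se <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    vals <- numeric(n_communities)
    for (r in seq_len(n_communities)) {
      N <- generate_community(richness_range, sd_range)
      S <- length(N)
      if (parameter == "alpha") {
        ex <- run_mismatch_experiment(
          N, list(biomass = rep(1, S), diversity = hill_order(q)),
          n_perturbations, mu = 0, alpha = grid[gi],
          intensity_range = intensity_range)
        vals[r] <- ex$pairs$proportion[1]
      } else {
        repeat {
          props <- list(f = generate_function(S, contribution_sd),
                        g = generate_function(S, contribution_sd))
          pred <- angle_between(props$f, props$g) / pi
          if (pred >= min_predicted) break
        }
        ex <- run_mismatch_experiment(N, props, n_perturbations,
                                      mu = grid[gi], alpha = 0,
                                      intensity_range = intensity_range)
        vals[r] <- relative_deviation(ex$pairs$proportion[1],
                                      ex$pairs$predicted[1])
      }
    }
    means[gi] <- mean(vals)
    se[gi] <- stats::sd(vals) / sqrt(n_communities)
  }
  fitted <- if (length(grid) > 1L) stats::isoreg(grid, means)$yf else means
  structure(list(parameter = parameter, grid = grid, mean_raw = means,
                 se = se, fitted = fitted,
                 response = if (parameter == "alpha") "proportion" else "deviation",
                 settings = list(n_communities = n_communities,
                                 n_perturbations = n_perturbations,
                                 richness_range = richness_range,
                                 sd_range = sd_range, q = q,
                                 contribution_sd = contribution_sd,
                                 intensity_range = intensity_range),
                 seed = seed),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve: %s -> %s, %d grid points>\n",
              x$parameter, x$response, length(x$grid)))
  print(data.frame(grid = x$grid, mean = x$mean_raw, se = x$se,
                   fitted = x$fitted))
  invisible(x)
}

# Monotone piecewise-linear inversion of the isotonic curve. Values outside
# the fitted range are clamped to the boundary with extrapolated = TRUE.
invert_calibration <- function(curve, value) {
  stopifnot(inherits(curve, "calibration_curve"))
  f <- curve$fitted
  g <- curve$grid
  if (length(g) == 1L) {
    return(list(estimate = g, extrapolated = value != f))
  }
  if (value <= f[1]) {
    return(list(estimate = g[1], extrapolated = value < f[1]))
  }
  if (value >= f[length(f)]) {
    return(list(estimate = g[length(g)], extrapolated = value > f[length(f)]))
  }
  est <- stats::approx(f, g, xout = value, ties = mean)$y
  list(estimate = est, extrapolated = FALSE)
}

#' Estimate population-level response consistency (bias) of a perturbation
#'
#' Computes the relative deviation of the observed mismatch proportion from
#' its theta/pi baseline and inverts a `"mu"` calibration curve at that
#' deviation. Returns the bias parameter estimate `mu_hat`, its Eq-(5)
#' scale counterpart `bias_hat` = |1/2 - Phi(-mu_hat)| (the expected
#' absolute deviation of the negative-response fraction from one half),
#' and flags. Deviations outside the curve's fitted range return the
#' boundary with `extrapolated = TRUE`. The assumption-free *relative*
#' ranking of perturbation classes (lower mismatch proportion at a fixed
#' pair implies lower response diversity) is provided by
#' [rank_classes()] / [perturbation_report()].
#'
#' @param n_mismatches,n_pairs mismatch tally for the pair under this
#'   perturbation class.
#' @param theta baseline collinearity angle of the pair (radians). When the
#'   true contributions are unknown, approximate it from broadness via
#'   `acos(cos_from_broadness(b_f, b_g))`.
#' @param curve a `"mu"` [build_calibration_curve()] object.
#' @return List with `proportion`, `predicted`, `deviation`, `mu_hat`,
#'   `bias_hat`, `extrapolated`, `n_pairs`.
#' @export
estimate_response_consistency <- function(n_mismatches, n_pairs, theta,
                                          curve) {
  if (missing(theta) || is.null(theta)) {
    stop("configuration error: a baseline angle `theta` is required",
         call. = FALSE)
  }
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$parameter != "mu") {
    stop("`curve` must be a 'mu' calibration curve", call. = FALSE)
  }
  if (n_pairs < 1L) stop("insufficient data: n_pairs >= 1", call. = FALSE)
  predicted <- mismatch_probability(theta)
  P <- n_mismatches / n_pairs
  dev <- relative_deviation(P, predicted)
  inv <- invert_calibration(curve, dev)
  list(proportion = P, predicted = predicted, deviation = dev,
       mu_hat = inv$estimate,
       bias_hat = abs(0.5 - stats::pnorm(-inv$estimate)),
       extrapolated = inv$extrapolated, n_pairs = n_pairs)
}

#' Estimate the biomass-scaling exponent of a perturbation class
#'
#' Inverts an `"alpha"` calibration curve (mismatch proportion between a
#' linear function and a diversity metric as a function of alpha) at the
#' observed proportion. Observed proportions outside the fitted range are
#' clamped to the grid boundary with `extrapolated = TRUE`.
#'
#' @param n_mismatches,n_pairs mismatch tally between the function and the
#'   diversity metric for this class.
#' @param curve an `"alpha"` [build_calibration_curve()] object.
#' @return List with `proportion`, `alpha_hat`, `extrapolated`, `n_pairs`.
#' @export
estimate_biomass_scaling <- function(n_mismatches, n_pairs, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$parameter != "alpha") {
    stop("`curve` must be an 'alpha' calibration curve", call. = FALSE)
  }
  if (n_pairs < 1L) stop("insufficient data: n_pairs >= 1", call. = FALSE)
  P <- n_mismatches / n_pairs
  inv <- invert_calibration(curve, P)
  list(proportion = P, alpha_hat = inv$estimate,
       extrapolated = inv$extrapolated, n_pairs = n_pairs)
}

#' Rank perturbation classes by mismatch proportion
#'
#' The package's assumption-free empirical summary: for a fixed property
#' pair, classes with a lower mismatch proportion have lower response
#' diversity (function pairs) or weaker biomass scaling (function vs
#' diversity pairs). Rankings are invariant to any monotone recalibration
#' of the curves.
#'
#' @param classes data.frame with columns `n_mismatches` and `n_pairs`
#'   (plus any id columns, carried through).
#' @return The input with `proportion` and `rank` columns (rank 1 = lowest
#'   proportion; ties share the average rank).
#' @export
rank_classes <- function(classes) {
  stopifnot(is.data.frame(classes),
            all(c("n_mismatches", "n_pairs") %in% names(classes)))
  classes$proportion <- classes$n_mismatches / classes$n_pairs
  classes$rank <- rank(classes$proportion)
  classes
}

#' Serialize / restore a calibration curve as JSON
#'
#' Full-precision JSON so a stored curve round-trips exactly, with the
#' simulator settings and seed kept as provenance.
#'
#' @param curve a [build_calibration_curve()] object.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the restored `"calibration_curve"`.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$seed <- if (is.null(obj$seed)) NULL else as.integer(obj$seed)
  structure(obj, class = "calibration_curve")
}
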