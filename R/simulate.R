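# In-silico perturbation-experiment engine: lognormal communities,
# biased / biomass-scaled displacement vectors, random positive functions,
# and mismatch tallies between aggregate properties.

#' Generate a lognormal community state
#'
#' Richness S is drawn uniformly from `richness_range` and biomasses are
#' exp of independent Normal(0, sd) draws with a per-community sd drawn
#' uniformly from `sd_range` ("zero mean" refers to the underlying normal,
#' the standard lognormal parameterization).
#'
#' @param richness_range integer interval, default c(20, 100).
#' @param sd_range interval for the lognormal sd, default c(0.5, 2).
#' @param seed optional integer seed for reproducibility.
#' @return Positive biomass vector with attributes `sd_log` (realized sd).
#' @examples
#' N <- generate_community(seed = 1)
#' length(N) >= 20
#' @export
generate_community <- function(richness_range = c(20, 100),
                               sd_range = c(0.5, 2),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(richness_range) != 2L || any(richness_range < 2) ||
      richness_range[1] > richness_range[2]) {
    stop("`richness_range` must be an interval with lower bound >= 2",
         call. = FALSE)
  }
  if (length(sd_range) != 2L || any(sd_range < 0) ||
      sd_range[1] > sd_range[2]) {
    stop("`sd_range` must be a nonnegative interval", call. = FALSE)
  }
  S <- if (richness_range[1] == richness_range[2]) {
    as.integer(richness_range[1])
  } else {
    sample(seq.int(richness_range[1], richness_range[2]), 1L)
  }
  sd_log <- stats::runif(1, sd_range[1], sd_range[2])
  N <- exp(stats::rnorm(S, 0, sd_log))
  structure(N, sd_log = sd_log)
}

#' Generate one perturbation displacement vector
#'
#' Draws x_i ~ Normal(mu, 1) independently, normalizes by the root mean
#' square, y_i = x_i / sqrt(mean(x^2)), and sets
#' Delta N_i = intensity * y_i * N_i^alpha. `mu` controls the consistency
#' of population-level responses (the expected fraction of negative
#' responses is Phi(-mu)); `alpha` scales absolute responses by biomass.
#'
#' @param N positive biomass vector.
#' @param mu population-response bias parameter, default 0.
#' @param alpha biomass-scaling exponent >= 0, default 0.
#' @param intensity perturbation intensity >= 0; if `NULL`, drawn uniformly
#'   from `intensity_range`.
#' @param intensity_range interval for the intensity draw, default c(0, 0.1).
#' @param seed optional integer seed.
#' @return Signed displacement vector (unclipped), with attributes
#'   `intensity` and `alpha`.
#' @examples
#' N <- generate_community(c(30, 30), c(1, 1), seed = 1)
#' d <- generate_perturbation(N, mu = 0, alpha = 0, intensity = 0.05)
#' @export
generate_perturbation <- function(N, mu = 0, alpha = 0, intensity = NULL,
                                  intensity_range = c(0, 0.1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_abundance(N)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (is.null(intensity)) {
    intensity <- stats::runif(1, intensity_range[1], intensity_range[2])
  }
  if (intensity < 0) stop("`intensity` must be >= 0", call. = FALSE)
  S <- length(N)
  x <- stats::rnorm(S, mean = mu)
  y <- x / sqrt(mean(x^2))
  structure(intensity * y * N^alpha, intensity = intensity, alpha = alpha)
}

#' Perturbed community state, clipped at zero
#'
#' Adds a displacement to a community state and clips negative biomasses at
#' zero, counting how many entries were clipped (attribute `n_clipped`).
#' Projections of linear functions use the unclipped displacement; only
#' evaluations of the perturbed state (e.g. diversity) use the clip.
#'
#' @param N positive biomass vector.
#' @param delta displacement, same length.
#' @return Nonnegative perturbed state with attribute `n_clipped`.
#' @export
perturbed_state <- function(N, delta) {
  assert_abundance(N)
  assert_same_length(N, delta, "community and displacement")
  raw <- N + delta
  structure(pmax(raw, 0), n_clipped = sum(raw < 0))
}

#' Population-level response bias of a displacement
#'
#' bias = |1/2 - #\{i : Delta N_i < 0\} / S|: the absolute deviation of the
#' negative-response fraction from one half. 0 means perfectly balanced
#' (high response diversity); 0.5 means all species respond in the same
#' direction.
#'
#' @param delta signed displacement vector.
#' @return Bias in [0, 0.5].
#' @examples
#' response_bias(c(-1, -1, -1, 1)) # 0.25
#' @export
response_bias <- function(delta) {
  if (!is.numeric(delta) || length(delta) < 1L || anyNA(delta)) {
    stop("`delta` must be a nonempty numeric vector", call. = FALSE)
  }
  abs(0.5 - mean(delta < 0))
}

#' Expected fraction of negative population responses
#'
#' With x_i ~ Normal(mu, 1) and positive intensity, the expected fraction
#' of species responding negatively is Phi(-mu), the standard normal CDF
#' at -mu.
#'
#' @param mu bias parameter (vectorized).
#' @return Probability.
#' @examples
#' expected_negative_fraction(0) # 0.5
#' @export
expected_negative_fraction <- function(mu) stats::pnorm(-mu)

#' Generate a random positive function (contribution direction)
#'
#' Per-capita contributions are exp of Normal(0, contribution_sd) draws.
#' sd = 0 yields total biomass (all contributions equal, broadness 1);
#' larger sd yields narrower functions.
#'
#' @param S number of species.
#' @param contribution_sd lognormal sd >= 0; if `NULL`, drawn uniformly
#'   from `sd_range`.
#' @param sd_range interval for the sd draw, default c(0, 1.3).
#' @param seed optional integer seed.
#' @return Positive contribution vector with attribute `contribution_sd`.
#' @examples
#' broadness(generate_function(50, 0)) # 1
#' @export
generate_function <- function(S, contribution_sd = NULL, sd_range = c(0, 1.3),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(contribution_sd)) {
    contribution_sd <- stats::runif(1, sd_range[1], sd_range[2])
  }
  if (contribution_sd < 0) stop("`contribution_sd` must be >= 0", call. = FALSE)
  structure(exp(stats::rnorm(S, 0, contribution_sd)),
            contribution_sd = contribution_sd)
}

# Vectorized displacement generator: S x n matrix of Delta N.
# mu scalar; alpha and intensity scalars or length-n vectors.
simulate_displacements <- function(N, n, mu, alpha, intensity) {
  S <- length(N)
  X <- matrix(stats::rnorm(S * n, mean = mu), S, n)
  Y <- X / rep(sqrt(colMeans(X^2)), each = S)
  if (length(alpha) == 1L) {
    W <- N^alpha
    D <- Y * W
  } else {
    D <- Y * exp(outer(log(N), alpha))
  }
  iv <- rep(intensity, length.out = n)
  D * rep(iv, each = S)
}

# Responses of a list of properties (directions / hill_order) to a block
# of displacements. Returns n x P matrix. Linear responses use the exact
# projection on the unclipped displacement; diversity responses are exact
# before/after differences of Hill diversity on the clipped state.
property_responses <- function(N, D, properties) {
  S <- length(N)
  n <- ncol(D)
  clipped <- NULL
  out <- matrix(NA_real_, n, length(properties))
  colnames(out) <- names(properties)
  for (k in seq_along(properties)) {
    pr <- properties[[k]]
    if (is_hill_order(pr)) {
      if (is.null(clipped)) {
        clipped <- pmax(N + D, 0)
        tot <- colSums(clipped)
        Pm <- clipped / rep(tot, each = S)
      }
      base <- drop(hill_cols(matrix(N / sum(N), ncol = 1), pr$q))
      out[, k] <- hill_cols(Pm, pr$q) - base
    } else {
      out[, k] <- colSums(pr * D)
    }
  }
  out
}

# number of entries clipped across a displacement block
count_clipped <- function(N, D) sum(N + D < 0)

#' Run an in-silico mismatch experiment on one community
#'
#' Applies `n_perturbations` displacement vectors to the community and
#' records, for every unordered pair of aggregate properties, the
#' proportion of perturbations with opposite nonzero response signs.
#' Linear-function responses are exact projections of the (unclipped)
#' displacement; diversity responses are exact before/after differences of
#' Hill diversity on the zero-clipped perturbed state. The predicted
#' mismatch proportion theta/pi accompanies each pair (using the gradient
#' direction at N for diversity metrics; NA when a richness metric is
#' involved).
#'
#' @param N positive biomass vector.
#' @param properties named list of contribution vectors and/or
#'   [hill_order()] metrics; at least 2.
#' @param n_perturbations number of perturbations, default 500.
#' @param mu bias parameter; if `NULL`, drawn once uniformly from
#'   \[-0.3, 0.3\] for the community (the simulation protocol default).
#' @param alpha scaling exponent; a scalar, or `NULL` to draw one per
#'   perturbation uniformly from \[0, 1\].
#' @param intensity_range interval for per-perturbation intensity draws,
#'   default c(0, 0.1).
#' @param zero_tolerance tolerance for [observed_sign()], default 0.
#' @param seed optional integer seed.
#' @return Object of class `"mismatch_experiment"`: list with
#'   `pairs` (data.frame: property_a, property_b, n_pairs, n_mismatches,
#'   proportion, theta, predicted), `records` (per-perturbation intensity,
#'   alpha, bias), `responses` (n x P matrix), `mu`, `n_clipped`.
#' @examples
#' N <- generate_community(c(40, 40), c(1, 1), seed = 1)
#' ex <- run_mismatch_experiment(N,
#'   list(biomass = rep(1, 40), f = generate_function(40, 1)),
#'   n_perturbations = 200, mu = 0, alpha = 0, seed = 2)
#' ex$pairs
#' @export
run_mismatch_experiment <- function(N, properties, n_perturbations = 500,
                                    mu = NULL, alpha = NULL,
                                    intensity_range = c(0, 0.1),
                                    zero_tolerance = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_abundance(N)
  if (!is.list(properties) || length(properties) < 2L) {
    stop("need at least 2 properties", call. = FALSE)
  }
  if (n_perturbations < 1L) {
    stop("config error: need at least 1 perturbation", call. = FALSE)
  }
  if (is.null(names(properties)) || any(names(properties) == "")) {
    names(properties) <- paste0("p", seq_along(properties))
  }
  if (is.null(mu)) mu <- stats::runif(1, -0.3, 0.3)
  alpha_vec <- if (is.null(alpha)) {
    stats::runif(n_perturbations, 0, 1)
  } else {
    rep(alpha, length.out = 1L)
  }
  intensity <- stats::runif(n_perturbations,
                            intensity_range[1], intensity_range[2])
  D <- simulate_displacements(N, n_perturbations, mu, alpha_vec, intensity)
  resp <- property_responses(N, D, properties)
  sgn <- observed_sign(resp, zero_tolerance)
  bias <- abs(0.5 - colMeans(D < 0))

  idx <- utils::combn(length(properties), 2)
  pairs <- data.frame(
    property_a = names(properties)[idx[1, ]],
    property_b = names(properties)[idx[2, ]],
    n_pairs = NA_integer_, n_mismatches = NA_integer_,
    proportion = NA_real_, theta = NA_real_, predicted = NA_real_,
    stringsAsFactors = FALSE
  )
  grads <- lapply(properties, function(pr) {
    if (is_hill_order(pr)) {
      if (pr$q == 0) NULL else diversity_gradient(N, pr$q)
    } else pr
  })
  for (r in seq_len(ncol(idx))) {
    i <- idx[1, r]; j <- idx[2, r]
    ok <- sgn[, i] != 0 & sgn[, j] != 0
    pairs$n_pairs[r] <- sum(ok)
    pairs$n_mismatches[r] <- sum(sgn[ok, i] * sgn[ok, j] < 0)
    pairs$proportion[r] <- if (pairs$n_pairs[r] > 0) {
      pairs$n_mismatches[r] / pairs$n_pairs[r]
    } else NA_real_
    gi <- grads[[i]]; gj <- grads[[j]]
    if (!is.null(gi) && !is.null(gj) &&
        !isTRUE(attr(gi, "degenerate")) && !isTRUE(attr(gj, "degenerate"))) {
      pairs$theta[r] <- vec_angle(gi, gj)
      pairs$predicted[r] <- pairs$theta[r] / pi
    }
  }
  structure(list(
    pairs = pairs,
    records = data.frame(perturbation = seq_len(n_perturbations),
                         intensity = intensity,
                         alpha = rep(alpha_vec, length.out = n_perturbations),
                         bias = bias),
    responses = resp,
    mu = mu,
    n_clipped = count_clipped(N, D)
  ), class = "mismatch_experiment")
}

#' @export
print.mismatch_experiment <- function(x, ...) {
  cat(sprintf("<mismatch_experiment: %d perturbations, %d properties, mu = %.3f>\n",
              nrow(x$records), ncol(x$responses), x$mu))
  print(x$pairs)
  invisible(x)
}

#' Sweep the simulation protocol over a parameter grid
#'
#' For each grid cell and replicate community, simulates a perturbation
#' experiment and records the predicted (theta/pi) and realized mismatch
#' proportion plus the realized mean response bias. Two pair modes:
#' `"random"` draws two random positive functions per community (at the
#' cell's `contribution_sd` when that column is present), `"biomass_diversity"`
#' observes total biomass against the Hill metric of order `q`.
#'
#' @param grid data.frame with any of the columns `mu`, `alpha`,
#'   `contribution_sd`; one row per cell. An empty grid returns an empty
#'   result.
#' @param replicates replicate communities per cell.
#' @param n_perturbations perturbations per community.
#' @param pair `"random"` or `"biomass_diversity"`.
#' @param q Hill order for the diversity member, default 2.
#' @param richness_range,sd_range community settings, see
#'   [generate_community()].
#' @param intensity_range per-perturbation intensity interval.
#' @param seed optional integer seed.
#' @return Tidy data.frame: one row per (cell, replicate) with columns
#'   mu, alpha, contribution_sd, replicate, theta, predicted, observed,
#'   n_pairs, mean_bias.
#' @export
mismatch_sweep <- function(grid, replicates = 10, n_perturbations = 500,
                           pair = c("random", "biomass_diversity"), q = 2,
                           richness_range = c(20, 100), sd_range = c(0.5, 2),
                           intensity_range = c(0, 0.1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pair <- match.arg(pair)
  cols <- c("mu", "alpha", "contribution_sd", "replicate", "theta",
            "predicted", "observed", "n_pairs", "mean_bias")
  empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  if (nrow(grid) == 0L) return(empty)
  out <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (cell in seq_len(nrow(grid))) {
    mu <- if ("mu" %in% names(grid)) grid$mu[cell] else 0
    alpha <- if ("alpha" %in% names(grid)) grid$alpha[cell] else 0
    csd <- if ("contribution_sd" %in% names(grid)) {
      grid$contribution_sd[cell]
    } else NA_real_
    for (rep_i in seq_len(replicates)) {
      N <- generate_community(richness_range, sd_range)
      S <- length(N)
      props <- if (pair == "random") {
        list(f = generate_function(S, if (is.na(csd)) NULL else csd),
             g = generate_function(S, if (is.na(csd)) NULL else csd))
      } else {
        list(biomass = rep(1, S), diversity = hill_order(q))
      }
      ex <- run_mismatch_experiment(N, props, n_perturbations, mu = mu,
                                    alpha = alpha,
                                    intensity_range = intensity_range)
      k <- k + 1L
      out[[k]] <- data.frame(
        mu = mu, alpha = alpha, contribution_sd = csd, replicate = rep_i,
        theta = ex$pairs$theta[1], predicted = ex$pairs$predicted[1],
        observed = ex$pairs$proportion[1], n_pairs = ex$pairs$n_pairs[1],
        mean_bias = mean(ex$records$bias))
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Write a sweep results table as CSV with a provenance header
#'
#' Writes the tidy results of [mismatch_sweep()] (or any experiment table)
#' as CSV, preceded by a `#`-prefixed comment line echoing the experiment
#' configuration as JSON so the file carries its own provenance. Read back
#' with `read.csv(path, comment.char = "#")`.
#'
#' @param results data.frame of results.
#' @param path file path.
#' @param config named list describing the run (grid, replicates, seed...).
#' @return Invisibly, `path`.
#' @export
write_sweep <- function(results, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config: %s",
                     jsonlite::toJSON(config, auto_unbox = TRUE,
                                      null = "null")), con)
  utils::write.csv(results, con, row.names = FALSE)
  invisible(path)
}
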