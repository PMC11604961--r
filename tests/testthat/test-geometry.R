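test_that("function responses are projections of the displacement", {
  expect_equal(function_response(c(1, 1), c(0, 0)), 0)
  # a mismatch pair: same displacement, opposite observed signs
  expect_equal(function_response(c(1, 1), c(2, -1)), 1)
  expect_equal(function_response(c(0, 1), c(2, -1)), -1)
  # brute-force summation oracle at length 30
  set.seed(11)
  phi <- rexp(30)
  dn <- rnorm(30)
  acc <- 0
  for (i in 1:30) acc <- acc + phi[i] * dn[i]
  expect_equal(function_response(phi, dn), acc)
  expect_error(function_response(c(1, 1), c(1, 2, 3)), "dimension")
})

test_that("collinearity angles are clamped arccosines in [0, pi/2]", {
  v <- rexp(20) + 0.1
  expect_equal(angle_between(v, v), 0)
  expect_equal(angle_between(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(angle_between(c(1, 1), c(1, 0)), pi / 4)
  expect_error(angle_between(c(0, 0), c(1, 0)), "degenerate")
  expect_error(angle_between(c(1, -1), c(1, 0)), "nonnegative")
  # invariant to positive rescaling of either argument
  set.seed(3)
  for (i in 1:20) {
    f <- rexp(15); g <- rexp(15)
    expect_equal(angle_between(7.3 * f, g), angle_between(f, 0.01 * g))
  }
})

test_that("mismatch probability is theta / pi on [0, pi]", {
  expect_equal(mismatch_probability(0), 0)
  expect_equal(mismatch_probability(pi / 2), 0.5)
  expect_equal(mismatch_probability(pi / 4), 0.25)
  expect_error(mismatch_probability(-0.1), "\\[0, pi\\]")
  expect_error(mismatch_probability(3.2), "\\[0, pi\\]")
})

test_that("Hill diversity matches closed forms and the Shannon limit", {
  expect_equal(hill_diversity(rep(0.25, 4), 2), 4)
  expect_equal(hill_diversity(c(0.5, 0.5, 0, 0), 0), 2)
  expect_equal(hill_diversity(c(0.7, 0.2, 0.1), 2), 1 / 0.54)
  # q = 1 is the exponential of Shannon entropy with 0 log 0 = 0
  p <- c(0.6, 0.4, 0)
  expect_equal(hill_diversity(p, 1), exp(-sum(p[1:2] * log(p[1:2]))))
  # uniform community has qD = S for every q
  for (q in c(0, 0.5, 1, 2, 3)) {
    expect_equal(hill_diversity(rep(1 / 7, 7), q), 7, tolerance = 1e-9)
  }
  expect_error(hill_diversity(c(-0.1, 1.1), 2), "nonnegative")
  expect_error(hill_diversity(c(0.3, 0.3), 2), "sum to 1")
})

test_that("broadness is scale-invariant Hill-Simpson evenness in [1/S, 1]", {
  expect_equal(broadness(rep(2.7, 12)), 1)
  expect_equal(broadness(c(5, 0, 0, 0)), 1 / 4)
  expect_equal(broadness(c(3, 1, 0, 0)), 0.4)
  set.seed(5)
  for (i in 1:25) {
    phi <- rexp(40)
    b <- broadness(phi)
    expect_gte(b, 1 / 40)
    expect_lte(b, 1)
    expect_equal(broadness(phi * 13.7), b)
  }
})

test_that("broadness-based cosine approximates the true angle for random positive functions", {
  expect_equal(cos_from_broadness(1, 1), 1)
  expect_equal(cos_from_broadness(1, 0.36), 0.6)
  expect_error(cos_from_broadness(0, 0.5), "broadness")
  expect_error(cos_from_broadness(0.5, 1.2), "broadness")
  set.seed(8)
  S <- 100
  true_theta <- approx_theta <- numeric(200)
  for (i in 1:200) {
    f <- generate_function(S, runif(1, 0.2, 1.3))
    g <- generate_function(S, runif(1, 0.2, 1.3))
    true_theta[i] <- angle_between(f, g)
    approx_theta[i] <- acos(cos_from_broadness(broadness(f), broadness(g)))
  }
  expect_gt(cor(true_theta, approx_theta), 0.9)
})

test_that("broadness_from_mismatch inverts the biomass-pair law on [0, 0.5]", {
  expect_equal(broadness_from_mismatch(0), 1)
  expect_equal(broadness_from_mismatch(0.5), 0, tolerance = 1e-12)
  expect_error(broadness_from_mismatch(0.6), "positive")
  # self-consistency: angle with total biomass -> P -> recovered broadness
  # tracks true broadness for random positive functions
  set.seed(9)
  S <- 80
  err <- replicate(200, {
    phi <- generate_function(S, runif(1, 0.2, 1.3))
    P <- mismatch_probability(angle_between(phi, rep(1, S)))
    broadness_from_mismatch(P) - broadness(phi)
  })
  expect_lt(mean(abs(err)), 0.05)
})

test_that("diversity gradients match finite differences up to a positive scalar", {
  fd_gradient <- function(N, q) {
    vapply(seq_along(N), function(i) {
      h <- 1e-6 * N[i]
      up <- N; up[i] <- up[i] + h
      dn <- N; dn[i] <- dn[i] - h
      (hill_diversity(up / sum(up), q) - hill_diversity(dn / sum(dn), q)) /
        (2 * h)
    }, numeric(1))
  }
  set.seed(12)
  for (rep_i in 1:100) {
    N <- exp(rnorm(sample(5:30, 1), 0, 1))
    for (q in c(0.5, 2, 3)) {
      g <- diversity_gradient(N, q)
      fd <- fd_gradient(N, q)
      cosine <- sum(g * fd) / sqrt(sum(g^2) * sum(fd^2))
      expect_gt(cosine, 1 - 1e-6)
    }
  }
  # q = 1 analytic Shannon-limit gradient obeys the same collinearity
  set.seed(13)
  for (rep_i in 1:20) {
    N <- exp(rnorm(12, 0, 1))
    g <- diversity_gradient(N, 1)
    fd <- fd_gradient(N, 1)
    expect_gt(sum(g * fd) / sqrt(sum(g^2) * sum(fd^2)), 1 - 1e-6)
  }
})

test_that("gradient signs and degeneracy follow abundance structure", {
  g <- diversity_gradient(c(9, 1), 2)
  # direct evaluation: entries proportional to -(p_i - sum p^2)
  expect_equal(g / max(abs(g)), -0.82^-2 * 0.2 * (c(0.9, 0.1) - 0.82) /
                 max(abs(0.82^-2 * 0.2 * (c(0.9, 0.1) - 0.82))),
               ignore_attr = TRUE)
  expect_gt(g[2], 0) # rare species raises diversity
  expect_lt(g[1], 0) # abundant species lowers it
  gu <- diversity_gradient(rep(3, 6), 2)
  expect_true(attr(gu, "degenerate"))
  expect_equal(max(abs(gu)), 0)
  expect_error(diversity_gradient(c(1, 2), 0), "unsupported")
})

test_that("biomass-scaled angles reduce to plain angles and can exceed pi/2", {
  set.seed(14)
  N <- exp(rnorm(30, 0, 1.2))
  f <- rexp(30); g <- rexp(30)
  expect_equal(scaled_angle(f, g, N, 0), angle_between(f, g))
  expect_equal(scaled_angle(f, g, rep(2, 30), 1.7), angle_between(f, g))
  # total biomass vs Hill-Simpson gradient at alpha = 1: predicted
  # mismatch proportion exceeds 1/2 on a lognormal community
  grad <- diversity_gradient(N, 2)
  th <- scaled_angle(rep(1, 30), grad, N, 1)
  expect_gt(th, pi / 2)
  expect_gt(mismatch_probability(th), 0.5)
  expect_error(scaled_angle(rep(0, 30), g, N, 1), "degenerate")
})

test_that("observed signs are tri-state with a zero tolerance", {
  expect_identical(observed_sign(1e-3), 1)
  expect_identical(observed_sign(0), 0)
  expect_identical(observed_sign(-1e-9, zero_tolerance = 1e-8), 0)
  expect_equal(observed_sign(c(2, -3, 0, 1e-4), 1e-3), c(1, -1, 0, 0))
  expect_error(observed_sign(1, zero_tolerance = -1), "nonnegative")
})
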