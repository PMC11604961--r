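test_that("community generation follows the lognormal protocol", {
  N <- generate_community(c(30, 30), c(0, 0), seed = 1)
  expect_equal(unclass(N), rep(1, 30), ignore_attr = TRUE)
  expect_identical(generate_community(seed = 7), generate_community(seed = 7))
  # distributional oracle: pooled log-biomass sd at sd = 1
  set.seed(2)
  logs <- unlist(replicate(1000, log(generate_community(c(20, 20), c(1, 1))),
                           simplify = FALSE))
  expect_gt(sd(logs), 0.95)
  expect_lt(sd(logs), 1.05)
  expect_error(generate_community(c(1, 5)), "richness_range")
})

test_that("perturbations follow the normalized biased-displacement protocol", {
  N <- generate_community(c(40, 40), c(1, 1), seed = 3)
  expect_equal(generate_perturbation(N, intensity = 0), rep(0, 40),
               ignore_attr = TRUE)
  # normalization: (1/S) sum y_i^2 = 1 exactly
  for (alpha in c(0, 0.5, 1)) {
    d <- generate_perturbation(N, mu = 0.2, alpha = alpha, intensity = 0.07)
    y <- d / (0.07 * N^alpha)
    expect_equal(mean(y^2), 1, tolerance = 1e-12)
  }
  # unbiased, unscaled perturbations have ~half the entries negative
  set.seed(4)
  fr <- replicate(2000, mean(generate_perturbation(N, 0, 0, 0.05) < 0))
  expect_lt(abs(mean(fr) - 0.5), 0.01)
  # alpha = 1: relative responses |dN_i| / N_i are exchangeable across
  # species (Kolmogorov-Smirnov on the two most different biomasses)
  set.seed(5)
  rel <- replicate(400, {
    d <- generate_perturbation(N, 0, 1, 0.05)
    abs(d) / N
  })
  i_lo <- which.min(N); i_hi <- which.max(N)
  ks <- suppressWarnings(ks.test(rel[i_lo, ], rel[i_hi, ]))
  expect_gt(ks$p.value, 0.01)
})

test_that("perturbed states are clipped at zero with a count", {
  N <- c(1, 0.01, 2)
  st <- perturbed_state(N, c(-0.5, -0.5, 0.1))
  expect_equal(unclass(st), c(0.5, 0, 2.1), ignore_attr = TRUE)
  expect_identical(attr(st, "n_clipped"), 1L)
})

test_that("response bias counts the negative fraction deviation", {
  expect_equal(response_bias(c(-1, -1, 1, 1)), 0)
  expect_equal(response_bias(c(-1, -2, -3)), 0.5)
  expect_equal(response_bias(c(-1, -1, -1, 1)), 0.25)
})

test_that("expected negative fraction is the normal CDF at -mu", {
  expect_equal(expected_negative_fraction(0), 0.5)
  expect_lt(expected_negative_fraction(50), 1e-10)
  set.seed(6)
  emp <- mean(rnorm(1e5, mean = 0.3) < 0)
  expect_lt(abs(emp - expected_negative_fraction(0.3)), 0.005)
})

test_that("random functions get narrower as the contribution sd grows", {
  expect_equal(broadness(generate_function(50, 0)), 1)
  expect_identical(generate_function(30, 1, seed = 9),
                   generate_function(30, 1, seed = 9))
  set.seed(10)
  b_narrow <- replicate(500, broadness(generate_function(100, 1.3)))
  b_broad <- replicate(500, broadness(generate_function(100, 0.3)))
  expect_lt(mean(b_narrow), mean(b_broad))
})

test_that("mismatch experiments tally opposite-sign responses per pair", {
  N <- generate_community(c(30, 30), c(1, 1), seed = 11)
  phi <- generate_function(30, 1, seed = 12)
  ex <- run_mismatch_experiment(N, list(a = phi, b = phi),
                                n_perturbations = 300, mu = 0, alpha = 0,
                                seed = 13)
  expect_equal(ex$pairs$proportion, 0)
  expect_equal(ex$pairs$theta, 0)
  expect_error(run_mismatch_experiment(N, list(a = phi, b = phi),
                                       n_perturbations = 0),
               "config error")
  expect_error(run_mismatch_experiment(N, list(a = phi)), "2 properties")
  # biased perturbations suppress mismatches below theta / pi
  set.seed(14)
  diffs <- replicate(15, {
    Nc <- generate_community(c(30, 60), c(0.5, 2))
    S <- length(Nc)
    f <- generate_function(S, 1); g <- generate_function(S, 1)
    exb <- run_mismatch_experiment(Nc, list(f = f, g = g), 400,
                                   mu = 0.3, alpha = 0)
    exb$pairs$predicted[1] - exb$pairs$proportion[1]
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("experiment records expose realized bias, alpha and intensity", {
  N <- generate_community(c(25, 25), c(1, 1), seed = 15)
  ex <- run_mismatch_experiment(N, list(bio = rep(1, 25), d = hill_order(2)),
                                n_perturbations = 200, mu = NULL,
                                alpha = NULL, seed = 16)
  expect_true(all(ex$records$bias >= 0 & ex$records$bias <= 0.5))
  expect_true(all(ex$records$alpha >= 0 & ex$records$alpha <= 1))
  expect_true(all(ex$records$intensity >= 0 & ex$records$intensity <= 0.1))
  expect_gte(ex$mu, -0.3); expect_lte(ex$mu, 0.3)
  # realized mean bias at fixed mu matches |1/2 - Phi(-mu)| within MC error
  ex2 <- run_mismatch_experiment(N, list(bio = rep(1, 25), d = hill_order(2)),
                                 n_perturbations = 2000, mu = 0.25,
                                 alpha = 0, seed = 17)
  expect_lt(abs(mean(ex2$records$bias) - abs(0.5 - pnorm(-0.25))), 0.03)
})

test_that("sweeps are tidy, deterministic and reproduce the 1:1 law", {
  expect_equal(nrow(mismatch_sweep(data.frame(mu = numeric(0)))), 0)
  grid <- data.frame(mu = 0, alpha = 0)
  s1 <- mismatch_sweep(grid, replicates = 3, n_perturbations = 100, seed = 18)
  s2 <- mismatch_sweep(grid, replicates = 3, n_perturbations = 100, seed = 18)
  expect_identical(s1, s2)
  # unbiased isotropic cell: realized proportions regress on theta/pi with
  # slope and intercept consistent with (1, 0)
  sw <- mismatch_sweep(grid, replicates = 40, n_perturbations = 500,
                       seed = 19)
  fit <- lm(observed ~ predicted, data = sw)
  ci <- confint(fit)
  expect_lt(ci["predicted", 1], 1)
  expect_gt(ci["predicted", 2], 1)
  expect_lt(ci["(Intercept)", 1], 0)
  expect_gt(ci["(Intercept)", 2], 0)
  # biomass scaling raises biomass-vs-diversity mismatches
  sw_a <- mismatch_sweep(data.frame(alpha = c(0, 1)), replicates = 8,
                         n_perturbations = 300, pair = "biomass_diversity",
                         sd_range = c(1, 2), seed = 20)
  m <- tapply(sw_a$observed, sw_a$alpha, mean)
  expect_lt(m["0"], m["1"])
})

test_that("sweep tables round-trip through CSV with a config header", {
  sw <- mismatch_sweep(data.frame(mu = 0, alpha = 0), replicates = 2,
                       n_perturbations = 50, seed = 21)
  p <- tempfile(fileext = ".csv")
  write_sweep(sw, p, config = list(mu = 0, alpha = 0, seed = 21))
  expect_match(readLines(p, n = 1), "^# config: \\{")
  back <- read.csv(p, comment.char = "#")
  expect_equal(back$observed, sw$observed)
})
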