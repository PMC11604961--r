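test_that("broadness estimates transform Wilson intervals through the mismatch map", {
  est <- estimate_broadness(0, 40)
  expect_equal(est$estimate, 1)
  expect_lt(est$lower, 1)
  expect_false(est$positive_violation)
  expect_false(est$low_confidence)

  est2 <- estimate_broadness(10, 20)
  expect_equal(est2$estimate, 0, tolerance = 1e-12)

  est3 <- estimate_broadness(12, 20)
  expect_true(est3$positive_violation)
  expect_equal(est3$estimate, 0, tolerance = 1e-12)

  expect_true(estimate_broadness(1, 5)$low_confidence)
  expect_error(estimate_broadness(0, 0), "insufficient")
  # interval is ordered and transforms the binomial interval monotonically
  est4 <- estimate_broadness(3, 30)
  ci <- wilson_interval(3, 30)
  expect_equal(est4$lower, cos(ci["upper"] * pi)^2, ignore_attr = TRUE)
  expect_equal(est4$upper, cos(ci["lower"] * pi)^2, ignore_attr = TRUE)
  expect_lt(est4$lower, est4$estimate)
  expect_gt(est4$upper, est4$estimate)
})

test_that("relative deviation is signed and anchored at its trivial points", {
  expect_equal(relative_deviation(0.4, 0.4), 0)
  expect_equal(relative_deviation(0, 0.4), 1)
  expect_error(relative_deviation(0.1, 0), "baseline")
  # deviation grows with |mu| at a fixed function pair
  set.seed(21)
  S <- 50
  N <- generate_community(c(S, S), c(1, 1))
  f <- generate_function(S, 1); g <- generate_function(S, 1)
  devs <- vapply(c(0, 0.15, 0.3), function(mu) {
    mean(replicate(6, {
      ex <- run_mismatch_experiment(N, list(f = f, g = g), 600, mu = mu,
                                    alpha = 0)
      relative_deviation(ex$pairs$proportion[1], ex$pairs$predicted[1])
    }))
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
})

test_that("calibration curves are monotone, invertible and serializable", {
  single <- build_calibration_curve("alpha", 0.5, n_communities = 2,
                                    n_perturbations = 50,
                                    richness_range = c(20, 20),
                                    sd_range = c(1, 1), seed = 22)
  expect_equal(single$fitted, single$mean_raw)
  est_single <- estimate_biomass_scaling(round(single$fitted * 50), 50, single)
  expect_equal(est_single$alpha_hat, 0.5)

  cc <- build_calibration_curve("alpha", seq(0, 1, 0.25),
                                n_communities = 8, n_perturbations = 300,
                                richness_range = c(30, 60),
                                sd_range = c(1, 2), seed = 23)
  expect_true(all(diff(cc$fitted) >= 0))
  # anchor: observed proportion at the alpha = 0 mean maps back to 0
  est0 <- estimate_biomass_scaling(round(cc$fitted[1] * 1000), 1000, cc)
  expect_equal(est0$alpha_hat, 0, tolerance = 0.02)
  # an observed proportion above 1/2 needs biomass scaling
  est_hi <- estimate_biomass_scaling(55, 100, cc)
  expect_gt(est_hi$alpha_hat, 0)
  # boundary clamping is flagged
  est_out <- estimate_biomass_scaling(99, 100, cc)
  expect_true(est_out$extrapolated)
  expect_equal(est_out$alpha_hat, 1)

  path <- tempfile(fileext = ".json")
  write_calibration(cc, path)
  cc2 <- read_calibration(path)
  expect_equal(cc2$grid, cc$grid, tolerance = 0)
  expect_equal(cc2$fitted, cc$fitted, tolerance = 0)
  expect_equal(cc2$mean_raw, cc$mean_raw, tolerance = 0)
  expect_equal(cc2$parameter, cc$parameter)
})

test_that("response-consistency estimation inverts the mu curve", {
  cc <- build_calibration_curve("mu", seq(0, 0.4, 0.1), n_communities = 10,
                                n_perturbations = 500,
                                richness_range = c(40, 40),
                                sd_range = c(1, 1), contribution_sd = 1,
                                seed = 24)
  expect_true(all(diff(cc$fitted) >= 0))
  # zero deviation -> (near) zero bias
  theta <- pi / 4
  n <- 4000
  est <- estimate_response_consistency(round(0.25 * n), n, theta, cc)
  expect_lt(est$mu_hat, 0.06)
  expect_lt(est$bias_hat, 0.03)
  # a strongly suppressed proportion maps to a positive mu
  est2 <- estimate_response_consistency(round(0.12 * n), n, theta, cc)
  expect_gt(est2$mu_hat, 0.1)
  expect_error(estimate_response_consistency(5, 50, NULL, cc),
               "configuration")
  cc_a <- build_calibration_curve("alpha", c(0, 1), n_communities = 2,
                                  n_perturbations = 50,
                                  richness_range = c(20, 20),
                                  sd_range = c(1, 1), seed = 25)
  expect_error(estimate_response_consistency(5, 50, theta, cc_a), "'mu'")
  expect_error(estimate_biomass_scaling(5, 50, cc), "'alpha'")
})

test_that("class rankings order by mismatch proportion", {
  df <- data.frame(class = c("a", "b", "c"),
                   n_mismatches = c(5, 1, 10), n_pairs = c(20, 20, 20))
  rk <- rank_classes(df)
  expect_equal(rk$class[order(rk$rank)], c("b", "a", "c"))
  # invariant to any monotone recalibration: ranking depends only on
  # proportions, which a monotone map preserves
  rk2 <- rank_classes(transform(df, n_mismatches = n_mismatches))
  expect_equal(rk$rank, rk2$rank)
})
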