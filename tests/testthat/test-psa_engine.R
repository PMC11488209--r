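test_that("gamma calibration reproduces the requested moments", {
  expect_equal(unname(gamma_from_moments(5, 5)["shape"]), 1) # exponential
  pars <- gamma_from_moments(389439, 30563)
  expect_equal(unname(pars["shape"]), (389439 / 30563)^2)
  expect_equal(unname(pars["scale"]), 30563^2 / 389439)
  expect_equal(round_half_up(pars[["shape"]], 2), 162.36)
  expect_equal(round_half_up(pars[["scale"]], 2), 2398.6, tolerance = 0.001)
  expect_error(gamma_from_moments(0, 1), "mean > 0")
  expect_error(gamma_from_moments(1, 0), "sd > 0")
})

test_that("beta calibration reproduces the requested moments", {
  u <- beta_from_moments(0.5, sqrt(1 / 12))
  expect_equal(unname(u), c(1, 1), tolerance = 1e-12) # uniform special case

  m <- 0.84
  s <- 0.0149
  pars <- beta_from_moments(m, s)
  nu <- m * (1 - m) / s^2 - 1 # method-of-moments oracle by hand
  expect_equal(unname(pars["alpha"]), m * nu)
  expect_equal(unname(pars["beta"]), (1 - m) * nu)
  expect_equal(unname(pars["alpha"]), 507.7, tolerance = 0.001)
  expect_equal(unname(pars["beta"]), 96.7, tolerance = 0.001)

  expect_error(beta_from_moments(1.2, 0.1), "in \\(0, 1\\)")
  expect_error(beta_from_moments(0.5, 0.6), "sd")
})

test_that("sampled moments match calibrated gamma and beta specs", {
  n <- 1e5
  g <- dist_spec("gamma", mean = 145020, sd = 26507, source = "ci_derived")
  draws <- withr::with_seed(41, stats::rgamma(n, shape = g$shape, scale = g$scale))
  expect_lt(abs(mean(draws) - g$mean), 4 * g$sd / sqrt(n))
  expect_lt(abs(stats::sd(draws) - g$sd), 4 * g$sd / sqrt(2 * n))

  b <- dist_spec("beta", mean = 0.84, sd = 0.0149, source = "stated_sd")
  bd <- withr::with_seed(42, stats::rbeta(n, b$alpha, b$beta))
  expect_lt(abs(mean(bd) - b$mean), 4 * b$sd / sqrt(n))
  expect_lt(abs(stats::sd(bd) - b$sd), 4 * b$sd / sqrt(2 * n))
})

test_that("printed 95% CIs convert to SDs by the normal-width rule", {
  expect_equal(round_half_up(sd_from_ci95(100014, 203922), 1), 26507.1)
  expect_equal(round_half_up(sd_from_ci95(331417, 451226), 1), 30563.5)
  expect_equal(sd_from_ci95(7, 7), 0)
  expect_error(sd_from_ci95(10, 5), "below")
})

test_that("percentile CIs use linear interpolation between order statistics", {
  expect_equal(percentile_ci(rep(3.5, 50)), c(lo = 3.5, hi = 3.5))
  expect_equal(percentile_ci(1:1000), c(lo = 25.975, hi = 975.025))
  x <- withr::with_seed(43, stats::rnorm(500))
  expect_equal(percentile_ci(x), percentile_ci(rev(sort(x)))) # permutation invariant
  expect_error(percentile_ci(numeric(0)), "no draws")
})

test_that("dist_spec defaults to the 10%-of-mean rule and validates point masses", {
  d <- dist_spec("gamma", mean = 200)
  expect_equal(d$sd, 20)
  expect_equal(d$source, "ten_percent_rule")
  expect_error(dist_spec("point", mean = 5, sd = 1), "sd = 0")
})

test_that("the PSA is deterministic in its seed and keeps per-quantity substreams stable", {
  spec <- reference_case_psa_spec(n_draws = 300, seed = 99)
  a <- run_psa(spec)
  b <- run_psa(spec)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)

  # adding an unrelated quantity must not perturb the others' draws
  wider <- psa_spec(
    quantities = c(
      spec$quantities,
      list(extra = dist_spec("beta", 0.5, 0.05, "stated_sd"))
    ),
    n_draws = 300, seed = 99
  )
  more <- econsultCBA:::sample_quantities(wider)
  expect_identical(more$total_benefit, a$draws$total_benefit)
})

test_that("degenerate point-mass PSA collapses to the ratio-of-means estimate", {
  spec <- psa_spec(
    quantities = list(
      total_benefit = dist_spec("point", 389439, 0),
      total_cost = dist_spec("point", 145020, 0)
    ),
    n_draws = 100, seed = 1
  )
  out <- run_psa(spec)
  expect_equal(unique(out$draws$roi), 389439 / 145020 - 1)
  expect_equal(
    out$summary$mean[out$summary$metric == "roi"],
    cba_point(389439, 145020)$roi
  )
  expect_equal(round_half_up(out$summary$mean[out$summary$metric == "roi"], 3), 1.685)

  doubled <- one_way_scenario(spec, 2)
  expect_equal(
    round_half_up(doubled$summary$mean[doubled$summary$metric == "roi"], 3),
    0.343 # (B - 2C) / 2C by hand
  )
})

test_that("per-draw and summary identities hold on every PSA run", {
  spec <- reference_case_psa_spec(n_draws = 1000, seed = 5)
  out <- run_psa(spec)
  expect_equal(out$draws$bcr - out$draws$roi, rep(1, 1000))
  s <- out$summary
  expect_true(all(s$lo <= s$hi))
  expect_equal(
    s$mean[s$metric == "bcr"] - s$mean[s$metric == "roi"], 1
  )
  # linearity: mean net benefit is exactly mean benefit minus mean cost
  expect_equal(
    s$mean[s$metric == "net_benefit"],
    s$mean[s$metric == "total_benefit"] - s$mean[s$metric == "total_cost"]
  )
  # Jensen: mean of per-draw ratios exceeds the ratio of means under cost noise
  expect_gt(
    s$mean[s$metric == "bcr"],
    s$mean[s$metric == "total_benefit"] / s$mean[s$metric == "total_cost"]
  )
})

test_that("a cost multiplier of one reproduces the reference run exactly", {
  spec <- reference_case_psa_spec(n_draws = 200, seed = 7)
  expect_identical(
    one_way_scenario(spec, 1)$draws,
    run_psa(spec)$draws
  )
})

test_that("mean ROI is stable across seeds within Monte Carlo error", {
  means <- vapply(c(2, 12, 22, 32), function(s) {
    out <- run_psa(reference_case_psa_spec(n_draws = 1000, seed = s))
    out$summary$mean[out$summary$metric == "roi"]
  }, numeric(1))
  ses <- vapply(c(2, 12, 22, 32), function(s) {
    out <- run_psa(reference_case_psa_spec(n_draws = 1000, seed = s))
    stats::sd(out$draws$roi) / sqrt(1000)
  }, numeric(1))
  grand <- mean(means)
  expect_true(all(abs(means - grand) < 3 * ses))
})
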