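test_that("proportion_estimate returns counts, proportion and binomial SE", {
  out <- proportion_estimate(rep(c(TRUE, FALSE), c(511, 97)))
  expect_equal(out$numerator, 511)
  expect_equal(out$denominator, 608)
  expect_equal(out$proportion, 511 / 608)
  expect_equal(round_half_up(100 * out$proportion), 84)
  expect_equal(out$se, sqrt((511 / 608) * (97 / 608) / 608))

  degenerate <- proportion_estimate(rep(FALSE, 100))
  expect_equal(degenerate$proportion, 0)
  expect_equal(degenerate$se, 0)

  expect_error(proportion_estimate(logical(0)), "no non-missing")
  expect_error(proportion_estimate(NA), "no non-missing")
})

test_that("proportion_estimate matches a brute-force recount on random input", {
  x <- withr::with_seed(31, stats::runif(500) < 0.3)
  out <- proportion_estimate(x)
  brute <- 0
  for (v in x) if (v) brute <- brute + 1
  expect_equal(out$numerator, brute)
})

test_that("top-two-box is the share of responses of 4 or 5", {
  expect_equal(top_two_box(rep(5, 10))$proportion, 1)
  expect_equal(top_two_box(c(5, 4, 3, 2, 1))$proportion, 0.4)
  expect_equal(top_two_box(c(4, NA, 1))$denominator, 2)
  expect_error(top_two_box(c(5, 6)), "position")
  expect_error(top_two_box(c(0, 3)), "out of range")
})

test_that("adding a top-box response never lowers the top-two-box rate", {
  for (seed in 1:20) {
    v <- random_likert(30, seed)
    expect_gte(
      top_two_box(c(v, 5))$proportion,
      top_two_box(v)$proportion
    )
  }
})

test_that("necessity breakdown groups the scale and keeps a residual share", {
  uniform <- necessity_breakdown(rep(necessity_scale, 10))
  expect_equal(uniform$shares$share, c(0.5, 0.5, 0))

  single <- necessity_breakdown("necessary")
  expect_equal(single$shares$share, c(0, 1, 0))

  mixed <- necessity_breakdown(
    rep(c(necessity_scale, "unsure", NA), c(11, 11, 8, 10, 5, 5))
  )
  expect_equal(mixed$n, 45)
  expect_equal(mixed$n_excluded, 5)
  expect_equal(sum(mixed$shares$share), 1)
  expect_equal(mixed$shares$share[3], 5 / 45)

  expect_error(necessity_breakdown(c("necessary", "maybe")), "scale")
  expect_error(necessity_breakdown(NA_character_), "no necessity")
})

test_that("usage-band distribution reports fixed-order counts and whole percents", {
  x <- tibble::tibble(usage_band = rep(usage_bands, c(34, 20, 18, 17)))
  out <- usage_band_distribution(x)
  expect_equal(out$usage_band, usage_bands)
  expect_equal(out$count, c(34, 20, 18, 17))
  expect_equal(out$share_pct, c(38, 22, 20, 19))
  expect_equal(out$share[1], 34 / 89) # hand division: 38.2% -> 38

  one <- usage_band_distribution(tibble::tibble(usage_band = rep("6-10", 5)))
  expect_equal(one$share_pct, c(0, 100, 0, 0))

  expect_error(usage_band_distribution(tibble::tibble(usage_band = "lots")), "usage_band")
})

test_that("non-avoided follow-up summarises the three items over the subset", {
  resp <- tibble::tibble(
    avoided_referral = rep(c("yes", "no"), c(10, 8)),
    intended_to_avoid = c(rep("not_applicable", 10), rep(c("no", "yes"), c(6, 2))),
    improved_referral_quality = c(rep("not_applicable", 10), rep(c("yes", "no"), c(7, 1))),
    improved_interim_care = c(rep("not_applicable", 10), rep("yes", 8))
  )
  out <- non_avoided_followup(resp)
  expect_equal(out$denominator, rep(8, 3))
  # brute-force recount over the non-avoided subset
  expect_equal(out$proportion[out$item == "not_intended_to_avoid"], 6 / 8)
  expect_equal(out$proportion[out$item == "improved_referral_quality"], 7 / 8)
  expect_equal(out$proportion[out$item == "improved_interim_care"], 1)

  expect_error(
    non_avoided_followup(dplyr::filter(resp, avoided_referral == "yes")),
    "no responses"
  )
})

test_that("survey shares always lie in [0, 1] and grouped shares sum to one", {
  for (seed in 1:15) {
    x <- withr::with_seed(seed, sample(
      c(necessity_scale, "unsure"), 80,
      replace = TRUE, prob = c(0.3, 0.25, 0.2, 0.15, 0.1)
    ))
    shares <- necessity_breakdown(x)$shares$share
    expect_true(all(shares >= 0 & shares <= 1))
    expect_equal(sum(shares), 1)
  }
})
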