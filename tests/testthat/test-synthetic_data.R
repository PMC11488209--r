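test_that("every generator is a pure function of configuration and seed", {
  cfg <- small_config(seed = 3)
  expect_identical(gen_consult_log(cfg), gen_consult_log(cfg))
  log <- gen_consult_log(cfg)
  expect_identical(
    gen_post_consult_surveys(log, cfg),
    gen_post_consult_surveys(log, cfg)
  )
  expect_identical(gen_experience_surveys(cfg), gen_experience_surveys(cfg))
  expect_identical(
    gen_fee_schedule(cfg)$comprehensive_fee,
    gen_fee_schedule(cfg)$comprehensive_fee
  )
  other_seed <- gen_consult_log(small_config(seed = 4))
  expect_false(identical(log$specialty, other_seed$specialty))
})

test_that("consult logs follow the configured specialty mix and window", {
  cfg <- generator_config(seed = 8)
  log <- gen_consult_log(cfg)
  expect_equal(nrow(log), 6072)
  expect_false(anyDuplicated(log$consult_id) > 0)
  expect_true(all(log$date >= cfg$window_start & log$date <= cfg$window_end))

  n_im <- sum(log$specialty == "internal_medicine")
  p <- cfg$specialty_shares[["internal_medicine"]]
  se <- sqrt(6072 * p * (1 - p)) # multinomial sampling oracle
  expect_lt(abs(n_im - 1318), 3 * se)

  expect_equal(nrow(gen_consult_log(generator_config(n_consults = 0))), 0)
  expect_error(
    generator_config(specialty_shares = c(a = 0.5, b = 0.4)),
    "sum to 1"
  )
})

test_that("post-consultation surveys honour their design", {
  cfg <- small_config(seed = 5)
  log <- gen_consult_log(cfg)
  sv <- gen_post_consult_surveys(log, cfg)

  expect_equal(nrow(sv$primary_care), 608)
  expect_equal(nrow(sv$specialist), 653)
  # responses are tied to distinct consults (sampled without replacement)
  expect_false(anyDuplicated(sv$primary_care$consult_id) > 0)
  expect_true(all(sv$primary_care$consult_id %in% log$consult_id))
  # role-specific items: necessity only for specialists, avoidance only for PCP
  expect_true(all(is.na(sv$primary_care$necessity)))
  expect_true(all(is.na(sv$specialist$avoided_referral)))
  expect_equal(sum(!is.na(sv$specialist$necessity)), 638)
  # follow-up items are not-applicable exactly when the referral was avoided
  avoided <- sv$primary_care$avoided_referral == "yes"
  expect_true(all(sv$primary_care$intended_to_avoid[avoided] == "not_applicable"))
  expect_true(all(sv$primary_care$intended_to_avoid[!avoided] %in% c("yes", "no")))

  all_avoided <- small_config(seed = 5, survey_params = list(avoidance = 1))
  sv2 <- gen_post_consult_surveys(gen_consult_log(all_avoided), all_avoided)
  expect_equal(sum(sv2$primary_care$avoided_referral == "no"), 0)

  tiny_log <- gen_consult_log(generator_config(n_consults = 10))
  expect_error(gen_post_consult_surveys(tiny_log, cfg), "exceed")
})

test_that("experience surveys follow the configured band weights", {
  cfg <- small_config(seed = 6)
  ex <- gen_experience_surveys(cfg)
  expect_equal(nrow(ex), 89)
  expect_true(all(ex$usage_band %in% usage_bands))
  expect_true(all(ex$overall_satisfaction %in% 1:5))

  one <- small_config(seed = 6, experience_params = list(n_respondents = 1))
  expect_equal(sum(usage_band_distribution(gen_experience_surveys(one))$share_pct == 100), 1)

  degenerate <- small_config(
    seed = 6,
    experience_params = list(band_weights = c(1, 0, 0, 0))
  )
  expect_true(all(gen_experience_surveys(degenerate)$usage_band == "1-5"))
})

test_that("generated fee schedules carry the phone-consult codes and the fee floor", {
  cfg <- small_config(seed = 7)
  sched <- gen_fee_schedule(cfg)
  expect_true(all(c("CONS 03.09 L", "VIST 03.09 K") %in% sched$codes$code_id))
  expect_true(all(sched$comprehensive_fee >= vh_encounter_cost(sched)))

  flat <- small_config(seed = 7, fee_params = list(comprehensive_fee_sd = 0))
  fs <- gen_fee_schedule(flat)
  expect_true(all(fs$comprehensive_fee == 174.17))
  expect_equal(
    net_avoided_cost(names(fs$comprehensive_fee)[1], fs)$net_avoided,
    76.35
  )
})

test_that("cost ledgers draw onboarding fees at the configured moments", {
  flat <- small_config(seed = 8, cost_params = list(onboarding_fee_sd = 0, n_groups = 3))
  led <- gen_cost_ledger(flat)
  expect_equal(sum(led$onboarding_fees), 3 * 1265)

  none <- small_config(seed = 8, cost_params = list(n_groups = 0))
  expect_length(gen_cost_ledger(none)$onboarding_fees, 0)

  many <- small_config(seed = 8, cost_params = list(n_groups = 10000))
  fees <- gen_cost_ledger(many)$onboarding_fees
  expect_lt(abs(mean(fees) - 1265), 3 * 230 / sqrt(10000)) # sampling oracle
})

test_that("generated datasets round-trip through the package readers", {
  cfg <- small_config(seed = 9)
  dir <- withr::local_tempdir()
  paths <- generate_dataset(cfg, dir)
  expect_true(all(file.exists(paths)))

  log <- gen_consult_log(cfg)
  expect_equal(read_consult_log(paths[["consults"]]), log)

  sv <- gen_post_consult_surveys(log, cfg)
  back <- read_post_consult_surveys(paths[["post_consult"]])
  expect_equal(back, dplyr::bind_rows(sv$primary_care, sv$specialist))

  sched <- gen_fee_schedule(cfg)
  sched_back <- read_fee_schedule(paths[["fee_codes"]], paths[["fee_sidecar"]])
  expect_equal(sched_back$comprehensive_fee, sched$comprehensive_fee)

  cost_back <- read_cost_config(paths[["cost_config"]])
  expect_equal(unclass(cost_back$config), unclass(gen_cost_ledger(cfg)$config))

  # byte-identical regeneration under the same seed
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, dir2)
  expect_identical(
    readLines(file.path(dir, "consults.csv")),
    readLines(file.path(dir2, "consults.csv"))
  )
})

test_that("survey estimators recover their generating parameters at the binomial rate", {
  # Exact 2-SE coverage of a binomial proportion (enumeration oracle):
  exact_coverage <- function(n, p) {
    se <- sqrt(p * (1 - p) / n)
    stats::pbinom(floor(n * (p + 2 * se)), n, p) -
      stats::pbinom(ceiling(n * (p - 2 * se)) - 1, n, p)
  }
  # The generators answer each item by an independent Bernoulli draw per
  # response, so the estimator's sampling distribution is exactly binomial;
  # high-repetition coverage is checked at the mechanism level and the full
  # generator is then matched against it on a smaller loop.
  within_2se <- function(est, p, n) abs(est - p) <= 2 * sqrt(p * (1 - p) / n)

  reps <- 2e4
  mech <- function(n, p) {
    mean(within_2se(stats::rbinom(reps, n, p) / n, p, n))
  }
  params <- list(
    avoidance = c(n = 608, p = 0.84),
    specialist_satisfaction = c(n = 653, p = 0.96),
    necessity_unnecessary = c(n = 638, p = 0.55)
  )
  withr::with_seed(51, {
    for (pp in params) {
      emp <- mech(pp[["n"]], pp[["p"]])
      exact <- exact_coverage(pp[["n"]], pp[["p"]])
      expect_gte(emp, 0.95) # the recovery property itself
      expect_lt(abs(emp - exact), 4 * sqrt(exact * (1 - exact) / reps))
    }
  })

  # Full-generator loop: coverage consistent with the exact oracle.
  k <- 60
  hits <- c(avoidance = 0, satisfaction = 0, necessity = 0)
  for (seed in seq_len(k)) {
    cfg <- small_config(seed = 1000 + seed)
    sv <- gen_post_consult_surveys(gen_consult_log(cfg), cfg)
    est_av <- proportion_estimate(sv$primary_care$avoided_referral == "yes")
    hits[["avoidance"]] <- hits[["avoidance"]] +
      within_2se(est_av$proportion, 0.84, 608)
    est_sat <- top_two_box(sv$specialist$satisfaction)
    hits[["satisfaction"]] <- hits[["satisfaction"]] +
      within_2se(est_sat$proportion, 0.96, 653)
    nec <- necessity_breakdown(sv$specialist$necessity)
    hits[["necessity"]] <- hits[["necessity"]] +
      within_2se(nec$shares$share[1], 0.55, 638)
  }
  for (nm in names(hits)) {
    expect_gte(hits[[nm]] / k, 0.95 - 3 * sqrt(0.95 * 0.05 / k))
  }
})
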