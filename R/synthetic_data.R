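#' Configuration of the synthetic-data generator
#'
#' The generator emulates the administrative and survey inputs of a
#' provincial e-consult feasibility evaluation so the whole pipeline runs
#' without access to the (non-public) platform data. Defaults encode the
#' evaluation's study conditions: 6,072 completed consults with the
#' published top-ten specialty mix (remainder pooled as `"other"`),
#' 873 primary-care providers and 143 specialists, survey response counts
#' and rates as printed (608 primary-care post-consultation responses at
#' 84% referral avoidance, 653 specialist responses of which 638 answered
#' the necessity item, 89 experience respondents with usage-band weights
#' 34/20/18/17), a fee schedule with the two phone-consult codes at $2.68
#' per MSU, and a cost ledger with ~$1,265 (SD $230) onboarding per
#' specialist group and a $10,000 monthly license.
#'
#' The comprehensive-fee mean of $174.17 is a derived calibration — the
#' published benefit total divided by referrals avoided, plus the $97.82
#' encounter cost — not a published fee; its dispersion (SD $25) has no
#' published anchor. The cost-timeline defaults (20 groups, 12 months) are
#' likewise unanchored choices, since the published cost total cannot be
#' decomposed into its timeline.
#'
#' @param seed Master integer seed; every generator draws from a substream
#'   derived from it, so outputs are jointly reproducible.
#' @param n_consults Number of consult records.
#' @param specialty_shares Named proportions summing to 1.
#' @param window_start,window_end Utilization window (ISO dates).
#' @param n_primary_care,n_specialists Provider registry sizes.
#' @param survey_params,experience_params,fee_params,cost_params Named lists
#'   overriding individual defaults (partial lists allowed).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_consults = 6072,
                             specialty_shares = NULL,
                             window_start = "2022-05-01",
                             window_end = "2024-01-31",
                             n_primary_care = 873,
                             n_specialists = 143,
                             survey_params = list(),
                             experience_params = list(),
                             fee_params = list(),
                             cost_params = list()) {
  if (is.null(specialty_shares)) {
    counts <- c(
      internal_medicine = 1318, psychiatry = 1020, obgyn = 431,
      endocrinology = 383, hematology = 322, hepatology = 279,
      rheumatology = 243, pediatrics = 237, infectious_diseases = 176,
      general_surgery = 103
    )
    counts <- c(counts, other = 6072 - sum(counts))
    specialty_shares <- counts / sum(counts)
  }
  if (abs(sum(specialty_shares) - 1) > 1e-9) {
    stop("`specialty_shares` must sum to 1", call. = FALSE)
  }
  if (any(specialty_shares < 0)) {
    stop("`specialty_shares` must be non-negative", call. = FALSE)
  }
  sp <- utils::modifyList(
    list(
      n_pcp_responses = 608,
      n_specialist_responses = 653,
      n_necessity = 638,
      avoidance = 0.84,
      pcp_satisfaction = 0.99,
      specialist_satisfaction = 0.96,
      # unnecessary-group, necessary-group, unsure residual
      necessity_split = c(0.55, 0.40, 0.05),
      # among non-avoided consults: not intended / improved quality / care
      non_avoided = c(
        not_intended = 0.89,
        improved_quality = 0.89,
        improved_care = 0.90
      )
    ),
    survey_params
  )
  ep <- utils::modifyList(
    list(
      n_respondents = 89,
      band_weights = c(34, 20, 18, 17),
      pcp_share = 873 / 1016,
      satisfaction = c(primary_care = 0.96, specialist = 0.92),
      continue_rate = 0.97,
      recommend_rate = 0.97,
      impact_rates = c(
        access = 0.95, referral_quality = 0.78, time_to_diagnosis = 0.93,
        capacity_comfort = 0.98, patient_care = 0.99, interprofessional = 0.98
      )
    ),
    experience_params
  )
  fp <- utils::modifyList(
    list(comprehensive_fee_mean = 174.17, comprehensive_fee_sd = 25),
    fee_params
  )
  cp <- utils::modifyList(
    list(
      onboarding_fee_mean = 1265, onboarding_fee_sd = 230,
      n_groups = 20, monthly_license = 10000, horizon_months = 12,
      annual_discount_rate = 0.07, discounting_enabled = TRUE
    ),
    cost_params
  )
  stopifnot(
    sp$avoidance >= 0, sp$avoidance <= 1,
    abs(sum(sp$necessity_split) - 1) < 1e-9,
    length(ep$band_weights) == 4, all(ep$band_weights >= 0)
  )
  structure(
    list(
      seed = as.integer(seed),
      n_consults = as.integer(n_consults),
      specialty_shares = specialty_shares,
      window_start = as.Date(window_start),
      window_end = as.Date(window_end),
      n_primary_care = as.integer(n_primary_care),
      n_specialists = as.integer(n_specialists),
      survey_params = sp,
      experience_params = ep,
      fee_params = fp,
      cost_params = cp
    ),
    class = "generator_config"
  )
}

# Run `expr` under the substream seed for generator `name`, restoring the
# caller's RNG state afterwards.
with_substream <- function(config, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(config$seed, name))
  force(expr)
}

# Likert value with a given top-two-box probability: 4/5 with prob p (split
# evenly), otherwise 1..3 uniform.
draw_likert <- function(n, top_two_rate) {
  top <- stats::runif(n) < top_two_rate
  ifelse(top, sample(4:5, n, replace = TRUE), sample(1:3, n, replace = TRUE))
}

#' Generate a synthetic consult log
#'
#' Specialties are drawn multinomially from the configured shares, dates
#' uniformly over the study window; all records are completed consults
#' requested by primary care.
#'
#' @param config A [generator_config()].
#' @return A tibble of consult records (`consult_id`, `specialty`, `date`,
#'   `completed`, `requesting_role`).
#' @export
gen_consult_log <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_consults
  if (n == 0) {
    return(tibble::tibble(
      consult_id = character(), specialty = character(),
      date = as.Date(character()), completed = logical(),
      requesting_role = character()
    ))
  }
  with_substream(config, "consult_log", {
    days <- seq(config$window_start, config$window_end, by = "day")
    tibble::tibble(
      consult_id = sprintf("C%06d", seq_len(n)),
      specialty = sample(
        names(config$specialty_shares), n,
        replace = TRUE, prob = config$specialty_shares
      ),
      date = sample(days, n, replace = TRUE),
      completed = TRUE,
      requesting_role = "primary_care"
    )
  })
}

#' Generate a synthetic provider registry
#'
#' @param config A [generator_config()].
#' @return A tibble of provider records (`provider_id`, `role`, `join_date`).
#' @export
gen_provider_registry <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_primary_care + config$n_specialists
  with_substream(config, "provider_registry", {
    days <- seq(config$window_start, config$window_end, by = "day")
    tibble::tibble(
      provider_id = sprintf("P%04d", seq_len(n)),
      role = rep(
        c("primary_care", "specialist"),
        c(config$n_primary_care, config$n_specialists)
      ),
      join_date = if (n > 0) sort(sample(days, n, replace = TRUE)) else as.Date(character())
    )
  })
}

#' Generate synthetic post-consultation survey responses
#'
#' Responses are sampled without replacement from the consult log (the real
#' survey was a per-consult pop-up, so each response is tied to a consult).
#' Primary-care responses carry satisfaction (top-two rate 0.99 by default)
#' and the avoided-referral item (Bernoulli at the avoidance rate); consults
#' that did not avoid a referral get the three follow-up items. Specialist
#' responses carry satisfaction (0.96) and the referral-necessity item at
#' the configured unnecessary/necessary/unsure split, answered for
#' `n_necessity` of the responses.
#'
#' @param log A consult log (see [gen_consult_log()]).
#' @param config A [generator_config()].
#' @return A list of tibbles `primary_care` and `specialist`.
#' @export
gen_post_consult_surveys <- function(log, config) {
  stopifnot(inherits(config, "generator_config"))
  sp <- config$survey_params
  if (max(sp$n_pcp_responses, sp$n_specialist_responses) > nrow(log)) {
    stop("survey response counts exceed the consult log size", call. = FALSE)
  }
  with_substream(config, "post_consult_surveys", {
    pcp_ids <- sample(log$consult_id, sp$n_pcp_responses)
    n1 <- sp$n_pcp_responses
    avoided <- stats::runif(n1) < sp$avoidance
    followup <- function(p_yes) {
      ifelse(avoided, "not_applicable",
        ifelse(stats::runif(n1) < p_yes, "yes", "no")
      )
    }
    primary_care <- tibble::tibble(
      consult_id = pcp_ids,
      responder_role = "primary_care",
      satisfaction = draw_likert(n1, sp$pcp_satisfaction),
      avoided_referral = ifelse(avoided, "yes", "no"),
      # "intended to avoid": no with prob not_intended among non-avoided
      intended_to_avoid = followup(1 - sp$non_avoided[["not_intended"]]),
      improved_referral_quality = followup(sp$non_avoided[["improved_quality"]]),
      improved_interim_care = followup(sp$non_avoided[["improved_care"]]),
      necessity = NA_character_
    )
    spec_ids <- sample(log$consult_id, sp$n_specialist_responses)
    n2 <- sp$n_specialist_responses
    split <- sp$necessity_split
    necessity <- sample(
      c(
        necessity_scale[1:2], # unnecessary group, split evenly
        necessity_scale[3:4], # necessary group, split evenly
        "unsure"
      ),
      n2,
      replace = TRUE,
      prob = c(rep(split[1] / 2, 2), rep(split[2] / 2, 2), split[3])
    )
    necessity[sample.int(n2, n2 - sp$n_necessity)] <- NA_character_
    specialist <- tibble::tibble(
      consult_id = spec_ids,
      responder_role = "specialist",
      satisfaction = draw_likert(n2, sp$specialist_satisfaction),
      avoided_referral = NA_character_,
      intended_to_avoid = NA_character_,
      improved_referral_quality = NA_character_,
      improved_interim_care = NA_character_,
      necessity = necessity
    )
    list(primary_care = primary_care, specialist = specialist)
  })
}

#' Generate synthetic provider-experience survey responses
#'
#' @param config A [generator_config()].
#' @return A tibble with `responder_role`, `usage_band`,
#'   `overall_satisfaction`, `intend_to_continue`, `would_recommend` and the
#'   six `impact_*` Likert items.
#' @export
gen_experience_surveys <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ep <- config$experience_params
  n <- ep$n_respondents
  if (n == 0) {
    return(tibble::tibble())
  }
  with_substream(config, "experience_surveys", {
    role <- ifelse(
      stats::runif(n) < ep$pcp_share, "primary_care", "specialist"
    )
    out <- tibble::tibble(
      responder_role = role,
      usage_band = sample(
        usage_bands, n,
        replace = TRUE, prob = ep$band_weights / sum(ep$band_weights)
      ),
      overall_satisfaction = draw_likert(n, ep$satisfaction[role]),
      intend_to_continue = draw_likert(n, ep$continue_rate),
      would_recommend = draw_likert(n, ep$recommend_rate)
    )
    for (item in names(ep$impact_rates)) {
      out[[paste0("impact_", item)]] <- draw_likert(n, ep$impact_rates[[item]])
    }
    out
  })
}

#' Generate a synthetic fee schedule
#'
#' Always contains the two phone-consult codes (11.5 and 25 MSU at the
#' configured rate); per-specialty comprehensive consultation fees are drawn
#' from a gamma distribution and truncated below at the encounter cost so
#' net avoided costs are non-negative by default (set
#' `truncate_at_encounter_cost = FALSE` to allow low-fee specialties).
#'
#' @param config A [generator_config()].
#' @param specialties Specialty names to price; defaults to the share map.
#' @param truncate_at_encounter_cost Resample fees below the virtual
#'   encounter cost?
#' @return A [fee_schedule()].
#' @export
gen_fee_schedule <- function(config,
                             specialties = names(config$specialty_shares),
                             truncate_at_encounter_cost = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  fp <- config$fee_params
  if (fp$comprehensive_fee_mean <= 0) {
    stop("comprehensive fee mean must be positive", call. = FALSE)
  }
  base <- default_fee_schedule()
  floor_fee <- vh_encounter_cost(base)
  fees <- with_substream(config, "fee_schedule", {
    if (fp$comprehensive_fee_sd == 0) {
      rep(fp$comprehensive_fee_mean, length(specialties))
    } else {
      pars <- gamma_from_moments(fp$comprehensive_fee_mean, fp$comprehensive_fee_sd)
      f <- stats::rgamma(length(specialties), shape = pars[["shape"]], scale = pars[["scale"]])
      if (truncate_at_encounter_cost) {
        while (any(f < floor_fee)) {
          i <- f < floor_fee
          f[i] <- stats::rgamma(sum(i), shape = pars[["shape"]], scale = pars[["scale"]])
        }
      }
      f
    }
  })
  default_fee_schedule(
    comprehensive_fee = stats::setNames(round_half_up(fees, 2), specialties)
  )
}

#' Generate a synthetic implementation-cost ledger
#'
#' @param config A [generator_config()].
#' @return A list: `config` (a [cost_config()]) and `onboarding_fees`
#'   (realized per-group fees drawn from gamma at the configured mean/SD).
#' @export
gen_cost_ledger <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cp <- config$cost_params
  fees <- with_substream(config, "cost_ledger", {
    if (cp$n_groups == 0) {
      numeric(0)
    } else if (cp$onboarding_fee_sd == 0) {
      rep(cp$onboarding_fee_mean, cp$n_groups)
    } else {
      pars <- gamma_from_moments(cp$onboarding_fee_mean, cp$onboarding_fee_sd)
      stats::rgamma(cp$n_groups, shape = pars[["shape"]], scale = pars[["scale"]])
    }
  })
  list(
    config = cost_config(
      onboarding_fee_mean = cp$onboarding_fee_mean,
      onboarding_fee_sd = cp$onboarding_fee_sd,
      n_groups = cp$n_groups,
      monthly_license = cp$monthly_license,
      horizon_months = cp$horizon_months,
      annual_discount_rate = cp$annual_discount_rate,
      discounting_enabled = cp$discounting_enabled
    ),
    onboarding_fees = round_half_up(fees, 2)
  )
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes every input the pipeline consumes — consult log, provider
#' registry, both survey files, fee schedule (CSV + JSON sidecar) and cost
#' configuration — in the dialects the package readers expect. Output is a
#' pure function of the configuration (including its seed).
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log <- gen_consult_log(config)
  registry <- gen_provider_registry(config)
  surveys <- gen_post_consult_surveys(log, config)
  experience <- gen_experience_surveys(config)
  schedule <- gen_fee_schedule(config)
  ledger <- gen_cost_ledger(config)

  paths <- c(
    consults = file.path(dir, "consults.csv"),
    providers = file.path(dir, "providers.csv"),
    post_consult = file.path(dir, "post_consult_surveys.csv"),
    experience = file.path(dir, "experience_surveys.csv"),
    fee_codes = file.path(dir, "fee_codes.csv"),
    fee_sidecar = file.path(dir, "fee_schedule.json"),
    cost_config = file.path(dir, "cost_config.json")
  )
  readr::write_csv(log, paths[["consults"]])
  readr::write_csv(registry, paths[["providers"]])
  readr::write_csv(
    dplyr::bind_rows(surveys$primary_care, surveys$specialist),
    paths[["post_consult"]]
  )
  readr::write_csv(experience, paths[["experience"]])
  write_fee_schedule(schedule, paths[["fee_codes"]], paths[["fee_sidecar"]])
  write_cost_config(ledger$config, paths[["cost_config"]],
    onboarding_fees = ledger$onboarding_fees
  )
  invisible(paths)
}
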