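#' Implementation and ongoing cost configuration
#'
#' The payer's cost ledger has two parts: a one-time onboarding fee per
#' specialist group, incurred at month zero, and an ongoing monthly platform
#' license. An annual opportunity cost of capital (default 7%) can be applied
#' as a monthly-compounded discount to the ongoing fees, reflecting the
#' returns foregone by committing funds to the platform.
#'
#' @param onboarding_fee_mean Onboarding fee per specialist group (dollars).
#' @param onboarding_fee_sd SD of the onboarding fee across groups (dollars);
#'   used by the synthetic generator and the PSA, not by the deterministic
#'   ledger.
#' @param n_groups Number of specialist groups onboarded.
#' @param monthly_license Monthly license fee (dollars).
#' @param horizon_months Number of months of ongoing fees accrued.
#' @param annual_discount_rate Annual opportunity cost of capital in
#'   `[0, 1)`; default `0.07`.
#' @param discounting_enabled Apply discounting to the monthly fees?
#' @return An object of class `cost_config` (a validated list).
#' @export
cost_config <- function(onboarding_fee_mean = 1265,
                        onboarding_fee_sd = 230,
                        n_groups = 0,
                        monthly_license = 10000,
                        horizon_months = 0,
                        annual_discount_rate = 0.07,
                        discounting_enabled = TRUE) {
  stopifnot(
    onboarding_fee_mean >= 0, onboarding_fee_sd >= 0,
    n_groups >= 0, monthly_license >= 0, horizon_months >= 0,
    annual_discount_rate >= 0, annual_discount_rate < 1
  )
  structure(
    list(
      onboarding_fee_mean = onboarding_fee_mean,
      onboarding_fee_sd = onboarding_fee_sd,
      n_groups = as.integer(n_groups),
      monthly_license = monthly_license,
      horizon_months = as.integer(horizon_months),
      annual_discount_rate = annual_discount_rate,
      discounting_enabled = isTRUE(discounting_enabled)
    ),
    class = "cost_config"
  )
}

#' Total implementation and ongoing cost with a monthly ledger
#'
#' Accrues `n_groups x onboarding_fee_mean` at month 0 (undiscounted) plus
#' the monthly license over the horizon. With discounting enabled, month `m`
#' is weighted by `(1 + r)^(-m / 12)` where `r` is the annual opportunity
#' cost of capital — monthly compounding of the annual rate.
#'
#' @param config A [cost_config()].
#' @return A list: `total` (dollars, rounded to cents), `ledger` (tibble of
#'   `month`, `nominal`, `discounted`), `discount_factor_monthly`.
#' @examples
#' cfg <- cost_config(n_groups = 3, horizon_months = 12, discounting_enabled = FALSE)
#' implementation_cost(cfg)$total # 123795
#' @export
implementation_cost <- function(config) {
  stopifnot(inherits(config, "cost_config"))
  d <- if (config$discounting_enabled) {
    (1 + config$annual_discount_rate)^(-1 / 12)
  } else {
    1
  }
  months <- seq_len(config$horizon_months)
  ledger <- tibble::tibble(
    month = c(0L, months),
    nominal = c(
      config$n_groups * config$onboarding_fee_mean,
      rep(config$monthly_license, config$horizon_months)
    ),
    discounted = c(
      config$n_groups * config$onboarding_fee_mean,
      config$monthly_license * d^months
    )
  )
  list(
    total = cents_to_dollars(as_cents(sum(ledger$discounted))),
    ledger = ledger,
    discount_factor_monthly = d
  )
}

#' Benefit-side inputs of the cost-benefit model
#'
#' @param consults_by_specialty Named integer vector: completed virtual
#'   consults per specialty over the economic window.
#' @param avoidance_proportion Proportion of consults that avoid an
#'   in-person referral, in `[0, 1]` (the survey-estimated rate, 0.84 in the
#'   reference case).
#' @param net_avoided_by_specialty Named numeric vector: net payer saving per
#'   averted referral for each specialty (see [net_avoided_cost()]). Every
#'   specialty with consults must have an entry.
#' @return An object of class `benefit_inputs`.
#' @export
benefit_inputs <- function(consults_by_specialty,
                           avoidance_proportion,
                           net_avoided_by_specialty) {
  stopifnot(
    avoidance_proportion >= 0, avoidance_proportion <= 1,
    !is.null(names(consults_by_specialty)),
    all(consults_by_specialty >= 0)
  )
  missing <- setdiff(
    names(consults_by_specialty), names(net_avoided_by_specialty)
  )
  if (length(missing)) {
    stop(
      "no net avoided cost configured for specialty(ies): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      consults_by_specialty = consults_by_specialty,
      avoidance_proportion = avoidance_proportion,
      net_avoided_by_specialty = net_avoided_by_specialty
    ),
    class = "benefit_inputs"
  )
}

#' Estimated in-person referrals avoided
#'
#' Per specialty, `consults x avoidance_proportion`, kept unrounded so no
#' rounding error compounds into the monetary totals; a round-half-up
#' integer of the grand total is returned for display alongside.
#'
#' @param inputs A [benefit_inputs()].
#' @return A list: `by_specialty` (tibble of `specialty`, `consults`,
#'   `avoided`), `total` (unrounded), `total_display` (rounded integer).
#' @examples
#' b <- benefit_inputs(c(all = 6072), 0.84, c(all = 76.35))
#' referrals_avoided(b)$total # 5100.48
#' @export
referrals_avoided <- function(inputs) {
  stopifnot(inherits(inputs, "benefit_inputs"))
  by_spec <- tibble::tibble(
    specialty = names(inputs$consults_by_specialty),
    consults = as.numeric(inputs$consults_by_specialty),
    avoided = as.numeric(inputs$consults_by_specialty) * inputs$avoidance_proportion
  )
  total <- sum(by_spec$avoided)
  list(
    by_specialty = by_spec,
    total = total,
    total_display = round_half_up(total)
  )
}

#' Total monetary benefit of averted referrals
#'
#' Sums, over specialties, the unrounded avoided-referral count times the
#' specialty's net avoided cost; rounded to cents only at the end.
#'
#' @param inputs A [benefit_inputs()].
#' @return Total benefit in dollars.
#' @examples
#' b <- benefit_inputs(c(all = 6072), 0.84, c(all = 76.35))
#' total_benefit(b) # 389421.65
#' @export
total_benefit <- function(inputs) {
  stopifnot(inherits(inputs, "benefit_inputs"))
  avoided <- referrals_avoided(inputs)$by_specialty
  per_avoided <- inputs$net_avoided_by_specialty[avoided$specialty]
  cents_to_dollars(as_cents(sum(avoided$avoided * per_avoided)))
}

#' Deterministic cost-benefit point metrics
#'
#' Net benefit `B - C`, benefit-cost ratio `B / C` and return on investment
#' `(B - C) / C`, computed exactly before any display rounding. These are
#' ratio-of-means point estimates; the probabilistic analysis
#' ([run_psa()]) reports the mean of per-draw ratios, which exceeds the
#' ratio of means when costs vary (Jensen's inequality).
#'
#' @param total_benefit,total_cost Dollars; `total_cost > 0` for the ratio
#'   metrics (with zero cost the ratios are returned as `NA` and the net
#'   benefit is still computed).
#' @return An object of class `cba_point`: list with `total_cost`,
#'   `total_benefit`, `net_benefit`, `bcr`, `roi`.
#' @examples
#' cba_point(389439, 145020)$net_benefit # 244419
#' @export
cba_point <- function(total_benefit, total_cost) {
  stopifnot(total_benefit >= 0, total_cost >= 0)
  net <- cents_to_dollars(as_cents(total_benefit) - as_cents(total_cost))
  if (total_cost > 0) {
    bcr <- total_benefit / total_cost
    roi <- (total_benefit - total_cost) / total_cost
  } else {
    bcr <- NA_real_
    roi <- NA_real_
  }
  structure(
    list(
      total_cost = total_cost,
      total_benefit = total_benefit,
      net_benefit = net,
      bcr = bcr,
      roi = roi
    ),
    class = "cba_point"
  )
}

#' @export
print.cba_point <- function(x, ...) {
  cat("<cba_point>\n")
  cat("  total cost:    $", fmt_money(x$total_cost), "\n", sep = "")
  cat("  total benefit: $", fmt_money(x$total_benefit), "\n", sep = "")
  cat("  net benefit:   $", fmt_money(x$net_benefit), "\n", sep = "")
  cat("  BCR: ", formatC(x$bcr, format = "f", digits = 1),
    "   ROI: ", formatC(x$roi, format = "f", digits = 1), "\n",
    sep = ""
  )
  invisible(x)
}
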