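#' Run the full evaluation pipeline
#'
#' Orchestrates every stage against a dataset directory (as written by
#' [generate_dataset()], or real data in the same dialect): utilization
#' tallies, survey summaries, fee-model costing, deterministic cost-benefit
#' analysis, probabilistic sensitivity analysis and the one-way
#' cost-multiplier scenario. Writes the three report tables as CSV, a
#' metrics JSON holding every computed number, and a run log recording the
#' seed, configuration hash and package version. Any stage failure aborts
#' with a message tagged by the stage name.
#'
#' The PSA here is structural: the avoidance proportion is drawn from a beta
#' distribution calibrated to its binomial standard error (the denominator
#' is known), while the benefit-at-full-avoidance and total-cost quantities
#' are drawn from gamma distributions under the 10%-of-mean SD rule (their
#' variability is not otherwise identified from one dataset).
#'
#' @param data_dir Directory with the input files (`consults.csv`,
#'   `providers.csv`, `post_consult_surveys.csv`, `experience_surveys.csv`,
#'   `fee_codes.csv`, `fee_schedule.json`, `cost_config.json`).
#' @param outdir Output directory for the report bundle.
#' @param utilization_window,economics_window Length-2 vectors of ISO dates;
#'   defaults follow the evaluation's two reporting windows.
#' @param min_consults Floor defining the "top" specialties (default 100).
#' @param n_draws PSA iterations (default 1000).
#' @param seed Master seed for the PSA.
#' @param cost_multiplier One-way scenario multiplier (default 2).
#' @return Invisibly, the metrics list (also written to `metrics.json`).
#' @export
run_pipeline <- function(data_dir,
                         outdir,
                         utilization_window = c("2022-05-01", "2024-01-31"),
                         economics_window = c("2022-05-01", "2023-11-30"),
                         min_consults = 100,
                         n_draws = 1000,
                         seed = 1L,
                         cost_multiplier = 2) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("read", {
    list(
      log = read_consult_log(file.path(data_dir, "consults.csv")),
      registry = read_provider_registry(file.path(data_dir, "providers.csv")),
      post = read_post_consult_surveys(
        file.path(data_dir, "post_consult_surveys.csv")
      ),
      experience = read_experience_surveys(
        file.path(data_dir, "experience_surveys.csv")
      ),
      schedule = read_fee_schedule(
        file.path(data_dir, "fee_codes.csv"),
        file.path(data_dir, "fee_schedule.json")
      ),
      cost = read_cost_config(file.path(data_dir, "cost_config.json"))
    )
  })

  util <- stage("utilization", {
    windowed <- filter_window(
      inputs$log, utilization_window[1], utilization_window[2]
    )
    tallies <- tally_by_specialty(windowed)
    list(
      tallies = tallies,
      top = top_specialties(tallies, min_consults),
      mix = provider_mix(inputs$registry),
      n_consults = nrow(windowed)
    )
  })

  survey <- stage("survey", {
    pcp <- dplyr::filter(inputs$post, .data$responder_role == "primary_care")
    spec <- dplyr::filter(inputs$post, .data$responder_role == "specialist")
    avoid_known <- pcp$avoided_referral[pcp$avoided_referral %in% c("yes", "no")]
    list(
      avoidance = proportion_estimate(avoid_known == "yes"),
      pcp_satisfaction = top_two_box(pcp$satisfaction),
      specialist_satisfaction = top_two_box(spec$satisfaction),
      necessity = necessity_breakdown(spec$necessity),
      non_avoided = non_avoided_followup(pcp),
      usage = usage_band_distribution(inputs$experience),
      continue_rate = top_two_box(inputs$experience$intend_to_continue),
      recommend_rate = top_two_box(inputs$experience$would_recommend)
    )
  })

  fees <- stage("fee_model", {
    econ_log <- filter_window(
      inputs$log, economics_window[1], economics_window[2]
    )
    econ_tallies <- tally_by_specialty(econ_log)
    net <- purrr::map_dfr(
      econ_tallies$specialty, net_avoided_cost,
      schedule = inputs$schedule
    )
    list(
      econ_tallies = econ_tallies,
      net_avoided = net,
      encounter_cost = vh_encounter_cost(inputs$schedule)
    )
  })

  cba <- stage("cba", {
    avoidance_hat <- survey$avoidance$proportion
    inputs_b <- benefit_inputs(
      consults_by_specialty = stats::setNames(
        fees$econ_tallies$count, fees$econ_tallies$specialty
      ),
      avoidance_proportion = avoidance_hat,
      net_avoided_by_specialty = stats::setNames(
        fees$net_avoided$net_avoided, fees$net_avoided$specialty
      )
    )
    cost <- implementation_cost(inputs$cost$config)
    b <- total_benefit(inputs_b)
    list(
      benefit_inputs = inputs_b,
      avoided = referrals_avoided(inputs_b),
      cost = cost,
      point = cba_point(b, cost$total)
    )
  })

  psa <- stage("psa", {
    avoidance_hat <- survey$avoidance$proportion
    # benefit at 100% avoidance; per-draw benefit = avoidance x this value
    value_at_full_avoidance <- cba$point$total_benefit / avoidance_hat
    spec <- psa_spec(
      quantities = list(
        avoidance = dist_spec(
          "beta", avoidance_hat, survey$avoidance$se, "stated_sd"
        ),
        value_at_full_avoidance = dist_spec(
          "gamma", value_at_full_avoidance,
          0.1 * value_at_full_avoidance, "ten_percent_rule"
        ),
        total_cost = dist_spec(
          "gamma", cba$cost$total, 0.1 * cba$cost$total, "ten_percent_rule"
        )
      ),
      n_draws = n_draws,
      seed = seed
    )
    model <- function(draws) {
      tibble::tibble(
        total_benefit = draws$avoidance * draws$value_at_full_avoidance,
        total_cost = draws$total_cost
      )
    }
    list(
      reference = run_psa(spec, model = model),
      scenario = one_way_scenario(spec, cost_multiplier, model = model)
    )
  })

  metrics <- stage("metrics", {
    s <- function(x) as.list(x) # tibble row -> named list for JSON
    list(
      meta = list(
        seed = as.integer(seed),
        n_draws = as.integer(n_draws),
        cost_multiplier = cost_multiplier,
        package_version = as.character(utils::packageVersion("econsultCBA"))
      ),
      table1 = list(
        by_role = lapply(seq_len(nrow(util$mix$by_role)), function(i) s(util$mix$by_role[i, ])),
        total = util$mix$total
      ),
      table2 = lapply(seq_len(nrow(util$tallies)), function(i) s(util$tallies[i, ])),
      top_specialties = list(
        min_consults = min_consults,
        n = nrow(util$top$subset),
        combined_share = util$top$combined_share
      ),
      n_consults = util$n_consults,
      survey = list(
        avoidance = s(survey$avoidance),
        pcp_satisfaction = s(survey$pcp_satisfaction),
        specialist_satisfaction = s(survey$specialist_satisfaction),
        necessity = list(
          n = survey$necessity$n,
          n_excluded = survey$necessity$n_excluded,
          shares = stats::setNames(
            as.list(survey$necessity$shares$share),
            survey$necessity$shares$group
          )
        ),
        non_avoided = lapply(
          seq_len(nrow(survey$non_avoided)),
          function(i) s(survey$non_avoided[i, ])
        ),
        usage_bands = lapply(
          seq_len(nrow(survey$usage)), function(i) s(survey$usage[i, ])
        ),
        continue_rate = s(survey$continue_rate),
        recommend_rate = s(survey$recommend_rate)
      ),
      economics = list(
        encounter_cost = fees$encounter_cost,
        referrals_avoided = cba$avoided$total,
        referrals_avoided_display = cba$avoided$total_display,
        point = unclass(cba$point)[c(
          "total_cost", "total_benefit", "net_benefit", "bcr", "roi"
        )],
        psa = list(
          reference = lapply(
            seq_len(nrow(psa$reference$summary)),
            function(i) s(psa$reference$summary[i, ])
          ),
          scenario = lapply(
            seq_len(nrow(psa$scenario$summary)),
            function(i) s(psa$scenario$summary[i, ])
          )
        )
      )
    )
  })

  stage("write", {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(render_table(metrics, 1), file.path(outdir, "table1.csv"))
    readr::write_csv(render_table(metrics, 2), file.path(outdir, "table2.csv"))
    readr::write_csv(render_table(metrics, 3), file.path(outdir, "table3.csv"))
    jsonlite::write_json(
      metrics, file.path(outdir, "metrics.json"),
      auto_unbox = TRUE, digits = NA
    )
    writeLines(
      c(
        paste0("timestamp: ", format(Sys.time(), usetz = TRUE)),
        paste0("seed: ", seed),
        paste0("config_hash: ", rlang::hash(list(
          utilization_window, economics_window, min_consults,
          n_draws, seed, cost_multiplier
        ))),
        paste0("package_version: ", metrics$meta$package_version),
        if (any(cba$benefit_inputs$net_avoided_by_specialty < 0)) {
          "warning: negative net avoided cost for at least one specialty"
        }
      ),
      file.path(outdir, "run_log.txt")
    )
  })

  invisible(metrics)
}

#' Render a report table from computed metrics
#'
#' Formats one of the three report tables — provider mix, consultations by
#' specialty, or the cost-benefit summary — purely from the metrics list
#' produced by [run_pipeline()]; nothing is recomputed here, only rounded
#' for display (Table 1: whole percent; Table 2: one-decimal percent;
#' Table 3: whole dollars, one-decimal ratios, percentile CIs).
#'
#' @param metrics Metrics list from [run_pipeline()] (or re-read from
#'   `metrics.json`).
#' @param table_id 1, 2 or 3.
#' @return A tibble of display-formatted cells.
#' @export
render_table <- function(metrics, table_id) {
  need <- function(x, field) {
    if (is.null(x)) stop("metrics are missing field: ", field, call. = FALSE)
    x
  }
  if (table_id == 1) {
    rows <- need(metrics$table1$by_role, "table1.by_role")
    tibble::tibble(
      healthcare_professional = c(
        vapply(rows, function(r) r$role, character(1)), "total"
      ),
      count = c(
        vapply(rows, function(r) as.numeric(r$count), numeric(1)),
        as.numeric(need(metrics$table1$total, "table1.total"))
      ),
      share = c(
        vapply(rows, function(r) {
          if (is.null(r$share_pct) || is.na(r$share_pct)) {
            ""
          } else {
            paste0(r$share_pct, "%")
          }
        }, character(1)),
        "100%"
      )
    )
  } else if (table_id == 2) {
    rows <- metrics$table2
    if (!length(rows)) {
      return(tibble::tibble(
        specialty = character(), share = character(), n_consults = numeric()
      ))
    }
    tibble::tibble(
      specialty = vapply(rows, function(r) r$specialty, character(1)),
      share = vapply(
        rows, function(r) fmt_pct(as.numeric(r$share), 1), character(1)
      ),
      n_consults = vapply(rows, function(r) as.numeric(r$count), numeric(1))
    )
  } else if (table_id == 3) {
    point <- need(metrics$economics$point, "economics.point")
    fmt_psa <- function(rows) {
      m <- stats::setNames(rows, vapply(rows, function(r) r$metric, character(1)))
      money <- function(r) {
        paste0(
          "$", fmt_money(as.numeric(r$mean)),
          " ($", fmt_money(as.numeric(r$lo)),
          " to $", fmt_money(as.numeric(r$hi)), ")"
        )
      }
      ratio <- function(r) {
        paste0(
          formatC(as.numeric(r$mean), format = "f", digits = 1),
          " (", formatC(as.numeric(r$lo), format = "f", digits = 1),
          " to ", formatC(as.numeric(r$hi), format = "f", digits = 1), ")"
        )
      }
      c(
        money(m$total_cost), money(m$total_benefit),
        ratio(m$bcr), money(m$net_benefit), ratio(m$roi)
      )
    }
    tibble::tibble(
      indicator = c(
        "Implementation and ongoing costs",
        "In-person referral costs avoided",
        "Benefit-cost ratio",
        "Cumulative net benefits",
        "Return on investment (ROI)"
      ),
      point_estimate = c(
        paste0("$", fmt_money(as.numeric(point$total_cost))),
        paste0("$", fmt_money(as.numeric(point$total_benefit))),
        formatC(as.numeric(point$bcr), format = "f", digits = 1),
        paste0("$", fmt_money(as.numeric(point$net_benefit))),
        formatC(as.numeric(point$roi), format = "f", digits = 1)
      ),
      reference_case = fmt_psa(
        need(metrics$economics$psa$reference, "economics.psa.reference")
      ),
      cost_scenario = fmt_psa(
        need(metrics$economics$psa$scenario, "economics.psa.scenario")
      )
    )
  } else {
    stop("`table_id` must be 1, 2 or 3", call. = FALSE)
  }
}
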