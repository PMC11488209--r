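#' Read pipeline input files
#'
#' Readers for the tabular inputs of the evaluation: the consult log, the
#' provider registry and the two survey files. All are plain CSV with
#' ISO-8601 dates and lowercase enumeration tokens; columns are validated on
#' read so downstream stages can assume the schema.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the validated columns.
#' @name readers
NULL

check_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(
      what, " is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' @rdname readers
#' @export
read_consult_log <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    consult_id = readr::col_character(),
    specialty = readr::col_character(),
    date = readr::col_date(),
    completed = readr::col_logical(),
    requesting_role = readr::col_character()
  ))
  df <- check_columns(df, c("consult_id", "specialty", "date", "completed"), "consult log")
  if (anyDuplicated(df$consult_id) > 0) {
    stop("consult log has duplicated consult_id values", call. = FALSE)
  }
  df
}

#' @rdname readers
#' @export
read_provider_registry <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    provider_id = readr::col_character(),
    role = readr::col_character(),
    join_date = readr::col_date()
  ))
  df <- check_columns(df, c("provider_id", "role"), "provider registry")
  if (anyDuplicated(df$provider_id) > 0) {
    stop("provider registry has duplicated provider_id values", call. = FALSE)
  }
  df
}

#' @rdname readers
#' @export
read_post_consult_surveys <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    consult_id = readr::col_character(),
    responder_role = readr::col_character(),
    satisfaction = readr::col_integer(),
    .default = readr::col_character()
  ))
  check_columns(
    df,
    c(
      "consult_id", "responder_role", "satisfaction", "avoided_referral",
      "intended_to_avoid", "improved_referral_quality",
      "improved_interim_care", "necessity"
    ),
    "post-consultation survey file"
  )
}

#' @rdname readers
#' @export
read_experience_surveys <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    responder_role = readr::col_character(),
    usage_band = readr::col_character(),
    .default = readr::col_integer()
  ))
  check_columns(
    df,
    c("responder_role", "usage_band", "overall_satisfaction",
      "intend_to_continue", "would_recommend"),
    "experience survey file"
  )
}

#' Read / write the cost configuration
#'
#' The cost configuration travels as JSON: the [cost_config()] fields plus,
#' optionally, the realized per-group onboarding fees of a synthetic ledger.
#'
#' @param path JSON file path.
#' @param config A [cost_config()] (writer).
#' @param onboarding_fees Optional numeric vector of realized fees (writer).
#' @return `read_cost_config()`: list with `config` (a `cost_config`) and
#'   `onboarding_fees` (possibly `NULL`). `write_cost_config()`: the path,
#'   invisibly.
#' @export
read_cost_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- cost_config(
    onboarding_fee_mean = raw$onboarding_fee_mean,
    onboarding_fee_sd = raw$onboarding_fee_sd,
    n_groups = raw$n_groups,
    monthly_license = raw$monthly_license,
    horizon_months = raw$horizon_months,
    annual_discount_rate = raw$annual_discount_rate,
    discounting_enabled = raw$discounting_enabled
  )
  list(config = cfg, onboarding_fees = raw$onboarding_fees)
}

#' @rdname read_cost_config
#' @export
write_cost_config <- function(config, path, onboarding_fees = NULL) {
  stopifnot(inherits(config, "cost_config"))
  out <- unclass(config)
  if (!is.null(onboarding_fees)) out$onboarding_fees <- onboarding_fees
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
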