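#' Construct a fee schedule
#'
#' A fee schedule bundles the provincial billing inputs of the model: the
#' phone-consult fee codes with their Medical Service Unit (MSU) weights, the
#' provincial rate paid per MSU, and the comprehensive in-person consultation
#' fee billed by each specialty. Payment for a coded service is
#' `MSU x rate_per_msu`; the comprehensive fee is what the payer avoids when a
#' virtual consult replaces an in-person referral. All amounts are 2022
#' Canadian dollars.
#'
#' @param codes A data frame with columns `code_id`, `description`,
#'   `msu_units` (one row per fee code; `code_id` unique, `msu_units >= 0`).
#' @param rate_per_msu Positive dollar rate paid per MSU.
#' @param comprehensive_fee Named numeric vector mapping specialty to its
#'   comprehensive consultation fee in dollars (all `>= 0`).
#' @return An object of class `fee_schedule`.
#' @seealso [default_fee_schedule()], [vh_encounter_cost()],
#'   [net_avoided_cost()]
#' @examples
#' sched <- default_fee_schedule(comprehensive_fee = c(cardiology = 174.17))
#' vh_encounter_cost(sched)
#' @export
fee_schedule <- function(codes, rate_per_msu, comprehensive_fee = numeric()) {
  codes <- tibble::as_tibble(codes)
  stopifnot(all(c("code_id", "description", "msu_units") %in% names(codes)))
  if (any(!nzchar(codes$code_id)) || anyDuplicated(codes$code_id) > 0) {
    stop("fee codes must have non-empty, unique `code_id`s", call. = FALSE)
  }
  if (any(codes$msu_units < 0)) {
    stop("`msu_units` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(rate_per_msu) || length(rate_per_msu) != 1 || rate_per_msu < 0) {
    stop("`rate_per_msu` must be a single non-negative number", call. = FALSE)
  }
  fee <- unlist(comprehensive_fee)
  if (length(fee) && (is.null(names(fee)) || any(!nzchar(names(fee))))) {
    stop("`comprehensive_fee` must be a named specialty -> dollars mapping",
      call. = FALSE
    )
  }
  if (any(fee < 0)) stop("comprehensive fees must be non-negative", call. = FALSE)
  structure(
    list(
      codes = codes,
      rate_per_msu = rate_per_msu,
      comprehensive_fee = fee,
      currency = "2022 CAD"
    ),
    class = "fee_schedule"
  )
}

# Fee-code ids of the two billed legs of one virtual encounter:
# requesting-physician call and specialist call-back.
VH_CODE_REQUESTING <- "CONS 03.09 L"
VH_CODE_SPECIALIST <- "VIST 03.09 K"

#' Default phone-consult fee schedule
#'
#' The bundled schedule carries the two Nova Scotia phone-consult codes that
#' make up a virtual encounter — the family-physician-to-specialist call
#' (`CONS 03.09 L`, 11.5 MSU) and the specialist call-back
#' (`VIST 03.09 K`, 25 MSU) — at the provincial rate of $2.68 per MSU.
#' Comprehensive consultation fees are specialty-specific inputs with no
#' published default, so they must be supplied (the synthetic generator
#' draws them; see [gen_fee_schedule()]).
#'
#' @param comprehensive_fee Named numeric vector of specialty fees (dollars).
#' @param rate_per_msu Rate per MSU in dollars; default `2.68`.
#' @return A `fee_schedule`.
#' @export
default_fee_schedule <- function(comprehensive_fee = numeric(),
                                 rate_per_msu = 2.68) {
  fee_schedule(
    codes = tibble::tibble(
      code_id = c(VH_CODE_REQUESTING, VH_CODE_SPECIALIST),
      description = c(
        "Family physician-to-specialist phone call",
        "Specialist-to-physician (or NP) phone call"
      ),
      msu_units = c(11.5, 25)
    ),
    rate_per_msu = rate_per_msu,
    comprehensive_fee = comprehensive_fee
  )
}

#' @export
print.fee_schedule <- function(x, ...) {
  cat("<fee_schedule> ", nrow(x$codes), " code(s) at $",
    format(x$rate_per_msu), "/MSU, ",
    length(x$comprehensive_fee), " specialty fee(s), ", x$currency, "\n",
    sep = ""
  )
  print(x$codes, ...)
  invisible(x)
}

#' Cost of a coded service from its MSU weight
#'
#' Payment under the fee-for-service schedule: `msu_units x rate_per_msu`,
#' rounded half-up to the cent.
#'
#' @param msu_units Non-negative MSU weight(s) of the service.
#' @param rate_per_msu Non-negative dollar rate per MSU.
#' @return Dollar cost(s), rounded to cents.
#' @examples
#' msu_cost(11.5, 2.68) # 30.82
#' msu_cost(25, 2.68) # 67.00
#' @export
msu_cost <- function(msu_units, rate_per_msu) {
  if (any(msu_units < 0) || any(rate_per_msu < 0)) {
    stop("`msu_units` and `rate_per_msu` must be non-negative", call. = FALSE)
  }
  cents_to_dollars(as_cents(msu_units * rate_per_msu))
}

#' Payer cost of one virtual encounter
#'
#' One virtual consultation bills both phone-consult legs: the requesting
#' physician's call and the specialist's call-back. This cost is paid whether
#' or not the consult avoids a referral, so it is the first component of the
#' avoided-cost calculation.
#'
#' @param schedule A [fee_schedule()] containing both phone-consult codes.
#' @return Dollar cost of one encounter (sum of the two coded services).
#' @examples
#' vh_encounter_cost(default_fee_schedule()) # 97.82
#' @export
vh_encounter_cost <- function(schedule) {
  stopifnot(inherits(schedule, "fee_schedule"))
  needed <- c(VH_CODE_REQUESTING, VH_CODE_SPECIALIST)
  missing <- setdiff(needed, schedule$codes$code_id)
  if (length(missing)) {
    stop(
      "fee schedule is missing phone-consult code(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  rows <- schedule$codes[match(needed, schedule$codes$code_id), ]
  sum(msu_cost(rows$msu_units, schedule$rate_per_msu))
}

#' Net payer cost avoided per averted in-person referral
#'
#' The avoided cost has two components: the virtual encounter cost (paid in
#' either scenario) and the specialty's comprehensive in-person consultation
#' fee (paid only if the referral happens). The net saving per averted
#' referral is their difference. A specialty whose comprehensive fee is below
#' the encounter cost yields a negative net saving; that is allowed but
#' flagged with a warning.
#'
#' @param specialty Specialty name present in the schedule's
#'   `comprehensive_fee` mapping.
#' @param schedule A [fee_schedule()].
#' @return A one-row tibble with columns `specialty`, `component_one`
#'   (encounter cost), `component_two` (comprehensive fee), `net_avoided`,
#'   and `flagged_negative`.
#' @examples
#' sched <- default_fee_schedule(comprehensive_fee = c(cardiology = 174.17))
#' net_avoided_cost("cardiology", sched)$net_avoided # 76.35
#' @export
net_avoided_cost <- function(specialty, schedule) {
  stopifnot(inherits(schedule, "fee_schedule"), length(specialty) == 1)
  if (!specialty %in% names(schedule$comprehensive_fee)) {
    stop("no comprehensive consultation fee for specialty: ", specialty,
      call. = FALSE
    )
  }
  one_c <- as_cents(vh_encounter_cost(schedule))
  two_c <- as_cents(schedule$comprehensive_fee[[specialty]])
  net_c <- two_c - one_c
  if (net_c < 0) {
    warning(
      "net avoided cost is negative for '", specialty,
      "': comprehensive fee below the encounter cost",
      call. = FALSE
    )
  }
  tibble::tibble(
    specialty = specialty,
    component_one = cents_to_dollars(one_c),
    component_two = cents_to_dollars(two_c),
    net_avoided = cents_to_dollars(net_c),
    flagged_negative = net_c < 0
  )
}

#' Read / write a fee schedule
#'
#' The on-disk form is a CSV of codes (`code_id`, `description`, `msu_units`)
#' plus a JSON sidecar holding `rate_per_msu` and the specialty-to-fee
#' mapping, so every money value round-trips as fixed-decimal text.
#'
#' @param codes_csv Path to the fee-code CSV.
#' @param sidecar_json Path to the JSON sidecar.
#' @param schedule A `fee_schedule` (for the writer).
#' @return `read_fee_schedule()` returns a `fee_schedule`;
#'   `write_fee_schedule()` returns the paths invisibly.
#' @export
read_fee_schedule <- function(codes_csv, sidecar_json) {
  codes <- readr::read_csv(codes_csv,
    col_types = readr::cols(
      code_id = readr::col_character(),
      description = readr::col_character(),
      msu_units = readr::col_double()
    )
  )
  side <- jsonlite::read_json(sidecar_json, simplifyVector = TRUE)
  fee <- unlist(side$comprehensive_fee)
  fee <- stats::setNames(as.numeric(fee), names(fee)) # stored as 2-dp text
  fee_schedule(
    codes = codes,
    rate_per_msu = as.numeric(side$rate_per_msu),
    comprehensive_fee = fee
  )
}

#' @rdname read_fee_schedule
#' @export
write_fee_schedule <- function(schedule, codes_csv, sidecar_json) {
  stopifnot(inherits(schedule, "fee_schedule"))
  readr::write_csv(schedule$codes, codes_csv)
  jsonlite::write_json(
    list(
      rate_per_msu = schedule$rate_per_msu,
      # fixed 2-decimal text keeps cents exact through the round trip
      comprehensive_fee = as.list(formatC(
        round_half_up(schedule$comprehensive_fee, 2),
        format = "f", digits = 2
      ))
    ),
    sidecar_json,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(codes_csv, sidecar_json))
}
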