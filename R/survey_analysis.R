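#' Proportion with binomial uncertainty
#'
#' Descriptive estimate of a yes/no survey proportion: numerator,
#' denominator, point proportion and the binomial standard error
#' `sqrt(p (1 - p) / n)`. Missing values are dropped from the denominator
#' (respondents who skipped the item are not part of the question's base),
#' matching how survey reports quote per-question denominators.
#'
#' @param x Logical vector of responses (`NA` allowed and excluded).
#' @return A one-row tibble: `numerator`, `denominator`, `proportion`, `se`.
#' @examples
#' proportion_estimate(rep(c(TRUE, FALSE), c(511, 97)))
#' @export
proportion_estimate <- function(x) {
  stopifnot(is.logical(x))
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) stop("no non-missing responses to summarise", call. = FALSE)
  k <- sum(x)
  p <- k / n
  tibble::tibble(
    numerator = k,
    denominator = n,
    proportion = p,
    se = sqrt(p * (1 - p) / n)
  )
}

likert_levels <- 1:5

#' Canonical response scales
#'
#' `necessity_scale` is the four-level referral-necessity coding;
#' `usage_bands` the ordered platform-usage bands of the provider-experience
#' survey. Stored values use these lowercase tokens.
#'
#' @format Character vectors.
#' @export
necessity_scale <- c(
  "unnecessary", "somewhat_unnecessary", "somewhat_necessary", "necessary"
)

#' @rdname necessity_scale
#' @format NULL
#' @export
usage_bands <- c("1-5", "6-10", "10-20", ">20")

#' Top-two-box rate of a 5-point Likert item
#'
#' The paired favourable categories of a 5-point scale ("satisfied or very
#' satisfied", "agree or strongly agree") are operationalised as responses
#' of 4 or 5.
#'
#' @param values Integer-valued responses in `1..5` (`NA` excluded).
#' @return A one-row tibble as in [proportion_estimate()].
#' @examples
#' top_two_box(c(5, 4, 3, 2, 1)) # proportion 0.4
#' @export
top_two_box <- function(values) {
  keep <- values[!is.na(values)]
  bad <- which(!keep %in% likert_levels)
  if (length(bad)) {
    stop(
      "Likert value out of range 1..5 at position(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  proportion_estimate(keep >= 4)
}

#' Referral-necessity breakdown
#'
#' Specialists rate, for each virtual consult, how necessary a direct
#' in-person referral of the same patient would have been, on a four-level
#' scale (an `"unsure"` token is tolerated for respondents who answered but
#' did not commit to a level). The report groups the two unfavourable levels
#' ("unnecessary" or "somewhat unnecessary") against the two favourable
#' ones; the residual share is the `"unsure"` fraction, so the three grouped
#' shares sum to one before rounding. Truly absent responses (`NA`) are
#' excluded from the denominator and their count reported.
#'
#' @param responses Character vector on the scale `unnecessary`,
#'   `somewhat_unnecessary`, `somewhat_necessary`, `necessary`, plus
#'   optionally `unsure`; `NA` excluded and counted.
#' @return A list: `n` (non-missing responses), `n_excluded`, and a tibble
#'   `shares` with rows `unnecessary_group`, `necessary_group`, `residual`.
#' @examples
#' necessity_breakdown(rep(necessity_scale, 5))$shares
#' @export
necessity_breakdown <- function(responses) {
  n_excluded <- sum(is.na(responses))
  x <- responses[!is.na(responses)]
  if (!length(x)) stop("no necessity responses to summarise", call. = FALSE)
  if (!all(x %in% c(necessity_scale, "unsure"))) {
    stop("necessity responses must be on the 4-level scale (or 'unsure')",
      call. = FALSE
    )
  }
  n <- length(x)
  unnec <- sum(x %in% necessity_scale[1:2]) / n
  nec <- sum(x %in% necessity_scale[3:4]) / n
  list(
    n = n,
    n_excluded = n_excluded,
    shares = tibble::tibble(
      group = c("unnecessary_group", "necessary_group", "residual"),
      share = c(unnec, nec, 1 - unnec - nec)
    )
  )
}

#' Distribution of respondents across usage bands
#'
#' Provider-experience respondents report how many consultations they have
#' done on the platform, in four ordered bands. Counts and whole-percent
#' shares are returned in fixed band order regardless of the data.
#'
#' @param responses Data frame with a `usage_band` column on the bands
#'   `1-5`, `6-10`, `10-20`, `>20`.
#' @return A tibble with `usage_band`, `count`, `share`, `share_pct`
#'   (round-half-up whole percent).
#' @examples
#' x <- tibble::tibble(usage_band = rep(usage_bands, c(34, 20, 18, 17)))
#' usage_band_distribution(x)$share_pct # 38 22 20 19
#' @export
usage_band_distribution <- function(responses) {
  responses <- tibble::as_tibble(responses)
  if (nrow(responses) && !all(responses$usage_band %in% usage_bands)) {
    stop("usage_band values must be one of: ",
      paste(usage_bands, collapse = ", "),
      call. = FALSE
    )
  }
  counts <- unname(vapply(
    usage_bands, function(b) sum(responses$usage_band == b), integer(1)
  ))
  total <- sum(counts)
  tibble::tibble(
    usage_band = usage_bands,
    count = counts,
    share = if (total > 0) counts / total else rep(NA_real_, 4),
    share_pct = if (total > 0) round_half_up(100 * counts / total) else rep(NA_real_, 4)
  )
}

#' Follow-up on consults that did not avoid a referral
#'
#' Among primary-care post-consultation responses whose consult did *not*
#' avoid an in-person referral, three follow-up questions are summarised:
#' whether the consult was never intended to avoid a referral, whether it
#' improved the quality of the resulting referral, and whether it improved
#' the patient's interim care.
#'
#' @param responses Post-consultation responses (data frame) with columns
#'   `avoided_referral`, `intended_to_avoid`, `improved_referral_quality`,
#'   `improved_interim_care`, each coded `"yes"`/`"no"` (tri-state with
#'   `"not_applicable"` treated as missing).
#' @return A tibble with one row per item (`not_intended_to_avoid`,
#'   `improved_referral_quality`, `improved_interim_care`) and the
#'   [proportion_estimate()] columns.
#' @export
non_avoided_followup <- function(responses) {
  responses <- tibble::as_tibble(responses)
  sub <- dplyr::filter(responses, .data$avoided_referral == "no")
  if (nrow(sub) == 0) {
    stop("no responses with avoided_referral == 'no'", call. = FALSE)
  }
  as_yes <- function(v) {
    out <- rep(NA, length(v))
    out[v == "yes"] <- TRUE
    out[v == "no"] <- FALSE
    out
  }
  items <- list(
    not_intended_to_avoid = !as_yes(sub$intended_to_avoid),
    improved_referral_quality = as_yes(sub$improved_referral_quality),
    improved_interim_care = as_yes(sub$improved_interim_care)
  )
  purrr::imap_dfr(items, function(v, nm) {
    dplyr::mutate(proportion_estimate(v), item = nm, .before = 1)
  })
}
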