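#' Tally completed consultations by specialty
#'
#' Produces the per-specialty consultation counts and shares behind the
#' utilization table: one row per distinct specialty, ordered by descending
#' count with alphabetical tie-breaks so reports are deterministic.
#'
#' @param log Consult log: a data frame with at least `specialty` and
#'   (if `completed_only`) a logical `completed` column.
#' @param completed_only If `TRUE` (default), only completed consults count.
#' @return A tibble with columns `specialty`, `count`, `share`
#'   (`count / total`, unrounded). Empty log gives a zero-row tibble.
#' @examples
#' log <- tibble::tibble(
#'   specialty = c("a", "a", "b"),
#'   completed = TRUE
#' )
#' tally_by_specialty(log)
#' @export
tally_by_specialty <- function(log, completed_only = TRUE) {
  log <- tibble::as_tibble(log)
  if (completed_only && "completed" %in% names(log)) {
    log <- dplyr::filter(log, .data$completed)
  }
  if (nrow(log) == 0) {
    return(tibble::tibble(
      specialty = character(), count = integer(), share = numeric()
    ))
  }
  log |>
    dplyr::count(.data$specialty, name = "count") |>
    dplyr::mutate(share = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$specialty)
}

#' Select the most active specialties
#'
#' The "top" specialties of the utilization report are those with at least
#' `min_consults` completed consultations (the published convention uses a
#' floor of 100). The combined share is measured against the grand total of
#' all tallied consults, not just the subset.
#'
#' @param tallies Output of [tally_by_specialty()].
#' @param min_consults Minimum consult count for inclusion (`>= 1`).
#' @return A list with `subset` (the qualifying tallies, same ordering) and
#'   `combined_share` (subset consults / all consults; 0 for an empty subset).
#' @examples
#' t <- tibble::tibble(specialty = c("a", "b"), count = c(150L, 50L))
#' top_specialties(t, 100)$combined_share # 0.75
#' @export
top_specialties <- function(tallies, min_consults) {
  stopifnot(min_consults >= 1)
  tallies <- tibble::as_tibble(tallies)
  total <- sum(tallies$count)
  subset <- dplyr::filter(tallies, .data$count >= min_consults)
  list(
    subset = subset,
    combined_share = if (total > 0) sum(subset$count) / total else 0
  )
}

#' Provider mix on the platform
#'
#' Counts registered providers by role (primary care vs specialist) and
#' reports whole-percent shares, the display convention of the provider
#' table.
#'
#' @param registry Provider registry: data frame with a `role` column whose
#'   values are `"primary_care"` or `"specialist"`.
#' @return A list with `by_role` (tibble of `role`, `count`, `share`,
#'   `share_pct` rounded half-up to whole percent) and `total`. An empty
#'   registry yields zero counts with `NA` shares.
#' @examples
#' reg <- tibble::tibble(role = c(rep("primary_care", 873), rep("specialist", 143)))
#' provider_mix(reg)$by_role$share_pct # 86, 14
#' @export
provider_mix <- function(registry) {
  registry <- tibble::as_tibble(registry)
  roles <- c("primary_care", "specialist")
  if (nrow(registry) && !all(registry$role %in% roles)) {
    bad <- setdiff(unique(registry$role), roles)
    stop("unknown provider role(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  counts <- unname(vapply(roles, function(r) sum(registry$role == r), integer(1)))
  total <- sum(counts)
  by_role <- tibble::tibble(
    role = roles,
    count = counts,
    share = if (total > 0) counts / total else rep(NA_real_, 2),
    share_pct = if (total > 0) round_half_up(100 * counts / total) else rep(NA_real_, 2)
  )
  list(by_role = by_role, total = total)
}

#' Restrict a consult log to a study window
#'
#' The evaluation uses two reporting windows (a longer one for utilization
#' and a shorter one for the economic analysis), so windowing is a filter
#' applied to the log rather than a property of it.
#'
#' @param log Consult log with a `date` column (`Date` or ISO-8601 text).
#' @param start,end Inclusive window bounds (`Date` or ISO-8601 text).
#' @return The filtered log.
#' @export
filter_window <- function(log, start, end) {
  log <- tibble::as_tibble(log)
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start) {
    stop("invalid study window", call. = FALSE)
  }
  dplyr::filter(log, as.Date(.data$date) >= start, as.Date(.data$date) <= end)
}
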