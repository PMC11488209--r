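# Shared in-code fixtures: small deterministic inputs built at test time.

# Consult log with the published per-specialty counts; the remainder below
# the top ten is split into pseudo-specialties of fewer than 100 consults
# each so the "minimum 100 consults" selection behaves as in the report.
published_consult_log <- function() {
  top <- c(
    internal_medicine = 1318, psychiatry = 1020, obgyn = 431,
    endocrinology = 383, hematology = 322, hepatology = 279,
    rheumatology = 243, pediatrics = 237, infectious_diseases = 176,
    general_surgery = 103
  )
  rest_total <- 6072 - sum(top)
  rest <- rep(78, rest_total %/% 78)
  if (rest_total %% 78 > 0) rest <- c(rest, rest_total %% 78)
  names(rest) <- sprintf("other_%02d", seq_along(rest))
  counts <- c(top, rest)
  tibble::tibble(
    consult_id = sprintf("C%05d", seq_len(sum(counts))),
    specialty = rep(names(counts), counts),
    date = as.Date("2023-01-15"),
    completed = TRUE,
    requesting_role = "primary_care"
  )
}

# Tiny generator configuration: full survey sizes need a log of >= 653
# consults, everything else scaled down for speed.
small_config <- function(seed = 1L, ...) {
  generator_config(
    seed = seed,
    n_consults = 700,
    n_primary_care = 60,
    n_specialists = 12,
    ...
  )
}

random_likert <- function(n, seed) {
  withr::with_seed(seed, sample(1:5, n, replace = TRUE))
}
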