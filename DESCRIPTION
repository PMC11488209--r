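Package: econsultCBA
Title: Cost-Benefit and Probabilistic Sensitivity Analysis for
    Provider-to-Provider e-Consult Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible health-economic evaluation pipeline for
    provider-to-provider virtual consultation (e-consult) platforms,
    built from a healthcare-payer perspective. Models per-encounter
    billing costs from fee-schedule Medical Service Units (MSUs), values
    avoided in-person specialist referrals, accrues implementation and
    licensing costs with an opportunity cost of capital, and computes
    net benefit, benefit-cost ratio and return on investment. Parameter
    uncertainty is propagated by seeded Monte Carlo probabilistic
    sensitivity analysis with gamma/beta distributions calibrated by
    method of moments, summarised with percentile confidence intervals,
    plus one-way cost-multiplier scenarios. Descriptive summaries of
    platform utilization and of post-consultation and provider-experience
    surveys reproduce the tabular reporting conventions of feasibility
    evaluations, and a synthetic-data generator emulates the
    administrative and survey inputs so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
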