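Package: cervcost
Title: Markov Cohort Model of Cervical Cancer Screening and Preventative
    Cryotherapy in HIV-Infected Women
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic monthly-cycle Markov cohort model of the natural
    history of cervical cancer in HIV-infected women, with a screen-and-treat
    cascade covering seven strategies (preventative cryotherapy without
    screening, VIA, Pap, HPV DNA testing, and their pairwise combinations),
    loss to follow-up in multi-visit cascades, treatment side effects, and
    stage-specific cancer care costs from societal and clinic perspectives.
    Computes discounted lifetime costs and life expectancy per strategy,
    CD4-stratified scenarios, one-way (tornado) sensitivity analyses, a
    loss-to-follow-up threshold analysis, and an individual-level Monte Carlo
    microsimulation used as a validation oracle for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
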