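Package: ctdnaCEA
Title: Cost-Effectiveness of ctDNA-Guided Treatment Switching in mCRPC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-dependent Markov cohort model comparing circulating tumor
    DNA (ctDNA) guided early treatment switching against standard of care in
    first-line ARPI-treated metastatic castration-resistant prostate cancer.
    Converts survival summaries into per-cycle transition probabilities on an
    irregular cycle grid with chemotherapy tunnel states, accumulates
    discounted costs and QALYs, and produces deterministic and probabilistic
    cost-effectiveness outputs (ICER, incremental net monetary benefit,
    cost-effectiveness plane, acceptability curve), one-way sensitivity
    (tornado) and scenario analyses. Includes a synthetic parameter-set
    generator and an individual-level microsimulation oracle for engine
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
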