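Package: mirhts
Title: Pooled MicroRNA Dropout Screens, Competition Fitness, qPCR
    Quantitation and Target Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gain-of-function pooled lentiviral microRNA (miR)
    dropout screens and their downstream validation arithmetic. Simulates
    pooled screens (Poisson single-hit transduction, clonal exponential
    growth, cell subsampling, stochastic qPCR detection at low template
    copies), calls growth-inhibitory candidate constructs from
    multi-timepoint multi-replicate detection tables, estimates per-day
    selection coefficients from GFP-competition time series via
    logit-linear regression, performs absolute (standard-curve) and
    relative (delta-delta-Ct) qPCR quantitation, prioritizes miR targets
    by set filtering over prediction databases, expression calls and
    growth annotation, scans 3'UTRs for canonical seed-match sites
    (8mer-A1, 7mer-m8, 7mer-A1), and normalizes reporter, growth, flow
    and densitometry readouts used to validate candidate targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
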