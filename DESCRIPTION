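Package: umamikit
Title: Umami Profiling of Bivalve Taste Compounds and Regulatory Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative umami profiling for shellfish taste chemistry: taste-activity
    values (TAV) of free amino acids and 5'-nucleotides against human detection
    thresholds, the Yamaguchi synergistic equivalent-umami-concentration (EUC) score in
    g MSG/100 g, HPLC calibration-curve quantification of nucleotides, 2^-ddCt relative
    gene expression with primer-efficiency validation, one-way ANOVA with Tukey HSD
    compact-letter grouping, expression-metabolite Pearson correlation matrices, and a
    seeded synthetic-data generator (moment-matched lognormal concentrations, calibrated
    Gaussian-copula gene-compound coupling) so the full analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
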