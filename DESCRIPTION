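Package: abca1flux
Title: Functional Classification of ABCA1 Missense Variants from
    Fluorescence-Based Cholesterol-Efflux Assays
Version: 0.1.0
Authors@R:
    person("abca1flux", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Turns raw plate-reader fluorescence wells into corrected,
    wild-type-normalized cholesterol-efflux activities for ABCA1 missense
    variants; derives pathogenic and benevolent activity thresholds from
    characterized Tangier-disease controls and from conservation-supported
    calibration variants in a vertebrate multiple sequence alignment; assigns
    three-class functional calls (loss-of-function, uncertain, benevolent);
    quantifies total and cell-surface protein from densitometry; calls
    proteasome-inhibitor (epoxomicin), chemical-chaperone (4-PBA) and ApoA1
    stabilization responses with F-test-gated two-sample t-tests; and scores
    two-channel membrane colocalization by Pearson correlation. A synthetic
    data generator with known ground truth makes every stage testable without
    access to raw experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
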