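Package: isofix
Title: Quantifying Symbiotic N2 Fixation from 15N Natural Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify symbiotic dinitrogen fixation in grain
    legumes from 15N natural-abundance measurements. Converts 15N/14N
    abundance ratios to delta-15N, estimates the B value from glasshouse
    plants grown solely on atmospheric N2, computes the percentage of
    plant N derived from the atmosphere (%Ndfa) by isotope dilution
    against non-fixing reference plants, and scales shoot N content to
    per-hectare N-fixed and soil N uptake budgets using plant density.
    Includes balanced factorial ANOVA with Duncan's multiple range test
    for field-trial responses, a simple-sequence-repeat (SSR) tandem
    motif scanner with consensus mismatch counting for aligned
    sequences, a synthetic field-trial generator for end-to-end
    testing, and a pipeline that turns per-plant CSV records into
    treatment-level symbiosis reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
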