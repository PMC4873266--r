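Package: diazoquant
Title: Quantification of Endophytic Nitrogen Fixation Assays in Poplar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for quantifying biological nitrogen fixation by
    diazotrophic endophytes in plant cuttings from closed-flask 15N2 tracer
    experiments. Models the flask headspace N2 pool through dose and
    air-exchange events to obtain the atmosphere 15N atom-percent excess;
    converts isotope-ratio mass spectrometry delta-15N values to atom
    percent 15N, percent nitrogen derived from atmosphere (%Ndfa), and
    fixation rates with below-detection-limit calling; quantifies acetylene
    reduction assay (ARA) ethylene production against a gas-chromatograph
    standard curve with fold-over-baseline positive calls; computes
    colony-forming units per gram from dilution plating with TNTC and
    detection-limit handling; aggregates subsamples to experimental units
    and performs least-squares-means style pairwise group comparisons; and
    generates complete synthetic studies with ground truth emulating
    heterogeneous endophyte colonization, so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
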