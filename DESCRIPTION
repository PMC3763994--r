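Package: supercell
Title: Supercell Statistics for Phenotyping Heterogeneous Single-Cell Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Phenotype classification from multiparameter single-cell
    measurements via "supercell statistics": random groups of N cells are
    averaged into supercells, which narrows overlapping per-class
    distributions by roughly 1/sqrt(N) and makes heterogeneous,
    non-separable single-cell data separable.  Supercells are classified
    with a linear max-margin boundary; the components of the unit normal
    ("perceptron amplitudes") rank measurements by their contribution to
    class separation, mapping the tradeoff between the number of cells
    averaged and the number of measurements needed.  Held-out patients
    are diagnosed by a leave-one-patient-out jackknife with an
    unclassified band for supercell clouds that straddle the boundary.
    Includes a synthetic-cohort generator with closed-form accuracy
    oracles, sequential gating to cell subpopulations, and a plain-text
    table format for cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
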