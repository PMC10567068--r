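Package: soluphi
Title: Transparent Intrinsic Aqueous Solubility Models with Flexibility-Aware Coefficients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts intrinsic aqueous solubility (log10 molar) of drug-like
    molecules with a family of transparent models: the classic General
    Solubility Equation, a grouped Abraham solvation (LFER) equation, a
    flexible-acceptor variant whose coefficients are smooth functions of the
    Kier molecular flexibility index plus the Abraham H-bond basicity, a
    consensus average, and a flexibility-thresholded model selector. Includes
    a hydrogen-suppressed SMILES parser and Kier kappa shape indices, the
    two-step binned-regression training procedure that re-derives all model
    coefficients from a solubility database, validation-type evaluation
    metrics, a synthetic compound-table generator for testing every stage
    without proprietary data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
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
RoxygenNote: 7.3.3
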