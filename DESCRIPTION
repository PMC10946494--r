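Package: shiftmap
Title: Chemical-Shift Mapping and Prediction for 1H NMR Metabolic Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the positional variability of 1H NMR chemical shifts in
    serum and plasma spectra. Chemically homologous protons experience similar
    matrix effects (pH, ionic strength, protein binding), so their chemical
    shifts are close to linearly related across samples. The package fits all
    ordered pairwise linear regression models between spin-system shift
    columns, summarises them with R-squared, RMSE, relative RMSE and maximum
    residual, assembles the best models into a rooted prediction map (either a
    fixed literature map or a minimum-error spanning arborescence), and
    predicts the shifts of a whole metabolite panel from the observed position
    of a single anchor signal such as the valine methyl doublet, in
    single-hop or fully chained mode. Includes simple 1D spectrum handling
    (two-column and JCAMP-DX input, reference calibration, prominence-based
    peak picking, multiplet centering) and a latent-factor simulator of
    correlated shift tables for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'arborescence.R'
    'chained-prediction.R'
    'cli.R'
    'map-builder.R'
    'pairwise-regression.R'
    'shift-table.R'
    'shiftmap-package.R'
    'spectra-io.R'
    'spin-systems.R'
    'synthetic-data.R'
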