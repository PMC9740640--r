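Package: hwturnover
Title: Protein Turnover Rates from Heavy-Water Metabolic Labeling LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates in vivo protein turnover rate constants from
    heavy-water (D2O) metabolic labeling time-course LC-MS experiments.
    Reads MS1 spectra (mzML) and peptide-spectrum matches (mzIdentML),
    integrates six mass-isotopomer abundances per peptide per experiment,
    tracks the depletion of the monoisotopic relative isotope abundance
    (RIA) across labeling durations, and fits a one-pool exponential decay
    to obtain peptide rate constants with confidence intervals and
    goodness-of-fit statistics.  Protein rates are the median of peptide
    rates.  Includes match-between-runs transfer of quantifications,
    per-protein CSV reports, validation plots with machine-readable
    sidecars, and a synthetic mzML/mzid experiment generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mzR,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
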