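Package: myrms
Title: Marker-Ion Myristoylome Profiling, Spike-In-Calibrated Differential
    Proteomics and Targeted Acyl-CoA Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying activity-dependent protein myristoylation in
    neurons by mass spectrometry. Provides a monoisotopic elemental-formula
    mass engine that derives multiple-reaction-monitoring (MRM) transitions
    for acyl-coenzyme-A species and the diagnostic b1 marker ion of
    N-acylated peptides; database-independent profiling of the N-terminal
    myristoylome by scanning MS/MS spectra (MGF) for the 268.23 m/z
    myristoyl-glycine fragment, isotope-aware precursor binning and PCA of
    per-sample marker profiles; spike-in-calibrated differential protein
    expression with fold-change cut-off derivation from an exogenous
    lysozyme process control; dual-inhibitor dysregulation and concordance
    scoring; internal-standard quantification of acyl-CoAs and derivatized
    free fatty acids from MRM peak areas; and seeded synthetic-data
    generators with machine-readable ground truth so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
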