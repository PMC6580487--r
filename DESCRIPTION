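Package: cdpqc
Title: Quality Control Toolkit for Cystine-Dense Peptide Production
Version: 0.1.0
Authors@R:
    person("Production QC", "Maintainers", email = "qc@example.org",
           role = c("aut", "cre"))
Description: Automated quality classification of paired intact/DTT-reduced
    liquid-chromatography UV traces of cystine-dense peptides into four
    categories (Perfect, PerfectPartial, Simple, Complex), with
    blank-subtraction normalization, robust noise estimation,
    signal-to-noise gated peak and shoulder detection inside a
    retention-time window, in-silico peptide properties
    (disulfide-corrected monoisotopic and average mass, net charge at a
    given pH, GRAVY hydrophobicity), ESI charge-state m/z validation,
    whole-body autoradiography standard-curve fitting and raw-signal to
    dpm transformation, a labeled synthetic chromatogram batch generator,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
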