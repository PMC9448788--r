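Package: aslbids
Title: Tools for ASL-BIDS Perfusion Datasets: Validation, Synthesis and CBF Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for the BIDS 'perf' datatype used to store arterial
    spin labeling (ASL) perfusion MRI. Provides a typed in-memory model of an
    ASL-BIDS subject (NIfTI images, JSON sidecars, the aslcontext TSV), a
    machine-readable registry of the REQUIRED/RECOMMENDED/OPTIONAL metadata
    ladder with conditional applicability, a rule-engine validator with stable
    rule identifiers, the two conversion-time transforms (intensity scaling
    and restoration of acquisition order), a synthetic dataset generator that
    emulates the five public ASL-BIDS example configurations with known
    ground-truth perfusion, and a single-delay cerebral blood flow (CBF)
    quantifier that demonstrates the REQUIRED metadata suffice for
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
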