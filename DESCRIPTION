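Package: phosphoRate
Title: Phosphorylation-Rate Quantification from 2-DE Gel Spot Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies per-spot protein phosphorylation rates from
    two-dimensional gel electrophoresis (2-DE) spot-volume tables, using
    either a phosphoprotein-specific stain (Pro-Q Diamond type) or chemical
    dephosphorylation (hydrogen fluoride-pyridine, HF-P) profiles against a
    total-protein reference stain. Provides total-density normalization,
    replicate detection rules, profile matching, bias-corrected percentile
    bootstrap confidence intervals with Bonferroni control, a two-tailed
    Fisher exact test of method-level detection, classification of
    dephosphorylation patterns (reduced, basic-shifted, disappeared, novel),
    pI/Mr gel calibration, and a synthetic gel-spot generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
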