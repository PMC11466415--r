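Package: tcreval
Title: Evaluation of Fixed-Backbone TCR Interface Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Metrics and statistical tests for judging fixed-backbone
    T cell receptor (TCR) interface designs against a native TCR:pMHC
    complex. Provides PDB parsing with chain-role annotation, all-atom
    interface contact detection, Shrake-Rupley solvent accessibility and
    burial classification, CDR delimitation from Aho numbering with five
    design-position selection scenarios, sequence-level design metrics
    (native sequence recovery, physicochemical similarity, uniqueness,
    positional Shannon entropy), alanine-scan hotspot classification, a
    subsampling bootstrap group-comparison test, Mann-Whitney rank tests,
    synthetic complex and design-set generators with known ground truth,
    and an end-to-end evaluation pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
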