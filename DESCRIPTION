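Package: eamem
Title: Entropic Associative Memory over Relational-Indeterminate Computing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A bank of table-format associative memory registers built on a
    relational-indeterminate computing kernel: relations as boolean incidence
    tables with abstraction (cell-wise disjunction), containment (material
    implication), constructive reduction (random selection among a relation's
    values, centred on the cue) and a computational entropy measure. Includes
    equal-width quantization of real-valued feature vectors onto m-bit levels,
    register/recognize/retrieve memory protocols with minimal-entropy register
    selection and relaxed recognition for degraded cues, a synthetic
    class-conditional feature-corpus generator with occlusion-style corruption,
    and an experiment harness measuring precision, recall and entropy across
    granularities, fill fractions and relaxation levels.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
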