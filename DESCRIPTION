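Package: BoneAgeDL
Title: Bone Age Assessment from Hand Radiographs with Ambiguous Report Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-distribution learning for pediatric bone age assessment from
    left-hand radiographs when only ambiguous radiology-report labels
    ("approximately 9 years old", "12-13 years old") are available. Provides a
    report-label codec that turns point and interval age statements into
    Gaussian label distributions over 240 monthly bins, weakly supervised hand
    localization from class activation maps, anchor-based bone-part proposal
    scoring with non-maximum suppression, a composite distribution-learning
    loss with temporal ensembling, a three-branch training and inference
    pipeline around a pluggable image backbone, and a deterministic synthetic
    phantom-radiograph generator so the whole stack is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
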