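Package: facetriad
Title: Structure, Color, and Texture Cues of Neutral Faces in a
    Dominance-Affiliation Face Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for reading emotion-resembling
    structure, color, and texture cues from neutral face images,
    combining per-metric classifiers into an accuracy-weighted emotion
    output, projecting that output into a dominance-affiliation
    (interpersonal circumplex) face space, constructing morphed stimuli
    from face-space positions, and running the correlation and bootstrap
    mediation statistics that link machine outputs to human impression
    ratings. Ships a fully synthetic face generator with planted,
    recoverable effects so every stage is testable without external
    face databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    nnet,
    png,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    lmerTest,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
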