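Package: compactSSP
Title: Compact-Model Protein Secondary Structure Prediction with a
    Complex-Valued Relaxation Network
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-state protein secondary structure prediction built
    around a fully complex-valued relaxation network (FCRN): per-residue
    probability features over a nine-residue window are normalized,
    mapped to the unit circle, and classified by a single-hidden-layer
    complex network with sech activation, exponential output and
    analytically solved output weights.  The package also implements the
    three-stage compact-training-set selection procedure (training-curve
    estimation, heuristic candidate construction, blind-set ranking), the
    full evaluation suite (Q3, per-class Q, Zemla-1999 segment overlap
    SOV, per-class Matthews correlation, helix/sheet confusion rate), the
    DSSP eight-to-three state reduction, a synthetic generator emulating
    energy-potential-derived residue probability features, and a
    hydrogen-bond contact analysis classifying main-chain/main-chain
    versus main-chain/water contacts by prediction outcome.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml, bio3d, withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
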