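Package: sigconnect
Title: Stage-Monotone Gene Signatures, Significant Connectivity Mapping,
    and Median-Effect Drug Synergy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end in-silico drug-repurposing toolkit for ordinal
    disease-stage expression cohorts, such as myelodysplastic syndrome (MDS)
    progressing to secondary acute myeloid leukemia. Derives gene signatures
    of disease development and progression by combining per-gene one-way
    ANOVA with Benjamini-Hochberg false-discovery control and a strict
    monotone-trend filter across ordered stages; queries signed-rank
    perturbagen reference profiles with normalized connection scores and
    permutation p-values under an expected-false-positive significance
    threshold; selects drug hits reversing the disease signature; and
    quantifies drug-pair interactions with median-effect (Chou-Talalay)
    curve fits and Combination Index values. Includes seeded synthetic-data
    generators with planted ground truth for every pipeline stage, and a
    reproducible pipeline runner with a provenance manifest.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
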