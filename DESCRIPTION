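Package: fmsf
Title: Flow-Mediated Skin Fluorescence Trace Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of Flow-Mediated Skin Fluorescence (FMSF) recordings
    acquired under a post-occlusive reactive hyperemia protocol. Segments
    NADH-fluorescence traces into baseline, occlusion, hyperemic and
    reperfusion phases, decomposes low-frequency microcirculatory
    oscillations into endothelial, neurogenic and myogenic bands by
    periodogram integration, and derives the standard vascular parameters
    (FM, NEURO, NOI, IRmax, HRmax, RHR, HS). Includes normality-gated
    two-group cohort statistics, a seedable synthetic trace and cohort
    generator with known ground truth, and CSV/JSON readers and writers
    for reproducible pipelines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
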