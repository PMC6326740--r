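Package: bgcnet
Title: Between-Network Global Connectivity Analysis for Parcellated
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end resting-state functional-connectivity
    pipeline relating between-network global connectivity (BGC) of cortical
    networks to depression-symptom severity: framewise-displacement motion
    scrubbing with a low-pass filtered FD trace, nuisance regression
    (12 motion parameters, ventricle/white-matter signals and derivatives,
    global signal), Pearson functional-connectivity matrices, region- and
    network-level BGC with connection-exclusion and within/between-network
    controls, CES-D scoring with three-factor subscores and Box-Cox
    normalization gated by a Kolmogorov-Smirnov test, and the full
    inferential surface (Pearson/Spearman/partial rank correlations,
    Benjamini-Hochberg FDR, Fisher z comparison of correlations). A
    synthetic-cohort generator with a planted, tunable BGC-symptom effect
    makes every stage testable without access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
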