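Package: gpimer
Title: Spectral Feature Analysis of Globus Pallidus Microelectrode Recordings
Version: 0.1.0
Authors@R: person("MER", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intraoperative microelectrode recordings
    (MER) acquired along globus pallidus internus (GPi) trajectories during
    deep brain stimulation surgery in dystonia. Detects the longest stable
    epoch of each recording by segment-RMS outlier rejection, extracts
    rectified-envelope spectral features (theta/alpha/beta/gamma power
    fractions, band ratios and baseline elevation) from Welch spectra at
    1/3 Hz resolution, normalizes recording depths to the GPi span, and runs
    the group-comparison statistics battery (Kruskal-Wallis with Dunn's
    post hoc test and Holm-Bonferroni correction, permutation Spearman
    correlations with Benjamini-Hochberg FDR, and linear mixed models for
    depth effects). Ships a seeded synthetic MER cohort generator with
    programmable per-group envelope modulation, artifacts and depth
    structure so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
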