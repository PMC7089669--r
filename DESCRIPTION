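Package: copath
Title: Co-Localization Analysis of Regional PET Binding in Frontotemporal
    Dementia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate analysis of regional PET binding-potential data
    across frontotemporal dementia syndromes: partial-volume correction and
    repeated-measures regional ANOVA with Greenhouse-Geisser correction of
    degrees of freedom, between-ligand spatial coupling with atrophy
    partialling and lobe-wise ANCOVA, principal spatial-mode analysis with
    scree-elbow component retention, an affinity-blind rank-dissimilarity /
    metric multidimensional-scaling / cross-validated support-vector-machine
    / permutation classifier, and stereological grid-count density analysis
    of histology point patterns.  Includes a seeded synthetic-cohort
    generator emulating the statistical structure of two-ligand regional
    binding studies so that every pipeline stage is testable without scan
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
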