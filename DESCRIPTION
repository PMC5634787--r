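Package: sacflux
Title: Fluid-Absorption Volumetry and Expression Analysis for the Developing Endolymphatic Sac
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies luminal fluid absorption in organ-cultured embryonic
    endolymphatic sacs from 3D confocal image stacks (smoothing, threshold
    segmentation, voxel counting, conversion to nanoliters) and normalizes
    absorption rates to a luminal surface area estimated with a two-spherical-
    caps-plus-conical-frustum model.  Includes the accompanying group
    statistics (Grubbs outlier screen, Shapiro-Wilk, one-way ANOVA with
    Bonferroni pairwise t-tests, Cohen's d), a single-cell expression workflow
    (median-of-ratios normalization, variable-gene filtering, PCA, principal-
    component-correlated gene selection, hierarchical clustering, rank-based
    differential expression with detection and specificity criteria, Fisher
    enrichment, single-cell qPCR conversion), a genotype-by-time polynomial
    regression analysis for expression time courses, relative qPCR
    quantification, and synthetic-data generators with known ground truth for
    every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    limma,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
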