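Package: surfReHo
Title: Surface-Based Regional Homogeneity Analysis of Resting-State fMRI
Version: 0.1.0
Authors@R: person("surfReHo", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes two-dimensional regional homogeneity (2dReHo) on
    triangulated cortical surface meshes: Kendall's coefficient of
    concordance over each vertex and its k-ring mesh neighborhood,
    applied to surface-projected resting-state fMRI time series.
    Includes mesh I/O (FreeSurfer binary geometry, GIFTI), functional
    preprocessing (volume-to-surface trilinear sampling at the
    mid-thickness surface, Friston-24 plus white-matter/CSF nuisance
    regression, band-pass filtering), geodesic Gaussian surface
    smoothing, vertex-wise two-sample group statistics with
    Benjamini-Hochberg false discovery rate control, signed cluster
    extraction, covariate-adjusted Spearman correlations with clinical
    variables, and a synthetic cohort generator with planted regional
    synchrony effects for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
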