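Package: shapeAsym
Title: Multiscale Cortical Shape Asymmetry from Laplace-Beltrami Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectral shape analysis of closed triangle surface meshes for
    studying brain shape and its asymmetry independent of size. Assembles
    linear or cubic finite-element discretizations of the Laplace-Beltrami
    operator, solves for the low eigenvalue spectrum (Shape-DNA), applies
    surface-area and volume normalizations, and derives the Shape Asymmetry
    Signature (SAS) as the per-index difference between area-normalized left-
    and right-hemisphere spectra. Provides spherical-harmonic eigen-group
    bookkeeping and wavelength mapping, Glass's-delta subject identifiability
    with truncation sweeps and permutation nulls, permutation GLM and
    PCA+CCA association pipelines with family-block exchangeability, and
    twin variance-component (ACTE family) heritability modelling. Includes
    synthetic surface and twin-cohort generators with known ground truth,
    mesh readers and writers (FreeSurfer binary, OFF, PLY), and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'mesh-io.R'
    'tables.R'
    'fem.R'
    'spectra.R'
    'synthetic-surfaces.R'
    'asymmetry.R'
    'eigengroups.R'
    'identifiability.R'
    'group-stats.R'
    'heritability.R'
    'pipeline.R'
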