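# shapeAsym

Multiscale analysis of cortical shape asymmetry from Laplace–Beltrami
spectra, for researchers studying brain laterality, morphometric
fingerprinting, and the genetics of brain shape — or any problem where
the shape of closed surfaces must be compared independently of their
size.

## What it computes

The package is built around the spectrum of the Laplace–Beltrami
operator (LBO) on a closed triangle mesh. Solving the Helmholtz equation
Δf = −λf on the surface gives eigenvalues 0 = λ₁ ≤ λ₂ ≤ …, the
"Shape-DNA" of the object: an isometry-invariant shape descriptor that
is unchanged by translation, rotation, and mirroring. After rescaling
each surface to unit area (λᵢ′ = area · λᵢ), spectra no longer encode
size, and the **Shape Asymmetry Signature (SAS)** of a subject is the
per-index difference between its left and right hemisphere spectra:

    Λᵢ = λᵢᴸ − λᵢᴿ        (area-normalized, index 1 is the zero mode)

Eigenvalue indices group into spherical-harmonic eigen-groups (group L
holds 2L+1 values, groups 0–11 hold the first 144) with physical
wavelength W = 2πRs/√(L(L+1)) on the equivalent sphere of radius
Rs = √(area/4π). On top of that sit:

* **finite-element spectra** — linear or cubic elements, sparse
  shift-invert ARPACK solver with a dense LAPACK oracle;
* **subject identifiability** — Glass's Δ on the t1–t2 Pearson
  correlation matrix, Δ = (mean rᵢᵢ − mean rᵢⱼ)/SD(rᵢⱼ), swept over
  spectral truncations to find the scale where individuals differ most,
  with a permutation null on the peak;
* **association statistics** — block-respecting permutation GLM,
  Cohen's d, Benjamini–Hochberg FDR, and a PCA → CCA pipeline with
  max-statistic FWER permutation inference and family-block bootstrap
  loadings;
* **twin heritability** — maximum-likelihood ACTE/ACE/…/E variance
  components on MZ/DZ/sibling families, AIC selection, likelihood-ratio
  tests;
* **synthetic generators** — icosphere cohorts with subject-,
  hemisphere- and session-specific spherical-harmonic shape fields, and
  twin-structured phenotypes with known variance proportions;
* **mesh and table I/O** — FreeSurfer binary surfaces, OFF, PLY (ascii
  and binary), and keyed CSV/TSV spectra, phenotype and pedigree tables.

A thin command-line front end (`inst/cli/shapeasym`) exposes the
simulate / spectrum / sas / groups / identify / herit / run steps for
shell pipelines; `runPipeline()` drives the same flow from R.

## Worked example

Eigenvalues of the unit sphere come in degenerate groups L(L+1) with
multiplicity 2L+1:

```r
library(shapeAsym)
sp <- computeSpectrum(icosphere(3), k = 10)
round(spectrumValues(sp), 3)
#>  [1]  0.000  2.012  2.012  2.012  6.070  6.070  6.070  6.070  6.070 12.245
round(groupWavelength(c(1, 9, 11), Rs = 67), 1)
#> [1] 297.7  44.4  36.6
```

The first line is the discretized sphere spectrum (analytic values 0,
2, 2, 2, 6, …); the second gives the spatial wavelengths of eigen-groups
1, 9 and 11 on a 67-mm template hemisphere — about 300 mm, 44 mm and
37 mm.

A synthetic longitudinal cohort with individual asymmetry injected at
harmonic degrees 2–6, run end to end:

```r
spec <- cohortSpec(n_subjects = 12, subject_sd = 1, asym_sd = 1,
                   session_sd = 0.15, scale_band = 2:6,
                   noise_band = 1:10, subdivisions = 3, seed = 7)
spectra <- computeSpectraTable(generateCohort(spec), k = 100,
                               normalization = "area")
sas  <- sasTable(spectra)
info <- spectraInfo(sas)
t1 <- spectraValues(sas)[info$session == "t1", ]
t2 <- spectraValues(sas)[info$session == "t2", ]

identifiabilitySweep(t1, t2, kMax = 100)
#> SweepCurve: k = 2..100, peak 2.317 at k = 23

permutationNull(t1, t2, kMax = 100, nPerm = 1000, seed = 2)$p
#> [1] 0.000999001
```

The sweep peaks at truncation k = 23 — inside eigen-group 4, i.e. within
the coarse band where the asymmetry signal was injected — with Glass's
Δ ≈ 2.3, and no permuted cohort reaches the observed peak
(p = 1/1001). Mirror-isometric cohorts (`asym_sd = 0, session_sd = 0`)
give SAS ≈ 0 at every index, the built-in exact zero reference.

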