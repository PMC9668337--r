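---
title: "Multiscale shape asymmetry from Laplace-Beltrami spectra: methods and design"
author: "shapeAsym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale shape asymmetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeAsym)
```

## The model

shapeAsym treats the shape of a closed surface — a cortical hemisphere
reconstructed from MRI, or a synthetic sphere-like mesh — through the
eigenvalue spectrum of its Laplace-Beltrami operator (LBO). Solving the
Helmholtz equation on the surface,

$$\Delta f = -\lambda f,$$

yields eigenfunctions $f_i$ ordered from coarse to fine spatial scales and
eigenvalues $0 = \lambda_1 \le \lambda_2 \le \dots$, the "Shape-DNA"
descriptor. The spectrum is isometry invariant: translating, rotating, or
mirroring an object changes no eigenvalue, which is what lets left and
right hemispheres be compared without registration, smoothing, or an
explicit left-right correspondence.

Eigenvalues grow linearly with index (Weyl's law,
$\lambda_n \sim 4\pi n/\mathrm{area}$), so raw spectra mostly encode
surface area, i.e. size. Two normalizations are provided:

* **surface-area normalization** (the default for all asymmetry work):
  rescaling the mesh to unit area, equivalently $\lambda_i' =
  \mathrm{area} \cdot \lambda_i$. Area-normalized spectra of same-shaped
  objects of any size coincide, and their Weyl slopes align across a
  cohort;
* **volume normalization**, $\lambda' = v^{2/D}\lambda$, kept for
  comparison. For a closed surface we take $v$ to be the enclosed 3-D
  volume with $D = 3$. This choice deserves a note: for a 2-manifold the
  Riemannian volume is its area, but with that reading the two
  normalizations would coincide, contradicting their observed different
  behaviour (volume normalization fails to equalize Weyl slopes when
  area-to-volume ratios vary); the enclosed-volume reading is the one
  that makes the contrast meaningful, and the package's tests reproduce
  the contrast on ellipsoid cohorts.

The **Shape Asymmetry Signature (SAS)** of a subject is the per-index
difference of the area-normalized spectra of the left and right
hemispheres,

$$\Lambda_i = \lambda^L_i - \lambda^R_i ,$$

a scale-resolved, size-independent summary of how the two hemispheres
differ in shape. Because mirroring is an isometry, a perfectly
mirror-symmetric brain has $\Lambda \equiv 0$; `computeSAS()` refuses
spectra that are not area-normalized because on any other normalization
the difference is dominated by size, which is exactly what the measure is
designed to exclude.

## Eigen-groups and wavelengths

On a sphere, eigenvalues come in degenerate groups indexed by the
spherical-harmonic degree $L$, with $2(L+1)-1 = 2L+1$ members; group $L$
spans 1-based indices $L^2+1$ to $(L+1)^2$, so groups 0-11 together hold
144 eigenvalues. Cortical surfaces are topologically spherical, and the
spherical grouping is used as a stable scale axis: per-group means smooth
eigenvalue-specific fluctuations, and each group maps to a physical
wavelength through the equivalent sphere of radius
$R_s = \sqrt{\mathrm{area}/4\pi}$:

$$W(L) = \frac{2\pi R_s}{\sqrt{L(L+1)}}.$$

For a template hemisphere with $R_s \approx 67$ mm this gives roughly
300 mm at $L=1$, 44 mm at $L=9$ and 37 mm at $L=11$. Wavelengths are
returned unrounded; rounding to the nearest mm happens only in display
output.

## Subject identifiability

Whether a feature vector (an SAS, a spectrum, any per-subject vector)
"fingerprints" individuals is quantified from the $N \times N$ Pearson
matrix between time-1 and time-2 vectors: within-subject correlations on
the diagonal, between-subject correlations off it. The identifiability
score is Glass's $\Delta$,

$$\Delta = \frac{\mathrm{mean}(r_{ii}) - \mathrm{mean}(r_{ij})}
                {\mathrm{SD}(r_{ij})},$$

with the between-subject group as the control (its SD, ddof = 1, over all
$N^2-N$ off-diagonal entries of the non-symmetric matrix). A pooled-SD
variant is available for comparison. The truncation sweep recomputes
$\Delta$ as more indices are included; its peak locates the spatial scale
at which individuals differ most. Two conventions exist for the constant
first index ($\lambda_1 \approx 0$, SAS index 1 $\approx 0$): the
package excludes it by default, because it carries no shape variance and
makes the smallest truncations degenerate (two-point correlations are
$\pm 1$ by construction); `includeFirst = TRUE` restores the literal
first-$k$ convention. Sweep ties break toward the smaller truncation —
the coarser, more parsimonious scale.

Significance uses a permutation null: the subject order of the t2 session
is shuffled, the whole sweep is recomputed, and the permuted **peak**
score is recorded, so the null respects the maximization over scales.
Both the raw exceedance proportion (which can be 0) and the
$(x+1)/(n+1)$-corrected p are reported; the corrected value is the
default for inference. Since shuffling only permutes columns of the
per-truncation correlation matrices, the null costs almost nothing
beyond the observed sweep.

## Association analyses

`glmPermutation()` tests one feature against a predictor with nuisance
covariates, permuting the predictor while keeping family blocks intact
(whole-block exchange among blocks of identical size); handedness-type
scores are treated as continuous by default, with categorization left to
the caller. `ccaPipeline()` implements the cognition pipeline: the
measure block is PCA-reduced to a cumulative-variance target (default
0.80), CCA is fitted against the 11 eigen-group means, and mode
significance uses a block-respecting permutation with a max-statistic
FWER procedure. The test statistic per permutation is the largest
canonical correlation (Roy's largest root) — the procedure's name leaves
the statistic open, and the largest root is the natural max-statistic
choice. Loading reliability comes from a family-block bootstrap:
correlations between each input variable and its block's canonical
variate are recomputed on resampled families with the original canonical
weights, the bootstrap SD gives a z-score, two-sided normal p-values are
FDR-corrected within each block. Covariate adjustment of both blocks is
available but off by default.

## Twin heritability

Variance components follow the ACTE family: additive genetics (A, with
$h^2 = a^2$), family-wide common environment (C), twin-pair-specific
environment (T), and unique environment plus measurement error (E).
Expected covariances: MZ co-twins $a^2+c^2+t^2$, DZ co-twins
$\tfrac12 a^2+c^2+t^2$, twin-sibling and sibling-sibling pairs
$\tfrac12 a^2+c^2$ (DZ-sibling and MZ-sibling pairs are treated
identically, the standard assumption, and T applies equally to MZ and DZ
pairs). The likelihood is written directly as a product of per-family
multivariate normals — families stack into a handful of covariance
structures, so each evaluation is a few small Cholesky factorizations —
and maximized under non-negativity bounds (L-BFGS-B) with a free mean.
This direct implementation keeps exact control over nested-model
comparisons. Model selection fits ACTE, ACE, ATE, CTE, TE, CE and E,
picks the lowest AIC ($2p - 2\ell$, ties to fewer parameters), and the A
and C components are tested by likelihood ratio against the full model
without them; with components on the boundary the $\chi^2$ reference is
conservative, and no 50:50 mixture correction is applied. Before
fitting, each phenotype is filtered by the strict boxplot rule (keep
$Q_1 - 1.5\,\mathrm{IQR} < v < Q_3 + 1.5\,\mathrm{IQR}$; constant data
retains nothing and warns) and residualized on age and sex. Families
with several non-twin siblings keep one, drawn with a fixed seed.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every downstream stage has inputs with known
ground truth.

`generateCohort()` builds, per subject, hemisphere and session, an
icosphere displaced radially by Gaussian random fields expanded in real
spherical harmonics: a subject field shared by both hemispheres, a
hemisphere-specific field (amplitude `asym_sd`) that is the subject's
individual asymmetry, and a fresh per-session noise field
(`session_sd`). The right hemisphere is produced by mirroring, so
`asym_sd = 0, session_sd = 0` gives exactly mirror-isometric hemisphere
pairs — an exact zero reference for the SAS. Amplitudes are RMS radial
displacements in mm, split evenly over the degrees of their band;
spherical-harmonic displacement (rather than vertex-wise noise) gives the
injected signal a controllable spatial scale aligned with eigen-groups,
which is what makes scale-recovery tests of the sweep possible. Defaults
are chosen to resemble a human-hemisphere setting: base radius 67 mm
(the template equivalent radius), subject and asymmetry fields of 2 and
1 mm RMS on degrees 2-6 (coarse, sulcus-scale variation), 0.2 mm
broadband session noise (degrees 1-12) for high test-retest
reliability, and icosphere subdivision 4 (2562 vertices), enough for
~150 accurate eigenvalues at seconds-per-mesh solve times. What the
generator does **not** emulate: cortical folding, the area distortions
of real anatomy, spatially correlated segmentation error, or any
size-shape coupling — so passing tests demonstrate the machinery's
correctness and calibration, not performance on real cortical surfaces.

A note on one derived behaviour: perturbing only degree $\ell$ shifts
eigen-groups from $L = \ell/2$ upward (first-order coupling needs
$2L \ge \ell$); coarser groups move only at second order. Tests assert
this computed selection rule rather than the looser intuition that
degree-$\ell$ energy lands near group $\ell$.

`generateTwinPhenotypes()` draws phenotypes $y = a G + c C + t T + e E$
from unit-variance latent components with the relatedness structure
above; trio families (twin pair + one sibling) alternate MZ/DZ zygosity
deterministically. Age and sex are attached with zero effect by default
so the stated variance proportions hold exactly for the raw values.

## Numerical choices

* **FEM discretization.** Linear (P1) elements by default; cubic (P3)
  Lagrange elements available. Both are assembled from reference-element
  quadrature (tensor Gauss on the Duffy-collapsed triangle, exact for
  the polynomial integrands); for P1 this reproduces the cotangent
  stiffness and consistent mass exactly. Low-order area-normalized
  eigenvalues from P1 converge under refinement to the same values as
  P3, which the convergence tests verify; exact numerical agreement with
  cubic-FEM reference implementations at high index is not claimed.
* **Eigensolver.** Generalized problem $K f = \lambda M f$ solved in
  shift-invert mode about a small negative shift (no singularity at the
  zero mode), symmetrized through the sparse Cholesky factor of $M$, via
  ARPACK Lanczos. The request is padded by 8 extra eigenvalues and uses
  a fixed RNG state for the start vector: spheres have eigenvalue
  clusters of multiplicity up to $2L+1$, and padding plus a fixed start
  prevents losing a copy of a cluster at the truncation boundary.
  Systems with at most 600 nodes use a dense LAPACK solve instead; the
  dense path doubles as the independent oracle in tests (agreement to
  1e-8 relative).
* **Zero mode.** $\lambda_1$ is reported as 0 when it is within solver
  noise of 0 ($|\lambda_1| < 10^{-6}\lambda_2$ is the documented closed-
  surface check); tiny negative values from the solver are clamped.
* **Degeneracy.** Eigenvalues are returned ascending with stable ties;
  individual eigenfunctions inside a degenerate cluster are
  solver-dependent and are not part of the public contract.
* **Orientation.** Winding is repaired automatically (with a warning)
  before signed-volume computations; spectra are orientation-blind.
* **Mesh validity.** Spectral operations require closed 2-manifolds;
  `validateMesh()` reports boundary and non-manifold edges and the genus
  from the Euler characteristic instead of throwing.
* **Indices.** All public APIs use 1-based eigenvalue indices with
  index 1 the near-zero mode, and 1-based vertex indices in memory —
  one internal convention everywhere, converted at file boundaries
  (OFF/PLY/FreeSurfer store 0-based indices).
* **Coordinates** are interpreted in mm and never reoriented
  (RAS/LPS is irrelevant to an isometry-invariant descriptor).

## Problem sizes in the test suite

The suite exercises the full stack at sizes chosen for a laptop-scale
run: sphere-spectrum accuracy and Weyl checks on icosphere(5) (10242
vertices, 310 eigenvalues); identifiability on a 12-subject, 2-session
cohort at subdivision 3 with 100 eigenvalues and 1000-permutation nulls;
GLM and CCA type-I calibration on 500 null simulations with 199
permutations each; heritability recovery from 500+500-pair cohorts.
Because a single 500+500-pair cohort gives the ML estimator a sampling
SD of about 0.07 on $a^2$, the recovery experiment averages estimates
over 12 replicate cohorts, separating estimator bias (what recovery
should test) from single-draw noise. Permutation counts in examples
default to full-scale values (50000 for CCA; GLM nulls are typically run
at 100000); tests reduce them, which only widens Monte-Carlo error, not
validity.

## Known limitations

* Real cortical meshes are accepted as given; no retopologization,
  decimation, or hole-filling is attempted, and meshes failing
  `validateMesh()` are rejected rather than repaired (beyond winding).
* The cubic-element path stores no curved geometry: elements are flat
  triangles, so at equal node budget its advantage over P1 is in the
  basis, not the geometry.
* The permutation CCA treats all same-size families as exchangeable;
  finer exchangeability schemes (e.g. within-zygosity-only exchange) are
  not implemented.
* Boundary-constrained LRTs are conservative; reported A/C p-values err
  on the cautious side.
* The identifiability engine accepts arbitrary per-subject feature
  vectors, but nothing in the package estimates functional connectivity
  or regional morphometry from images — those arrive as tables.
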