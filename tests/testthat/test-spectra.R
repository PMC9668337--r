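# FEM assembly, eigensolver, geometric quantities, normalizations.

test_that("FEM systems annihilate constants and integrate to the area", {
  for (degree in c(1, 3)) {
    mesh <- perturbWithHarmonics(icosphere(2), c(0, 0.05, 0.05),
                                 seed = 1)
    fem <- assembleFEM(mesh, degree)
    ones <- rep(1, fem@nNodes)
    expect_lt(max(abs(fem@stiffness %*% ones)), 1e-10)
    expect_equal(sum(fem@mass), surfaceArea(mesh), tolerance = 1e-10)
    expect_lt(max(abs(fem@stiffness - Matrix::t(fem@stiffness))), 1e-12)
  }
  # degree-1 mass entries are non-negative
  fem1 <- assembleFEM(icosphere(1), 1)
  expect_gte(min(fem1@mass@x), 0)
  # cubic node count: V + 2E + F
  fem3 <- assembleFEM(icosphere(1), 3)
  expect_equal(fem3@nNodes, 42L + 2L * 120L + 80L)
})

test_that("degenerate triangles are rejected with the face named", {
  tet <- tetrahedron()
  v <- meshVertices(tet)
  v[4, ] <- (v[1, ] + v[2, ]) / 2      # vertex collapsed onto an edge
  bad <- TriangleMesh(v, meshFaces(tet))
  expect_error(assembleFEM(bad, 1), "face")
})

test_that("unit icosphere(4) reproduces the analytic sphere spectrum", {
  v <- spectrumValues(computeSpectrum(icosphere(4), k = 10))
  expect_lt(v[1], 1e-6 * v[2])
  expect_lt(max(abs(v[2:4] - 2) / 2), 0.01)
  expect_lt(max(abs(v[5:9] - 6) / 6), 0.015)
})

test_that("eigenvalues scale as 1/s^2 under uniform scaling", {
  m1 <- perturbWithHarmonics(icosphere(2), c(0, 0.05, 0.03), seed = 2)
  m2 <- m1; m2@vertices <- 2 * m2@vertices
  v1 <- spectrumValues(computeSpectrum(m1, k = 15))
  v2 <- spectrumValues(computeSpectrum(m2, k = 15))
  expect_equal(v2[2:15], v1[2:15] / 4, tolerance = 1e-9)
})

test_that("spectra are invariant to rotation, translation and mirroring", {
  m <- perturbWithHarmonics(icosphere(2), c(0, 0.05, 0.03, 0.02),
                            seed = 3)
  v0 <- spectrumValues(computeSpectrum(m, k = 20))
  th <- 0.83
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
              c(0, 0, 1))
  moved <- m
  moved@vertices <- sweep(m@vertices %*% Rz, 2, c(3, -1, 7), "+")
  expect_lt(max(abs(spectrumValues(computeSpectrum(moved, k = 20)) - v0)),
            1e-9)
  mirrored <- shapeAsym:::.mirrorMesh(m)
  expect_lt(max(abs(spectrumValues(computeSpectrum(mirrored, k = 20)) -
                      v0)), 1e-9)
})

test_that("sparse shift-invert matches the dense oracle", {
  m <- icosphere(2)                     # 162 nodes
  d <- spectrumValues(computeSpectrum(m, k = 20, method = "dense"))
  a <- spectrumValues(computeSpectrum(m, k = 20, method = "arpack"))
  expect_lt(max(abs(d[2:20] - a[2:20]) / d[2:20]), 1e-8)
  expect_error(computeSpectrum(icosphere(0), k = 12), "smaller")
})

test_that("refinement monotonically reduces the eigenvalue error", {
  err <- vapply(1:3, function(s) {
    v <- spectrumValues(computeSpectrum(icosphere(s), k = 10,
                                        method = "dense"))
    mean(abs(v[2:4] - 2) / 2)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("surface area and enclosed volume match closed forms", {
  cube <- cubeMesh()
  expect_equal(surfaceArea(cube), 6)
  expect_equal(enclosedVolume(cube), 1)
  ico <- icosphere(4)
  expect_lt(surfaceArea(ico), 4 * pi)
  expect_gt(surfaceArea(ico), 4 * pi * 0.995)
  expect_lt(enclosedVolume(ico), 4 * pi / 3)
  expect_gt(enclosedVolume(ico), 4 * pi / 3 * 0.99)
  # scaling: area ~ s^2
  sc <- cube; sc@vertices <- 3 * sc@vertices
  expect_equal(surfaceArea(sc), 54)
  # mirrored mesh keeps its (positive) volume
  expect_equal(enclosedVolume(shapeAsym:::.mirrorMesh(cube)), 1)
  open <- cube; open@faces <- open@faces[-1, ]
  expect_error(enclosedVolume(open), "closed")
})

test_that("area normalization equalizes spectra across sizes", {
  sp1 <- computeSpectrum(icosphere(3, 1), k = 10)
  sp3 <- computeSpectrum(icosphere(3, 3), k = 10)
  n1 <- normalizeArea(sp1); n3 <- normalizeArea(sp3)
  expect_identical(spectrumNormalization(n1), "area")
  expect_equal(spectrumValues(n1)[2:10], spectrumValues(n3)[2:10],
               tolerance = 1e-9)
  # first nonzero triple of the unit sphere: area * 2/R^2 -> 8*pi
  expect_equal(mean(spectrumValues(n1)[2:4]), 8 * pi, tolerance = 0.01)
  expect_equal(spectrumValues(n1)[1], 0)
  expect_error(normalizeArea(n1), "already")
  expect_error(normalizeArea(sp1, area = -1), "positive")
})

test_that("volume normalization is identity at v = 1 and radius-invariant
           for spheres", {
  sp <- computeSpectrum(icosphere(2), k = 8)
  expect_equal(spectrumValues(normalizeVolume(sp, volume = 1)),
               spectrumValues(sp))
  v1 <- spectrumValues(normalizeVolume(computeSpectrum(icosphere(3, 1),
                                                       k = 8)))
  v2 <- spectrumValues(normalizeVolume(computeSpectrum(icosphere(3, 2),
                                                       k = 8)))
  expect_equal(v1[2:8], v2[2:8], tolerance = 1e-9)
  expect_error(normalizeVolume(sp, volume = 0), "positive")
})

test_that("area normalization aligns Weyl slopes where volume
           normalization does not", {
  shapes <- list(c(1, 1, 1), c(1.8, 1, 1 / 1.8))   # equal enclosed volume
  slopes <- vapply(shapes, function(ax) {
    sp <- computeSpectrum(ellipsoidMesh(ax[1], ax[2], ax[3], 3), k = 40,
                          method = "arpack")
    va <- spectrumValues(normalizeArea(sp))
    vv <- spectrumValues(normalizeVolume(sp))
    n <- 15:40
    c(area = unname(coef(lm(va[n] ~ n))[2]),
      vol = unname(coef(lm(vv[n] ~ n))[2]))
  }, numeric(2))
  spread <- function(x) abs(diff(x)) / mean(x)
  expect_lt(spread(slopes["area", ]), 0.05)
  expect_gt(spread(slopes["vol", ]), 2 * spread(slopes["area", ]))
})
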