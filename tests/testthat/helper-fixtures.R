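# Shared fixtures, all built in code. Expensive spectra are cached per
# test run in `.fixcache`.

.fixcache <- new.env(parent = emptyenv())

memoFix <- function(name, expr) {
  if (!exists(name, envir = .fixcache)) assign(name, expr, .fixcache)
  get(name, envir = .fixcache)
}

tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  TriangleMesh(v, f)
}

cubeMesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  dimnames(v) <- NULL
  # 12 triangles, outward orientation fixed by repairOrientation
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0
             c(5, 6, 7), c(6, 8, 7),   # z = 1
             c(1, 2, 5), c(2, 6, 5),   # y = 0
             c(3, 7, 4), c(4, 7, 8),   # y = 1
             c(1, 5, 3), c(3, 5, 7),   # x = 0
             c(2, 4, 6), c(4, 8, 6))   # x = 1
  suppressWarnings(repairOrientation(TriangleMesh(v, f)))
}

torusMesh <- function(nu = 16, nv = 10, R = 2, r = 0.7) {
  iu <- rep(seq_len(nu) - 1L, times = nv)
  iv <- rep(seq_len(nv) - 1L, each = nu)
  th <- 2 * pi * iu / nu; ph <- 2 * pi * iv / nv
  v <- cbind((R + r * cos(ph)) * cos(th),
             (R + r * cos(ph)) * sin(th),
             r * sin(ph))
  idx <- function(i, j) (j %% nv) * nu + (i %% nu) + 1L
  f <- NULL
  for (j in 0:(nv - 1L)) for (i in 0:(nu - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    c_ <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
    f <- rbind(f, c(a, b, d), c(a, d, c_))
  }
  suppressWarnings(repairOrientation(TriangleMesh(v, f)))
}

# small signal cohort used by several identifiability tests: direct
# feature simulation (subject signal in indices 2..25, noise everywhere)
featureCohort <- function(N = 20, k = 150, signalSD = 1, noiseSD = 0.3,
                          seed = 1, signalIdx = 2:25,
                          fineNoiseSD = noiseSD) {
  set.seed(seed)
  sig <- matrix(0, N, k)
  sig[, signalIdx] <- rnorm(N * length(signalIdx), 0, signalSD)
  # session noise; fineNoiseSD > noiseSD emulates the growth of
  # measurement noise at fine spatial scales
  nsd <- rep(noiseSD, k)
  nsd[seq_len(k) > max(signalIdx)] <- fineNoiseSD
  t1 <- sig + matrix(rnorm(N * k, 0, rep(nsd, each = N)), N, k)
  t2 <- sig + matrix(rnorm(N * k, 0, rep(nsd, each = N)), N, k)
  t1[, 1] <- 0; t2[, 1] <- 0      # constant near-zero first mode
  list(t1 = t1, t2 = t2)
}

sphere5Spectrum <- function() memoFix("sphere5", {
  computeSpectrum(icosphere(5), k = 310, degree = 1, method = "arpack")
})

meshCohortSAS <- function() memoFix("meshCohort", {
  spec <- cohortSpec(n_subjects = 12, n_sessions = 2, subject_sd = 1,
                     asym_sd = 1, session_sd = 0.15, scale_band = 2:6,
                     noise_band = 1:10, subdivisions = 3, seed = 7)
  st <- computeSpectraTable(generateCohort(spec), k = 100,
                            normalization = "area")
  sas <- sasTable(st)
  info <- spectraInfo(sas)
  list(t1 = spectraValues(sas)[info$session == "t1", , drop = FALSE],
       t2 = spectraValues(sas)[info$session == "t2", , drop = FALSE],
       spectra = st)
})
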