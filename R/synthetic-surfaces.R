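# Synthetic closed genus-0 surfaces and cohorts with known ground truth:
# icospheres, ellipsoids, random radial spherical-harmonic perturbations,
# longitudinal two-hemisphere cohorts, and twin-structured phenotypes.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Icosphere: subdivided icosahedron projected to a sphere
#'
#' Closed genus-0 triangulation of the sphere with 10 * 4^s + 2 vertices
#' at subdivision level s, all at distance \code{radius} from the origin,
#' consistently oriented with outward normals.
#'
#' @param subdivisions number of 4-to-1 subdivision rounds (>= 0).
#' @param radius sphere radius in mm (> 0).
#' @return A \linkS4class{TriangleMesh}.
#' @examples
#' nVertices(icosphere(3))  # 642
#' @export
icosphere <- function(subdivisions = 2, radius = 1) {
  if (radius <= 0) stop("radius must be positive")
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L) stop("subdivisions must be >= 0")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11),
             c(1, 11, 12), c(2, 6, 10), c(6, 12, 5), c(12, 11, 3),
             c(11, 8, 7), c(8, 2, 9), c(4, 10, 5), c(4, 5, 3),
             c(4, 3, 7), c(4, 7, 9), c(4, 9, 10), c(5, 10, 6),
             c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    ePairs <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    lo <- pmin(ePairs[, 1], ePairs[, 2])
    hi <- pmax(ePairs[, 1], ePairs[, 2])
    key <- (as.double(lo) - 1) * nv + as.double(hi)
    uk <- unique(key)
    mid <- nv + match(key, uk)
    # midpoint coordinates for unique edges, projected to the sphere
    first <- match(uk, key)
    mv <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
    mv <- mv / sqrt(rowSums(mv^2))
    v <- rbind(v, mv)
    nf <- nrow(f)
    m12 <- mid[seq_len(nf)]
    m23 <- mid[nf + seq_len(nf)]
    m31 <- mid[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  mesh <- TriangleMesh(v * radius, f,
                       metadata = list(kind = "icosphere",
                                       subdivisions = subdivisions,
                                       radius = radius))
  suppressWarnings(repairOrientation(mesh))
}

#' Ellipsoid mesh from an anisotropically scaled icosphere
#'
#' @param a,b,c semi-axes in mm (> 0).
#' @param subdivisions icosphere subdivision level.
#' @return A \linkS4class{TriangleMesh}.
#' @export
ellipsoidMesh <- function(a = 1, b = 1, c = 1, subdivisions = 2) {
  if (a <= 0 || b <= 0 || c <= 0) stop("semi-axes must be positive")
  mesh <- icosphere(subdivisions, 1)
  mesh@vertices <- mesh@vertices %*% diag(c(a, b, c))
  mesh@metadata <- list(kind = "ellipsoid", axes = c(a, b, c),
                        subdivisions = subdivisions)
  mesh
}

# real orthonormal spherical harmonics of degree l at unit directions;
# returns an n x (2l+1) matrix (orders m = -l..l)
.realSH <- function(l, dirs) {
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  P <- t(pracma::legendre(l, ct))      # n x (l+1), orders m = 0..l
  n <- nrow(dirs)
  out <- matrix(0, n, 2L * l + 1L)
  for (m in 0:l) {
    N <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    if (m == 0L) {
      out[, l + 1L] <- N * P[, 1L]
    } else {
      out[, l + 1L + m] <- sqrt(2) * N * P[, m + 1L] * cos(m * phi)
      out[, l + 1L - m] <- sqrt(2) * N * P[, m + 1L] * sin(m * phi)
    }
  }
  out
}

# random radial field at mesh vertices; per-degree amplitude = RMS radial
# displacement (mm) contributed by that degree, split evenly over its
# 2l+1 coefficients
.randomHarmonicField <- function(mesh, amplitudes) {
  v <- mesh@vertices
  dirs <- v / sqrt(rowSums(v^2))
  field <- numeric(nrow(v))
  for (l in seq_along(amplitudes)) {
    amp <- amplitudes[[l]]
    if (amp <= 0) next
    nc <- 2L * l + 1L
    coefSD <- amp * sqrt(4 * pi / nc)
    coef <- rnorm(nc, 0, coefSD)
    field <- field + as.numeric(.realSH(l, dirs) %*% coef)
  }
  field
}

#' Perturb a star-shaped mesh with a random spherical-harmonic field
#'
#' Displaces every vertex radially by a random field whose degree-l part
#' has i.i.d. coefficients with standard deviation set by
#' \code{amplitudes[l]} (interpreted as the RMS radial displacement, in
#' mm, contributed by degree l). Deterministic given \code{seed}.
#'
#' @param mesh a star-shaped (about the origin) \linkS4class{TriangleMesh}.
#' @param amplitudes numeric vector; element l is the amplitude of
#'   spherical-harmonic degree l (degree 0 is never perturbed).
#' @param seed RNG seed (NULL uses the current RNG state).
#' @return The perturbed \linkS4class{TriangleMesh}.
#' @export
perturbWithHarmonics <- function(mesh, amplitudes, seed = NULL) {
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  field <- .withSeed(seed, .randomHarmonicField(mesh, amplitudes))
  .displaceRadially(mesh, field)
}

.displaceRadially <- function(mesh, field) {
  v <- mesh@vertices
  r <- sqrt(rowSums(v^2))
  newr <- r + field
  if (any(newr <= 0))
    stop("radial displacement drives ", sum(newr <= 0),
         " vertex radii to <= 0")
  mesh@vertices <- v * (newr / r)
  mesh
}

.mirrorMesh <- function(mesh) {
  mesh@vertices[, 1] <- -mesh@vertices[, 1]
  mesh@faces <- mesh@faces[, c(1L, 3L, 2L)]  # restore outward orientation
  mesh
}

#' Cohort specification for synthetic longitudinal surfaces
#'
#' Amplitudes are RMS radial displacements in mm (see
#' \code{\link{perturbWithHarmonics}}). The subject and asymmetry fields
#' live on \code{scale_band} degrees; session noise is broadband
#' (\code{noise_band}).
#'
#' @param n_subjects number of subjects.
#' @param n_sessions number of imaging sessions (>= 2).
#' @param subject_sd amplitude of the subject-specific field shared by
#'   both hemispheres (mm).
#' @param asym_sd amplitude of each hemisphere-specific (asymmetry) field
#'   (mm).
#' @param session_sd amplitude of per-session noise fields (mm).
#' @param scale_band integer degrees carrying subject/asymmetry signal.
#' @param seed RNG seed.
#' @param subdivisions icosphere resolution of the base sphere.
#' @param radius base sphere radius (mm); the default matches the
#'   equivalent-sphere radius of an average human hemisphere.
#' @param noise_band integer degrees of the session-noise field.
#' @return A validated list of class "CohortSpec".
#' @export
cohortSpec <- function(n_subjects = 10, n_sessions = 2, subject_sd = 2,
                       asym_sd = 1, session_sd = 0.2, scale_band = 2:6,
                       seed = 1, subdivisions = 4, radius = 67,
                       noise_band = 1:12) {
  if (n_sessions < 2) stop("n_sessions must be >= 2")
  if (any(c(subject_sd, asym_sd, session_sd) < 0))
    stop("amplitudes must be >= 0")
  if (any(scale_band < 1)) stop("scale_band degrees must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 subject_sd = subject_sd, asym_sd = asym_sd,
                 session_sd = session_sd, scale_band = as.integer(scale_band),
                 seed = seed, subdivisions = as.integer(subdivisions),
                 radius = radius, noise_band = as.integer(noise_band)),
            class = "CohortSpec")
}

#' Generate a synthetic longitudinal two-hemisphere cohort
#'
#' Each hemisphere mesh is a base sphere displaced by (i) a
#' subject-specific field shared by both hemispheres, (ii) a
#' hemisphere-specific field scaled by \code{asym_sd}, and (iii) a
#' per-session noise field scaled by \code{session_sd}. The right
#' hemisphere is built in the same frame and then mirrored, so that with
#' \code{asym_sd = 0} and \code{session_sd = 0} the two hemispheres are
#' exactly mirror-isometric and the SAS is zero up to solver tolerance.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return Named list of \linkS4class{TriangleMesh}; names are
#'   "subject|session|hemi" with hemi in "L"/"R".
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  base <- icosphere(spec$subdivisions, spec$radius)
  maxdeg <- max(spec$scale_band, spec$noise_band)
  bandAmp <- function(band, sd) {
    a <- numeric(maxdeg)
    a[band] <- sd / sqrt(length(band))
    a
  }
  subjAmp <- bandAmp(spec$scale_band, spec$subject_sd)
  asymAmp <- bandAmp(spec$scale_band, spec$asym_sd)
  noiseAmp <- bandAmp(spec$noise_band, spec$session_sd)
  out <- list()
  .withSeed(spec$seed, {
    for (i in seq_len(spec$n_subjects)) {
      subjF <- .randomHarmonicField(base, subjAmp)
      hemiF <- list(L = .randomHarmonicField(base, asymAmp),
                    R = .randomHarmonicField(base, asymAmp))
      for (s in seq_len(spec$n_sessions)) {
        for (h in c("L", "R")) {
          noiseF <- .randomHarmonicField(base, noiseAmp)
          m <- .displaceRadially(base, subjF + hemiF[[h]] + noiseF)
          if (h == "R") m <- .mirrorMesh(m)
          m@metadata <- list(subject = sprintf("sub%03d", i),
                             session = sprintf("t%d", s), hemi = h)
          out[[sprintf("sub%03d|t%d|%s", i, s, h)]] <- m
        }
      }
    }
  })
  out
}

#' Twin cohort specification
#'
#' @param n_mz_pairs,n_dz_pairs numbers of twin-pair-only families.
#' @param n_sib_trios number of families consisting of a twin pair plus
#'   one non-twin sibling (zygosity alternates MZ/DZ across trios).
#' @param a2,c2,t2,e2 variance proportions of the additive-genetic, common
#'   environmental, twin-specific environmental and unique environmental
#'   components; must sum to 1.
#' @param seed RNG seed.
#' @return A validated list of class "TwinSpec".
#' @export
twinSpec <- function(n_mz_pairs = 100, n_dz_pairs = 100, n_sib_trios = 0,
                     a2 = 0.4, c2 = 0.2, t2 = 0, e2 = 0.4, seed = 1) {
  if (any(c(a2, c2, t2, e2) < 0) || any(c(a2, c2, t2, e2) > 1))
    stop("variance proportions must be in [0, 1]")
  if (abs(a2 + c2 + t2 + e2 - 1) > 1e-9)
    stop("variance proportions must sum to 1")
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_sib_trios = as.integer(n_sib_trios),
                 a2 = a2, c2 = c2, t2 = t2, e2 = e2, seed = seed),
            class = "TwinSpec")
}

#' Generate twin-structured phenotypes with known variance components
#'
#' Phenotype = a*G + c*C + t*T + e*E with unit-variance latent draws:
#' G is fully shared within MZ pairs and correlated 0.5 between DZ
#' co-twins and all twin-sibling/sibling pairs; C is shared within
#' family; T is shared within the twin pair only; E is unique. Age and
#' sex covariates are attached (with no effect on the phenotype by
#' default, so the stated proportions hold exactly for the raw values).
#'
#' @param spec a \code{\link{twinSpec}}.
#' @param beta_age,beta_sex optional covariate effects added to the
#'   phenotype.
#' @return A TwinCohort data.frame with columns subject, family, zygosity
#'   ("MZ"/"DZ" of the family's twin pair), role ("twin"/"sibling"), age,
#'   sex, phenotype.
#' @export
generateTwinPhenotypes <- function(spec, beta_age = 0, beta_sex = 0) {
  stopifnot(inherits(spec, "TwinSpec"))
  a <- sqrt(spec$a2); cc <- sqrt(spec$c2)
  tt <- sqrt(spec$t2); e <- sqrt(spec$e2)
  .withSeed(spec$seed, {
    rows <- list()
    fid <- 0L
    addFamily <- function(zyg, withSib) {
      fid <<- fid + 1L
      n <- if (withSib) 3L else 2L
      gFam <- rnorm(1, 0, sqrt(0.5))
      gTwinUnique <- if (zyg == "MZ") rep(rnorm(1, 0, sqrt(0.5)), 2L)
                     else rnorm(2L, 0, sqrt(0.5))
      G <- gFam + c(gTwinUnique, if (withSib) rnorm(1, 0, sqrt(0.5)))
      C <- rep(rnorm(1), n)
      Tw <- c(rep(rnorm(1), 2L), if (withSib) rnorm(1))
      E <- rnorm(n)
      age <- round(runif(n, 22, 36))
      sex <- sample(0:1, n, replace = TRUE)
      y <- a * G + cc * C + tt * Tw + e * E +
        beta_age * age + beta_sex * sex
      data.frame(subject = sprintf("fam%04d_%d", fid, seq_len(n)),
                 family = sprintf("fam%04d", fid),
                 zygosity = zyg,
                 role = c("twin", "twin", if (withSib) "sibling"),
                 age = age, sex = sex, phenotype = y,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(spec$n_mz_pairs)) rows[[length(rows) + 1L]] <-
      addFamily("MZ", FALSE)
    for (i in seq_len(spec$n_dz_pairs)) rows[[length(rows) + 1L]] <-
      addFamily("DZ", FALSE)
    for (i in seq_len(spec$n_sib_trios)) rows[[length(rows) + 1L]] <-
      addFamily(if (i %% 2L == 1L) "MZ" else "DZ", TRUE)
    do.call(rbind, rows)
  })
}
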