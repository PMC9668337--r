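# Core S4 containers. Vertex indices are 1-based throughout the package;
# on-disk conventions (0-based OFF/PLY/FreeSurfer) are converted at I/O time.

#' TriangleMesh: a triangle surface mesh
#'
#' Holds an embedded triangle surface: an n x 3 matrix of vertex
#' coordinates (mm) and an m x 3 integer matrix of 1-based vertex indices.
#' Downstream spectral operations require the mesh to be a closed, oriented
#' genus-0 2-manifold; use \code{\link{validateMesh}} to check.
#'
#' @slot vertices numeric matrix, n x 3 vertex coordinates in mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @slot metadata list, free-form provenance tags (e.g. source file).
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix", metadata = "list"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3), metadata = list()))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("faces must have 3 columns")
  if (nrow(f) > 0L) {
    if (any(!is.finite(f))) return("face indices must be finite")
    if (any(f < 1L) || any(f > nrow(v)))
      return("face indices must refer to existing vertices (1-based)")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      return("degenerate face: repeated vertex index within a face")
  }
  if (any(!is.finite(v))) return("vertex coordinates must be finite")
  TRUE
})

#' Construct a TriangleMesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param metadata optional list of provenance tags.
#' @return A \linkS4class{TriangleMesh}.
#' @examples
#' # regular tetrahedron
#' v <- rbind(c(1,1,1), c(1,-1,-1), c(-1,1,-1), c(-1,-1,1))
#' f <- rbind(c(1,3,2), c(1,2,4), c(1,4,3), c(2,3,4))
#' TriangleMesh(v, f)
#' @export
TriangleMesh <- function(vertices, faces, metadata = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  new("TriangleMesh", vertices = vertices, faces = faces,
      metadata = as.list(metadata))
}

#' @describeIn TriangleMesh-class number of vertices
#' @param mesh,object a TriangleMesh
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' @describeIn TriangleMesh-class number of faces
#' @export
nFaces <- function(mesh) nrow(mesh@faces)

#' @describeIn TriangleMesh-class vertex coordinate matrix
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @describeIn TriangleMesh-class 1-based face index matrix
#' @export
meshFaces <- function(mesh) mesh@faces

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nVertices(object), nFaces(object)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' EigenSpectrum: ascending Laplace-Beltrami eigenvalues
#'
#' The Shape-DNA descriptor of one surface: the k algebraically smallest
#' eigenvalues of the Laplace-Beltrami operator, ascending, with a
#' normalization tag. Unnormalized values have units 1/mm^2; area-normalized
#' values are dimensionless.
#'
#' @slot values numeric, ascending eigenvalues (index 1 is the ~0 mode for
#'   closed surfaces).
#' @slot normalization one of "none", "volume", "area".
#' @slot area surface area of the source mesh (mm^2; NA if unknown).
#' @slot volume enclosed volume of the source mesh (mm^3; NA if unknown).
#' @export
setClass("EigenSpectrum",
  representation(values = "numeric", normalization = "character",
                 area = "numeric", volume = "numeric"),
  prototype(values = numeric(0), normalization = "none",
            area = NA_real_, volume = NA_real_))

setValidity("EigenSpectrum", function(object) {
  if (length(object@normalization) != 1L ||
      !object@normalization %in% c("none", "volume", "area"))
    return("normalization must be one of 'none', 'volume', 'area'")
  v <- object@values
  if (any(!is.finite(v))) return("eigenvalues must be finite")
  if (is.unsorted(v, strictly = FALSE)) return("eigenvalues must be ascending")
  TRUE
})

#' @describeIn EigenSpectrum-class eigenvalues as a numeric vector
#' @param spectrum,object an EigenSpectrum
#' @export
spectrumValues <- function(spectrum) spectrum@values

#' @describeIn EigenSpectrum-class normalization tag
#' @export
spectrumNormalization <- function(spectrum) spectrum@normalization

#' @describeIn EigenSpectrum-class number of eigenvalues
#' @export
spectrumK <- function(spectrum) length(spectrum@values)

setMethod("show", "EigenSpectrum", function(object) {
  cat(sprintf("EigenSpectrum: k = %d, normalization = %s\n",
              length(object@values), object@normalization))
  k <- min(6L, length(object@values))
  if (k > 0)
    cat("  values:", paste(signif(object@values[seq_len(k)], 5),
                           collapse = ", "),
        if (length(object@values) > k) "...", "\n")
})

#' SpectraTable: per-scan spectral feature rows
#'
#' Rows keyed by (subject, session, hemisphere), columns the eigenvalue
#' (or SAS) indices 1..k, plus a normalization tag shared by all rows.
#'
#' @slot info data.frame with character columns subject, session, hemi.
#' @slot values numeric matrix, one row per scan, k columns.
#' @slot normalization normalization tag of all rows.
#' @export
setClass("SpectraTable",
  representation(info = "data.frame", values = "matrix",
                 normalization = "character"),
  prototype(info = data.frame(subject = character(0),
                              session = character(0), hemi = character(0)),
            values = matrix(numeric(0), 0, 0), normalization = "none"))

setValidity("SpectraTable", function(object) {
  if (!all(c("subject", "session", "hemi") %in% names(object@info)))
    return("info must have subject, session, hemi columns")
  if (nrow(object@info) != nrow(object@values))
    return("info and values must have the same number of rows")
  TRUE
})

#' Construct a SpectraTable
#'
#' @param info data.frame with subject, session, hemi columns.
#' @param values numeric matrix of spectral values, rows matching info.
#' @param normalization normalization tag ("none", "volume", "area", or
#'   "sas" for SAS tables).
#' @return A \linkS4class{SpectraTable}.
#' @export
SpectraTable <- function(info, values, normalization = "none") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  for (cn in c("subject", "session", "hemi"))
    info[[cn]] <- as.character(info[[cn]])
  new("SpectraTable", info = info, values = values,
      normalization = normalization)
}

#' @describeIn SpectraTable-class value matrix (rows = scans)
#' @param x,object a SpectraTable
#' @export
spectraValues <- function(x) x@values

#' @describeIn SpectraTable-class key data.frame (subject, session, hemi)
#' @export
spectraInfo <- function(x) x@info

setMethod("show", "SpectraTable", function(object) {
  cat(sprintf("SpectraTable: %d rows x %d indices, normalization = %s\n",
              nrow(object@values), ncol(object@values),
              object@normalization))
  cat(sprintf("  subjects: %d, sessions: %s, hemis: %s\n",
              length(unique(object@info$subject)),
              paste(unique(object@info$session), collapse = "/"),
              paste(unique(object@info$hemi), collapse = "/")))
})

#' SASVector: shape asymmetry signature of one subject
#'
#' Per-index left-minus-right difference of area-normalized eigenvalue
#' spectra.
#'
#' @slot values numeric vector of differences (index 1 is ~0).
#' @export
setClass("SASVector", representation(values = "numeric"),
         prototype(values = numeric(0)))

#' @describeIn SASVector-class values as numeric vector
#' @param sas,object a SASVector
#' @export
sasValues <- function(sas) sas@values

setMethod("show", "SASVector", function(object) {
  cat(sprintf("SASVector: k = %d, |max| = %.4g\n", length(object@values),
              if (length(object@values)) max(abs(object@values)) else NA))
})

#' IdentifiabilityResult: Glass's-delta subject identifiability
#'
#' @slot corr N x N Pearson matrix (rows = subjects at t1, cols at t2).
#' @slot score Glass's delta.
#' @slot withinMean mean of the diagonal.
#' @slot betweenMean mean of the off-diagonal entries.
#' @slot betweenSD sd (ddof = 1) of the off-diagonal entries.
#' @slot kUsed number of feature indices used.
#' @export
setClass("IdentifiabilityResult",
  representation(corr = "matrix", score = "numeric", withinMean = "numeric",
                 betweenMean = "numeric", betweenSD = "numeric",
                 kUsed = "integer"))

setMethod("show", "IdentifiabilityResult", function(object) {
  cat(sprintf(paste0("IdentifiabilityResult: N = %d, k = %d\n",
                     "  Glass's delta = %.3f (within %.3f, between %.3f ",
                     "+/- %.3f)\n"),
              nrow(object@corr), object@kUsed, object@score,
              object@withinMean, object@betweenMean, object@betweenSD))
})

#' SweepCurve: identifiability versus truncation number
#'
#' @slot ks integer truncations evaluated.
#' @slot scores Glass's delta per truncation.
#' @slot peakK truncation attaining the maximum score (ties -> smallest k).
#' @slot peakScore maximum score.
#' @slot groupMeans named numeric, mean score over truncations inside each
#'   eigen-group's index range.
#' @slot includeFirst whether feature index 1 was included in correlations.
#' @export
setClass("SweepCurve",
  representation(ks = "integer", scores = "numeric", peakK = "integer",
                 peakScore = "numeric", groupMeans = "numeric",
                 includeFirst = "logical"))

setMethod("show", "SweepCurve", function(object) {
  cat(sprintf("SweepCurve: k = %d..%d, peak %.3f at k = %d\n",
              min(object@ks), max(object@ks), object@peakScore,
              object@peakK))
})

#' CCAResult: canonical correlation analysis with permutation inference
#'
#' @slot cancor canonical correlations, non-increasing, in [0, 1].
#' @slot pFWER max-statistic FWER-corrected permutation p per mode.
#' @slot xLoadings data.frame per left-block variable: loading, bootSE, z,
#'   p, pFDR.
#' @slot yLoadings same for the right block.
#' @slot nPerm,nBoot iteration counts used.
#' @export
setClass("CCAResult",
  representation(cancor = "numeric", pFWER = "numeric",
                 xLoadings = "data.frame", yLoadings = "data.frame",
                 nPerm = "integer", nBoot = "integer"))

setMethod("show", "CCAResult", function(object) {
  cat("CCAResult:\n  canonical r:",
      paste(sprintf("%.3f", object@cancor), collapse = ", "),
      "\n  p_FWER:",
      paste(sprintf("%.4f", object@pFWER), collapse = ", "), "\n")
})

#' VarianceComponents: one fitted twin variance-component model
#'
#' Standardized components of the ACTE family: additive genetic (a2, the
#' heritability h2), common environment (c2), twin-specific environment
#' (t2) and unique environment (e2).
#'
#' @slot model model label, one of ACTE, ACE, ATE, CTE, TE, CE, E.
#' @slot a2,c2,t2,e2 standardized variance proportions (sum to 1).
#' @slot totalVar fitted total phenotypic variance.
#' @slot loglik maximized log-likelihood.
#' @slot nParams number of free parameters (variance components + mean).
#' @slot aic Akaike information criterion.
#' @export
setClass("VarianceComponents",
  representation(model = "character", a2 = "numeric", c2 = "numeric",
                 t2 = "numeric", e2 = "numeric", totalVar = "numeric",
                 loglik = "numeric", nParams = "integer", aic = "numeric"))

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(paste0("VarianceComponents [%s]: a2 = %.3f, c2 = %.3f, ",
                     "t2 = %.3f, e2 = %.3f\n  loglik = %.2f, AIC = %.2f\n"),
              object@model, object@a2, object@c2, object@t2, object@e2,
              object@loglik, object@aic))
})

#' @describeIn VarianceComponents-class heritability (a2) of a fit
#' @param fit a VarianceComponents object
#' @export
heritability <- function(fit) fit@a2
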