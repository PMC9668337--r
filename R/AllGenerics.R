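#' @import methods
#' @importFrom stats cor sd quantile var optim lm lm.fit resid prcomp
#'   p.adjust pnorm pchisq rnorm runif complete.cases setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

#' Surface area of a triangle mesh
#'
#' Sum of the areas of all triangular faces, in mm^2 when vertex
#' coordinates are in mm.
#'
#' @param mesh A \linkS4class{TriangleMesh}.
#' @return Numeric scalar, total surface area (> 0).
#' @examples
#' surfaceArea(icosphere(2))   # approaches 4*pi from below
#' @export
setGeneric("surfaceArea", function(mesh) standardGeneric("surfaceArea"))

#' Enclosed volume of a closed triangle mesh
#'
#' Signed divergence-theorem volume, returned positive after orientation
#' repair. Errors on open (non-closed) meshes.
#'
#' @param mesh A closed, consistently oriented \linkS4class{TriangleMesh}.
#' @return Numeric scalar, enclosed volume in mm^3.
#' @examples
#' enclosedVolume(icosphere(3))   # approaches 4*pi/3 from below
#' @export
setGeneric("enclosedVolume", function(mesh) standardGeneric("enclosedVolume"))

#' Validate mesh topology
#'
#' Checks that a mesh is a closed, oriented 2-manifold and computes its
#' genus from the Euler characteristic. Reports problems instead of
#' throwing.
#'
#' @param mesh A \linkS4class{TriangleMesh}.
#' @return A list with logical flags \code{closed}, \code{manifold},
#'   \code{oriented}, integer \code{genus} (NA when not a closed manifold),
#'   \code{boundary_edges} (index matrix of edges on a boundary) and
#'   \code{nonmanifold_edges}.
#' @export
setGeneric("validateMesh", function(mesh) standardGeneric("validateMesh"))

#' @rdname computeSpectrum
#' @export
setGeneric("computeSpectrum",
  function(mesh, k = 50, degree = 1, method = c("auto", "arpack", "dense"))
    standardGeneric("computeSpectrum"))

#' @rdname assembleFEM
#' @export
setGeneric("assembleFEM",
  function(mesh, degree = 1) standardGeneric("assembleFEM"))
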