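# Spherical-harmonic eigen-group bookkeeping. Eigenvalue indexing is
# 1-based with index 1 the (near-)zero constant mode; group L spans
# 1-based indices L^2+1 .. (L+1)^2 and holds 2(L+1)-1 = 2L+1 values.

#' Eigen-group of a 1-based eigenvalue index
#'
#' Group 0 is index 1; group 1 is indices 2-4; group 2 is 5-9; generally
#' L = ceiling(sqrt(i)) - 1.
#'
#' @param i 1-based eigenvalue index (vectorized).
#' @return Integer group degree L.
#' @export
groupOfIndex <- function(i) {
  if (any(i < 1)) stop("eigenvalue indices are 1-based (i >= 1)")
  as.integer(ceiling(sqrt(i)) - 1)
}

#' Cumulative eigenvalue count through group L
#'
#' Groups 0..L together hold (L+1)^2 eigenvalues; through group 11 that
#' is 144.
#'
#' @param L group degree (vectorized, >= 0).
#' @return Integer count (L+1)^2.
#' @export
cumulativeCount <- function(L) {
  if (any(L < 0)) stop("L must be >= 0")
  as.integer((L + 1)^2)
}

#' Spatial wavelength of an eigen-group on the equivalent sphere
#'
#' W = 2 * pi * Rs / sqrt(L * (L + 1)). For L = 0 the wavelength is
#' infinite (returned as Inf).
#'
#' @param L group degree (vectorized, >= 0).
#' @param Rs equivalent-sphere radius in mm (~67 mm for an average human
#'   hemisphere template).
#' @return Wavelength in mm (unrounded).
#' @examples
#' groupWavelength(11, 67)  # ~36.6 mm
#' @export
groupWavelength <- function(L, Rs) {
  if (any(Rs <= 0)) stop("Rs must be positive")
  if (any(L < 0)) stop("L must be >= 0")
  ifelse(L == 0, Inf, 2 * pi * Rs / sqrt(L * (L + 1)))
}

#' Equivalent-sphere radius from a surface area
#'
#' @param area surface area in mm^2 (> 0).
#' @return Radius sqrt(area / (4 * pi)) in mm.
#' @export
equivalentRadius <- function(area) {
  if (any(area <= 0)) stop("area must be positive")
  sqrt(area / (4 * pi))
}

#' Per-eigen-group means of a per-index vector
#'
#' Averages a per-index vector (SAS values, identifiability scores, ...)
#' over each group's index range; group 1 uses indices 2-4, group 11 ends
#' at index 144. The vector must cover the final group completely.
#'
#' @param values per-index numeric vector (1-based indices).
#' @param Lmax largest group degree (default 11).
#' @param Lmin smallest group degree (default 1, skipping the constant
#'   mode).
#' @return Named numeric vector of group means (names "L<degree>").
#' @export
groupMeans <- function(values, Lmax = 11, Lmin = 1) {
  if (Lmin < 0 || Lmax < Lmin) stop("need 0 <= Lmin <= Lmax")
  need <- cumulativeCount(Lmax)
  if (length(values) < need)
    stop("vector covers ", length(values), " indices; group ", Lmax,
         " needs ", need)
  Ls <- Lmin:Lmax
  out <- vapply(Ls, function(L)
    mean(values[(L^2 + 1L):((L + 1L)^2)]), numeric(1))
  names(out) <- paste0("L", Ls)
  out
}
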