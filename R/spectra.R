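# Size normalizations of eigenvalue spectra, and batch spectrum
# computation over keyed mesh collections.

#' Surface-area normalization of a spectrum
#'
#' Rescales the mesh to unit surface area, which multiplies every
#' eigenvalue by the area (scaling coordinates by s scales eigenvalues by
#' 1/s^2). Area-normalized spectra are dimensionless and size-independent.
#'
#' @param spectrum an unnormalized \linkS4class{EigenSpectrum}.
#' @param area total surface area in mm^2; defaults to the area recorded
#'   in the spectrum.
#' @return An \linkS4class{EigenSpectrum} with normalization "area".
#' @export
normalizeArea <- function(spectrum, area = spectrum@area) {
  if (spectrum@normalization != "none")
    stop("spectrum is already normalized (", spectrum@normalization, ")")
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  new("EigenSpectrum", values = area * spectrum@values,
      normalization = "area", area = spectrum@area,
      volume = spectrum@volume)
}

#' Volume normalization of a spectrum
#'
#' Classical unit-volume normalization lambda' = v^(2/D) * lambda. For
#' closed surfaces v defaults to the enclosed 3-D volume with D = 3.
#' Unlike area normalization this does not equalize the Weyl slope of
#' spectra across shapes with different area-to-volume ratios.
#'
#' @param spectrum an unnormalized \linkS4class{EigenSpectrum}.
#' @param volume the volume v; defaults to the enclosed volume recorded in
#'   the spectrum.
#' @param D manifold dimension used in the exponent (default 3).
#' @return An \linkS4class{EigenSpectrum} with normalization "volume".
#' @export
normalizeVolume <- function(spectrum, volume = spectrum@volume, D = 3) {
  if (spectrum@normalization != "none")
    stop("spectrum is already normalized (", spectrum@normalization, ")")
  if (!is.finite(volume) || volume <= 0) stop("volume must be positive")
  new("EigenSpectrum", values = volume^(2 / D) * spectrum@values,
      normalization = "volume", area = spectrum@area,
      volume = spectrum@volume)
}

#' Compute spectra for a keyed collection of meshes
#'
#' Convenience wrapper: runs \code{\link{computeSpectrum}} (and optionally
#' a normalization) over a named list of meshes as produced by
#' \code{\link{generateCohort}}, returning a \linkS4class{SpectraTable}.
#'
#' @param meshes named list of \linkS4class{TriangleMesh}; names must be
#'   "subject|session|hemi" keys (see \code{\link{generateCohort}}).
#' @param k,degree,method passed to \code{\link{computeSpectrum}}.
#' @param normalization "area", "volume", or "none".
#' @return A \linkS4class{SpectraTable} with one row per mesh.
#' @export
computeSpectraTable <- function(meshes, k = 150, degree = 1,
                                method = c("auto", "arpack", "dense"),
                                normalization = c("area", "none",
                                                  "volume")) {
  normalization <- match.arg(normalization)
  method <- match.arg(method)
  keys <- strsplit(names(meshes), "|", fixed = TRUE)
  if (any(lengths(keys) != 3L))
    stop("mesh names must be 'subject|session|hemi' keys")
  vals <- matrix(NA_real_, length(meshes), k)
  for (i in seq_along(meshes)) {
    sp <- computeSpectrum(meshes[[i]], k = k, degree = degree,
                          method = method)
    sp <- switch(normalization, area = normalizeArea(sp),
                 volume = normalizeVolume(sp), none = sp)
    vals[i, ] <- spectrumValues(sp)
  }
  info <- data.frame(subject = vapply(keys, `[[`, "", 1L),
                     session = vapply(keys, `[[`, "", 2L),
                     hemi = vapply(keys, `[[`, "", 3L),
                     stringsAsFactors = FALSE)
  SpectraTable(info, vals, normalization = normalization)
}
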