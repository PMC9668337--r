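# Shape Asymmetry Signature and regional asymmetry indices.

#' Shape Asymmetry Signature (SAS)
#'
#' Per-index difference between the area-normalized eigenvalue spectra of
#' the left and right hemisphere: Lambda_i = lambdaL_i - lambdaR_i. No
#' registration or smoothing is involved; mirroring does not change a
#' spectrum, so a mirror-symmetric brain has SAS ~ 0 at every index.
#'
#' @param left,right \linkS4class{EigenSpectrum} objects with
#'   normalization "area" and equal k.
#' @return A \linkS4class{SASVector}.
#' @export
computeSAS <- function(left, right) {
  if (!is(left, "EigenSpectrum") || !is(right, "EigenSpectrum"))
    stop("computeSAS expects two EigenSpectrum objects")
  if (left@normalization != "area" || right@normalization != "area")
    stop("SAS is defined on area-normalized spectra only")
  if (length(left@values) != length(right@values))
    stop("spectra have different k (", length(left@values), " vs ",
         length(right@values), ")")
  new("SASVector", values = left@values - right@values)
}

#' SAS table from a spectra table
#'
#' Pairs L and R rows per (subject, session) in an area-normalized
#' \linkS4class{SpectraTable} and returns per-scan SAS rows.
#'
#' @param spectra an area-normalized \linkS4class{SpectraTable} with hemi
#'   labels "L" and "R".
#' @return A \linkS4class{SpectraTable} with normalization tag "sas" and
#'   hemi "LR".
#' @export
sasTable <- function(spectra) {
  if (spectra@normalization != "area")
    stop("SAS is defined on area-normalized spectra only")
  info <- spectra@info
  keys <- paste(info$subject, info$session, sep = "|")
  uk <- unique(keys)
  out <- matrix(NA_real_, length(uk), ncol(spectra@values))
  for (i in seq_along(uk)) {
    iL <- which(keys == uk[i] & info$hemi == "L")
    iR <- which(keys == uk[i] & info$hemi == "R")
    if (length(iL) != 1L || length(iR) != 1L)
      stop("subject/session ", uk[i], " lacks exactly one L and one R row")
    out[i, ] <- spectra@values[iL, ] - spectra@values[iR, ]
  }
  parts <- strsplit(uk, "|", fixed = TRUE)
  SpectraTable(data.frame(subject = vapply(parts, `[[`, "", 1L),
                          session = vapply(parts, `[[`, "", 2L),
                          hemi = "LR", stringsAsFactors = FALSE),
               out, normalization = "sas")
}

#' Overall asymmetry level
#'
#' The sum of the SAS over an index range, plus an absolute-sum companion
#' (both are returned; neither is privileged).
#'
#' @param sas a \linkS4class{SASVector} or numeric vector.
#' @param indexRange integer indices to sum over (default: all).
#' @return Named numeric c(sum, absSum).
#' @export
overallAsymmetry <- function(sas, indexRange = NULL) {
  v <- if (is(sas, "SASVector")) sas@values else as.numeric(sas)
  if (is.null(indexRange)) indexRange <- seq_along(v)
  if (!length(indexRange)) stop("empty index range")
  if (max(indexRange) > length(v) || min(indexRange) < 1)
    stop("index range outside 1..", length(v))
  x <- v[indexRange]
  c(sum = sum(x), absSum = sum(abs(x)))
}

#' Traditional asymmetry index
#'
#' AI = (pl - pr) / (0.5 * (pl + pr)). Returns NA with an "undefined"
#' attribute where the denominator is zero. The total-size effect remains
#' in the denominator of this index, which motivates
#' \code{\link{revisedAI}}.
#'
#' @param pl,pr left and right measurement values (vectors allowed).
#' @return Numeric vector of AI values; NA where undefined.
#' @export
traditionalAI <- function(pl, pr) {
  num <- pl - pr
  den <- 0.5 * (pl + pr)
  out <- ifelse(den == 0, ifelse(num == 0, 0, NA_real_), num / den)
  und <- which(den == 0 & num != 0)
  if (length(und)) attr(out, "undefined") <- und
  out
}

#' Revised asymmetry index (mean-adjusted)
#'
#' Subtracts the subject's mean measurement M over all regions of both
#' hemispheres before forming the index:
#' RAI = ((pl - M) - (pr - M)) / (0.5 * ((pl - M) + (pr - M))).
#' Invariant to adding a constant to every region of both hemispheres,
#' removing the global-size term from the denominator.
#'
#' @param pl,pr per-region measurement vectors (equal length).
#' @return Numeric vector of RAI values; NA (flagged via the "undefined"
#'   attribute) where the adjusted denominator vanishes with a nonzero
#'   numerator (a symmetric 0/0 region is reported as 0).
#' @export
revisedAI <- function(pl, pr) {
  if (length(pl) != length(pr)) stop("pl and pr must have equal length")
  M <- mean(c(pl, pr))
  al <- pl - M; ar <- pr - M
  num <- al - ar
  den <- 0.5 * (al + ar)
  out <- ifelse(den == 0, ifelse(num == 0, 0, NA_real_), num / den)
  und <- which(den == 0 & num != 0)
  if (length(und)) attr(out, "undefined") <- und
  out
}

#' Flag cohort outliers from spectral deviations
#'
#' A scan is flagged when strictly more than \code{maxViolations} of its
#' first \code{nEigen} indices deviate from the cohort mean by more than
#' \code{sdThresh} cohort standard deviations (sample SD, ddof = 1).
#'
#' @param cohort a \linkS4class{SpectraTable} or numeric matrix
#'   (rows = scans).
#' @param nEigen number of leading indices examined (default 200).
#' @param sdThresh deviation threshold in cohort SDs (default 4).
#' @param maxViolations largest tolerated number of deviant indices
#'   (default 2; "more than two" flags).
#' @return Logical vector, one flag per row.
#' @export
qcFlagOutliers <- function(cohort, nEigen = 200, sdThresh = 4,
                           maxViolations = 2) {
  vals <- if (is(cohort, "SpectraTable")) cohort@values else
    as.matrix(cohort)
  if (nrow(vals) < 3L) stop("need at least 3 scans for cohort QC")
  if (nEigen > ncol(vals))
    stop("nEigen (", nEigen, ") exceeds available indices (", ncol(vals),
         ")")
  x <- vals[, seq_len(nEigen), drop = FALSE]
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  dev <- abs(sweep(sweep(x, 2L, mu), 2L, pmax(sdv, .Machine$double.xmin),
                   "/"))
  rowSums(dev > sdThresh) > maxViolations
}
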