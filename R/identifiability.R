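# Subject identifiability: t1-t2 Pearson correlation matrices, Glass's
# delta, truncation sweeps across spatial scales, and permutation nulls.

.featureMatrix <- function(x) {
  if (is(x, "SpectraTable")) x@values else as.matrix(x)
}

#' Between-session correlation matrix
#'
#' Entry (i, j) is the Pearson correlation between subject i's t1 feature
#' vector and subject j's t2 feature vector, across feature indices.
#' Subject ordering must match between the two matrices.
#'
#' @param F1,F2 N x k feature matrices (rows = subjects, same order).
#' @return N x N correlation matrix.
#' @export
correlationMatrix <- function(F1, F2) {
  F1 <- .featureMatrix(F1); F2 <- .featureMatrix(F2)
  if (nrow(F1) != nrow(F2)) stop("F1 and F2 must have the same N")
  if (ncol(F1) != ncol(F2)) stop("F1 and F2 must have the same k")
  v1 <- apply(F1, 1L, var); v2 <- apply(F2, 1L, var)
  if (any(v1 == 0))
    stop("zero-variance t1 feature vector for subject ", which(v1 == 0)[1])
  if (any(v2 == 0))
    stop("zero-variance t2 feature vector for subject ", which(v2 == 0)[1])
  cor(t(F1), t(F2))
}

#' Glass's delta identifiability score
#'
#' (mean within-subject correlation - mean between-subject correlation) /
#' SD of the between-subject correlations, where "within" is the diagonal
#' and "between" is all N^2 - N off-diagonal entries of the (generally
#' non-symmetric) matrix; SD uses ddof = 1.
#'
#' @param corrMat N x N correlation matrix (N >= 3).
#' @param pooled if TRUE, use the pooled SD of both groups (Cohen's-d
#'   style variant) instead of the between-group SD.
#' @return Numeric score.
#' @export
glassDelta <- function(corrMat, pooled = FALSE) {
  corrMat <- as.matrix(corrMat)
  N <- nrow(corrMat)
  if (N < 3L || ncol(corrMat) != N)
    stop("corrMat must be square with N >= 3")
  within <- diag(corrMat)
  between <- corrMat[row(corrMat) != col(corrMat)]
  sdB <- sd(between)
  if (pooled) {
    nW <- length(within); nB <- length(between)
    sdB <- sqrt(((nW - 1) * var(within) + (nB - 1) * var(between)) /
                  (nW + nB - 2))
  }
  if (sdB == 0) stop("between-subject correlations have zero SD")
  (mean(within) - mean(between)) / sdB
}

#' Identifiability of one feature set
#'
#' Convenience wrapper: correlation matrix plus Glass's delta.
#'
#' @param F1,F2 N x k feature matrices (same subject order).
#' @return An \linkS4class{IdentifiabilityResult}.
#' @export
identifiabilityScore <- function(F1, F2) {
  C <- correlationMatrix(F1, F2)
  between <- C[row(C) != col(C)]
  new("IdentifiabilityResult", corr = C, score = glassDelta(C),
      withinMean = mean(diag(C)), betweenMean = mean(between),
      betweenSD = sd(between), kUsed = ncol(.featureMatrix(F1)))
}

#' Cross-feature identifiability
#'
#' Applies the same machinery to heterogeneous feature pairs, e.g.
#' identifying a subject's left hemisphere from right-hemisphere
#' descriptors.
#'
#' @param A,B N x k feature matrices over matched subjects.
#' @return An \linkS4class{IdentifiabilityResult}.
#' @export
crossFeatureIdentifiability <- function(A, B) identifiabilityScore(A, B)

# iterate over truncations; calls fn(k, C) for each k with the Pearson
# matrix over the used feature set (features 1..k, or 2..k when the
# constant first index is excluded). Returns fn results in a list.
.truncationScan <- function(X, Y, ks, includeFirst, fn) {
  N <- nrow(X)
  Sx <- Sy <- Sxx <- Syy <- numeric(N)
  Sxy <- matrix(0, N, N)
  m <- 0L
  cur <- if (includeFirst) 0L else 1L   # features consumed so far
  out <- vector("list", length(ks))
  names(out) <- as.character(ks)
  maxk <- max(ks)
  ki <- 1L
  for (f in seq.int(cur + 1L, maxk)) {
    xf <- X[, f]; yf <- Y[, f]
    Sx <- Sx + xf; Sy <- Sy + yf
    Sxx <- Sxx + xf^2; Syy <- Syy + yf^2
    Sxy <- Sxy + tcrossprod(xf, yf)
    m <- m + 1L
    while (ki <= length(ks) && ks[ki] == f) {
      if (m < 2L) {
        out[[ki]] <- fn(ks[ki], NULL)
      } else {
        vx <- Sxx - Sx^2 / m
        vy <- Syy - Sy^2 / m
        den <- sqrt(outer(pmax(vx, 0), pmax(vy, 0)))
        C <- (Sxy - outer(Sx, Sy) / m) / den
        C[!is.finite(C)] <- NA_real_
        out[[ki]] <- fn(ks[ki], C)
      }
      ki <- ki + 1L
    }
  }
  out
}

.scoreFromCorr <- function(C) {
  if (is.null(C) || anyNA(C)) return(NA_real_)
  within <- diag(C)
  between <- C[row(C) != col(C)]
  sdB <- sd(between)
  if (!is.finite(sdB) || sdB == 0) return(NA_real_)
  (mean(within) - mean(between)) / sdB
}

#' Identifiability sweep across truncation numbers
#'
#' Recomputes Glass's delta as progressively more eigenvalue (or SAS)
#' indices are included, from truncation kMin to kMax, yielding the
#' characteristic spatial scale at which individual differences peak.
#'
#' @param t1,t2 N x k feature matrices or \linkS4class{SpectraTable}s
#'   (same subject order; one row per subject).
#' @param kMin,kMax truncation range (truncation k uses feature indices
#'   1..k).
#' @param includeFirst include the constant first index (~0 eigenvalue /
#'   SAS entry) in the correlations. Default FALSE: that entry carries no
#'   shape information and makes very small truncations degenerate;
#'   TRUE reproduces the literal first-two-eigenvalues convention, where
#'   two-point correlations are +/-1 by construction.
#' @return A \linkS4class{SweepCurve}; truncations whose correlations are
#'   undefined or degenerate get NA scores. Group means cover every
#'   eigen-group whose index range lies within [kMin, kMax].
#' @export
identifiabilitySweep <- function(t1, t2, kMin = 2, kMax = NULL,
                                 includeFirst = FALSE) {
  X <- .featureMatrix(t1); Y <- .featureMatrix(t2)
  if (nrow(X) != nrow(Y)) stop("t1 and t2 must have the same N")
  if (is.null(kMax)) kMax <- ncol(X)
  if (kMax > ncol(X) || kMax > ncol(Y))
    stop("kMax (", kMax, ") exceeds available features (", ncol(X), ")")
  kMin <- max(kMin, if (includeFirst) 2L else 2L)
  ks <- seq.int(kMin, kMax)
  scores <- unlist(.truncationScan(X, Y, ks, includeFirst,
                                   function(k, C) .scoreFromCorr(C)))
  ok <- which(!is.na(scores))
  if (!length(ok)) stop("no truncation yields a defined score")
  peakI <- ok[which.max(scores[ok])]   # which.max takes the first maximum
  Ls <- seq_len(groupOfIndex(kMax) + 1L) - 1L
  Ls <- Ls[Ls >= 1L]
  gm <- vapply(Ls, function(L) {
    lo <- L^2 + 1L; hi <- (L + 1L)^2
    if (lo < kMin || hi > kMax) return(NA_real_)
    mean(scores[ks >= lo & ks <= hi], na.rm = TRUE)
  }, numeric(1))
  names(gm) <- paste0("L", Ls)
  gm <- gm[!is.na(gm)]
  new("SweepCurve", ks = as.integer(ks), scores = as.numeric(scores),
      peakK = as.integer(ks[peakI]), peakScore = scores[peakI],
      groupMeans = gm, includeFirst = includeFirst)
}

#' Permutation null for the peak identifiability score
#'
#' Shuffles the subject order of the t2 session nPerm times; for each
#' shuffle the whole truncation sweep is recomputed and its peak score
#' recorded. The p-value compares the observed peak with the null peaks:
#' p = (#(null >= observed) + 1) / (nPerm + 1); the raw proportion
#' (which can be 0) is reported alongside.
#'
#' @param t1,t2 feature matrices or \linkS4class{SpectraTable}s.
#' @param kMax largest truncation (default: all features).
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param kMin,includeFirst as in \code{\link{identifiabilitySweep}}.
#' @return List with p, pRaw, observedPeak, observedPeakK, nullPeaks.
#' @export
permutationNull <- function(t1, t2, kMax = NULL, nPerm = 1000, seed = 1,
                            kMin = 2, includeFirst = FALSE) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  X <- .featureMatrix(t1); Y <- .featureMatrix(t2)
  N <- nrow(X)
  if (is.null(kMax)) kMax <- ncol(X)
  perms <- .withSeed(seed,
    vapply(seq_len(nPerm), function(i) sample.int(N), integer(N)))
  ks <- seq.int(max(kMin, 2L), kMax)
  idx <- matrix(seq_len(N), N, nPerm) +
    (perms - 1L) * N                       # linear index of C[i, perm[i]]
  nOff <- N^2 - N
  obs <- rep(NA_real_, length(ks))
  nullMax <- rep(-Inf, nPerm)
  step <- function(k, C) {
    if (is.null(C) || anyNA(C)) return(NULL)
    ki <- match(k, ks)
    obs[ki] <<- .scoreFromCorr(C)
    S <- sum(C); S2 <- sum(C^2)
    D <- matrix(C[idx], N, nPerm)
    dSum <- colSums(D); dSq <- colSums(D^2)
    bMean <- (S - dSum) / nOff
    bVar <- (S2 - dSq - nOff * bMean^2) / (nOff - 1)
    sc <- (dSum / N - bMean) / sqrt(pmax(bVar, 0))
    sc[!is.finite(sc)] <- -Inf
    nullMax <<- pmax(nullMax, sc)
    NULL
  }
  .truncationScan(X, Y, ks, includeFirst, step)
  ok <- which(!is.na(obs))
  observedPeak <- max(obs[ok])
  peakK <- ks[ok[which.max(obs[ok])]]
  exceed <- sum(nullMax >= observedPeak)
  list(p = (exceed + 1) / (nPerm + 1), pRaw = exceed / nPerm,
       observedPeak = observedPeak, observedPeakK = peakK,
       nullPeaks = nullMax)
}
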