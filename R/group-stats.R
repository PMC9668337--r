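# Association analyses on SAS features: block-respecting permutation GLM,
# effect sizes, FDR, and the PCA -> CCA pipeline with max-statistic FWER
# permutation inference and family-block bootstrap loadings.

#' Exchangeability blocks from family identifiers
#'
#' Subjects sharing a family id form one block; admissible permutations
#' exchange whole blocks of identical size (within-block order is kept),
#' so family structure is never broken. Singleton blocks reduce to
#' unrestricted permutation.
#'
#' @param family character/factor vector of per-subject family ids; NULL
#'   or omitted ids become singleton blocks.
#' @return Object of class "ExchangeabilityBlocks".
#' @export
exchangeabilityBlocks <- function(family) {
  family <- as.character(family)
  family[is.na(family)] <- paste0(".single", seq_len(sum(is.na(family))))
  idx <- split(seq_along(family), family)
  sizes <- lengths(idx)
  structure(list(blocks = idx, sizes = sizes, n = length(family)),
            class = "ExchangeabilityBlocks")
}

# n x nPerm matrix of block-respecting permutation index vectors
.blockPermutations <- function(blocks, nPerm, seed = NULL) {
  if (is.null(blocks)) stop("blocks must be provided")
  drawAll <- function() {
    out <- integer(blocks$n)
    for (s in unique(blocks$sizes)) {
      members <- blocks$blocks[blocks$sizes == s]
      ord <- sample.int(length(members))
      from <- unlist(members, use.names = FALSE)
      to <- unlist(members[ord], use.names = FALSE)
      out[from] <- to
    }
    out
  }
  .withSeed(seed, vapply(seq_len(nPerm), function(i) drawAll(),
                         integer(blocks$n)))
}

#' Permutation GLM for one feature
#'
#' Tests the association between a response (one SAS index) and a
#' predictor, adjusting for covariates, by permuting the predictor
#' across subjects while keeping family blocks intact (whole-block
#' exchange among blocks of identical size). Two-sided p with the +1
#' correction.
#'
#' @param y numeric response (one per subject).
#' @param predictor numeric predictor of interest (e.g. sex, EHI score).
#' @param covariates optional numeric matrix/data.frame of nuisance
#'   covariates.
#' @param blocks \code{\link{exchangeabilityBlocks}}; NULL treats every
#'   subject as a singleton block.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return List with coefficient, p, permCoefficients.
#' @export
glmPermutation <- function(y, predictor, covariates = NULL, blocks = NULL,
                           nPerm = 1000, seed = 1) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  n <- length(y)
  Z <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  if (qr(cbind(Z, predictor))$rank < ncol(Z) + 1L)
    stop("rank-deficient design")
  if (is.null(blocks)) blocks <- exchangeabilityBlocks(rep(NA, n))
  if (blocks$n != n) stop("blocks do not match the number of subjects")
  qz <- qr(Z)
  Qz <- qr.Q(qz)[, seq_len(qz$rank), drop = FALSE]
  ry <- y - Qz %*% crossprod(Qz, y)
  coefOf <- function(xcols) {
    rx <- xcols - Qz %*% crossprod(Qz, xcols)
    colSums(rx * as.numeric(ry)) / colSums(rx^2)
  }
  obs <- coefOf(cbind(predictor))
  perms <- .blockPermutations(blocks, nPerm, seed)
  Xp <- matrix(predictor[perms], n, nPerm)
  permCoef <- coefOf(Xp)
  p <- (sum(abs(permCoef) >= abs(obs)) + 1) / (nPerm + 1)
  list(coefficient = as.numeric(obs), p = p, permCoefficients = permCoef)
}

#' Cohen's d effect size
#'
#' Mean difference divided by the pooled standard deviation.
#'
#' @param groupA,groupB numeric vectors (each of length >= 2).
#' @return Numeric d (positive when groupA has the larger mean).
#' @export
cohensD <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L) stop("each group needs >= 2 observations")
  sp <- sqrt(((nA - 1) * var(groupA) + (nB - 1) * var(groupB)) /
               (nA + nB - 2))
  if (sp == 0) stop("zero pooled SD")
  (mean(groupA) - mean(groupB)) / sp
}

#' Benjamini-Hochberg FDR correction
#'
#' @param pvals numeric p-values in [0, 1].
#' @param q target false discovery rate (default 0.05).
#' @return List with logical \code{reject} and numeric \code{adjusted}
#'   (BH-adjusted p-values); empty input yields empty output.
#' @export
fdrBH <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(reject = logical(0),
                                  adjusted = numeric(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  list(reject = !is.na(adj) & adj <= q, adjusted = adj)
}

#' PCA dimensionality reduction to a variance target
#'
#' Standardizes columns and retains the smallest number of principal
#' components whose cumulative explained variance reaches the target.
#' Complete cases are required: rows with missing values must be filtered
#' by the caller first (as when subjects lacking any cognitive measure
#' are excluded).
#'
#' @param x subjects x measures numeric matrix/data.frame.
#' @param varianceTarget cumulative explained-variance target in (0, 1].
#' @return List with scores (n x m), loadings, explained (per-component
#'   proportions), m.
#' @export
pcaReduce <- function(x, varianceTarget = 0.80) {
  x <- as.matrix(x)
  if (anyNA(x))
    stop("missing values present; filter to complete cases before PCA")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(expl) >= varianceTarget - 1e-12)[1]
  list(scores = pc$x[, seq_len(m), drop = FALSE],
       loadings = pc$rotation[, seq_len(m), drop = FALSE],
       explained = expl, m = m)
}

# canonical correlations of centered blocks via orthonormal bases
.cancorCore <- function(Xc, Yc) {
  qx <- qr(Xc); qy <- qr(Yc)
  if (qx$rank < ncol(Xc) || qy$rank < ncol(Yc))
    stop("degenerate covariance: a block is rank-deficient")
  Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(qy$rank), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy))
  # canonical weights in original (centered) coordinates
  A <- backsolve(qr.R(qx), sv$u)
  B <- backsolve(qr.R(qy), sv$v)
  list(cor = pmin(sv$d, 1), Qx = Qx, Qy = Qy, A = A, B = B)
}

#' PCA + CCA association pipeline with permutation FWER and bootstrap
#' loadings
#'
#' Reduces the right-hand block (e.g. 13 cognitive measures) by PCA to a
#' cumulative-variance target, fits a canonical correlation analysis
#' against the left-hand block (e.g. 11 SAS eigen-group means), assesses
#' mode significance by block-respecting permutation with a max-statistic
#' (largest canonical correlation) FWER procedure, and estimates loading
#' reliability by family-block bootstrap: loading / bootstrap SE gives z,
#' two-sided normal p, FDR-corrected across variables within each block.
#'
#' @param x subjects x p left block (SAS eigen-group means).
#' @param y subjects x q right block (cognitive measures; complete cases).
#' @param blocks \code{\link{exchangeabilityBlocks}} or NULL (singletons).
#' @param nPerm permutation count (full-scale default 50000; reduce for
#'   quick runs).
#' @param nBoot bootstrap count (default 1000).
#' @param seed RNG seed.
#' @param varianceTarget PCA cumulative-variance target for y.
#' @param covariates optional covariates regressed out of both blocks
#'   before the CCA (default NULL, off).
#' @return A \linkS4class{CCAResult}.
#' @export
ccaPipeline <- function(x, y, blocks = NULL, nPerm = 50000, nBoot = 1000,
                        seed = 1, varianceTarget = 0.80,
                        covariates = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have matching subject rows")
  n <- nrow(x)
  red <- pcaReduce(y, varianceTarget)
  Yp <- red$scores
  if (n <= ncol(x) + ncol(Yp))
    stop("need more subjects than total features for CCA")
  if (!is.null(covariates)) {
    Z <- cbind(1, as.matrix(covariates))
    Qz <- qr.Q(qr(Z))
    x <- x - Qz %*% crossprod(Qz, x)
    Yp <- Yp - Qz %*% crossprod(Qz, Yp)
  }
  Xc <- scale(x, center = TRUE, scale = FALSE)
  Yc <- scale(Yp, center = TRUE, scale = FALSE)
  cc <- .cancorCore(Xc, Yc)
  nModes <- length(cc$cor)
  if (is.null(blocks)) blocks <- exchangeabilityBlocks(rep(NA, n))
  perms <- .blockPermutations(blocks, nPerm, seed)
  # permuting rows of the centered Y block permutes rows of its
  # orthonormal basis, so each permutation needs only a small svd
  nullMax <- vapply(seq_len(nPerm), function(i) {
    svd(crossprod(cc$Qx, cc$Qy[perms[, i], , drop = FALSE]),
        nu = 0, nv = 0)$d[1]
  }, numeric(1))
  pF <- vapply(cc$cor, function(r) (sum(nullMax >= r) + 1) / (nPerm + 1),
               numeric(1))
  pF <- cummax(pF)    # enforce step-down monotonicity across modes
  # loadings on mode 1: correlations of each input variable with the
  # canonical variate of its own block
  u1 <- as.numeric(Xc %*% cc$A[, 1])
  v1 <- as.numeric(Yc %*% cc$B[, 1])
  xLoad <- as.numeric(cor(x, u1))
  yLoad <- as.numeric(cor(y, v1))   # structure corrs of raw measures
  bootIdx <- .withSeed(seed + 1L, {
    lapply(seq_len(nBoot), function(i) {
      fams <- sample(length(blocks$blocks), replace = TRUE)
      unlist(blocks$blocks[fams], use.names = FALSE)
    })
  })
  bx <- sapply(bootIdx, function(ix) {
    ui <- as.numeric(scale(x[ix, , drop = FALSE], scale = FALSE) %*%
                       cc$A[, 1])
    suppressWarnings(as.numeric(cor(x[ix, , drop = FALSE], ui)))
  })
  byIdx <- sapply(bootIdx, function(ix) {
    vi <- as.numeric(scale(Yp[ix, , drop = FALSE], scale = FALSE) %*%
                       cc$B[, 1])
    suppressWarnings(as.numeric(cor(y[ix, , drop = FALSE], vi)))
  })
  if (is.null(dim(bx))) bx <- matrix(bx, nrow = 1)
  if (is.null(dim(byIdx))) byIdx <- matrix(byIdx, nrow = 1)
  mkLoad <- function(load, boot) {
    se <- apply(boot, 1L, sd, na.rm = TRUE)
    z <- load / se
    p <- 2 * pnorm(-abs(z))
    data.frame(loading = load, bootSE = se, z = z, p = p,
               pFDR = p.adjust(p, method = "BH"))
  }
  xl <- mkLoad(xLoad, bx)
  yl <- mkLoad(yLoad, byIdx)
  rownames(xl) <- colnames(x)
  rownames(yl) <- colnames(y)
  new("CCAResult", cancor = cc$cor, pFWER = pF, xLoadings = xl,
      yLoadings = yl, nPerm = as.integer(nPerm), nBoot = as.integer(nBoot))
}
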