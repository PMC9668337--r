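# Twin variance-component modelling: IQR outlier handling, covariate
# adjustment, direct per-family multivariate-normal maximum likelihood
# for the ACTE model family, AIC model selection, and likelihood-ratio
# tests. Expected covariances: var = a2+c2+t2+e2; cov(MZ) = a2+c2+t2;
# cov(DZ) = a2/2+c2+t2; cov(twin, sib) = cov(sib, sib) = a2/2+c2.

VC_MODELS <- c("ACTE", "ACE", "ATE", "CTE", "TE", "CE", "E")

#' IQR outlier exclusion
#'
#' Keeps values v with Q1 - 1.5*IQR < v < Q3 + 1.5*IQR (strict
#' inequalities), quartiles from \code{stats::quantile} defaults.
#' Constant data (IQR = 0) retains nothing under the strict bounds and
#' triggers a warning.
#'
#' @param values numeric vector (length >= 4).
#' @return List with \code{values} (retained) and \code{keep} (logical
#'   mask).
#' @export
excludeOutliersIQR <- function(values) {
  if (length(values) < 4L) stop("need at least 4 values")
  qs <- quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- qs[2] - qs[1]
  keep <- !is.na(values) & values > qs[1] - 1.5 * iqr &
    values < qs[2] + 1.5 * iqr
  if (!any(keep))
    warning("IQR filter removed every value (constant data?)")
  list(values = values[keep], keep = keep)
}

#' Residualize a phenotype on covariates
#'
#' Ordinary least-squares residuals of y on an intercept plus the given
#' covariates.
#'
#' @param y numeric phenotype.
#' @param covariates numeric matrix/data.frame of covariates.
#' @return Numeric residual vector (mean ~0).
#' @export
residualize <- function(y, covariates) {
  X <- cbind(1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  fit <- lm.fit(X, y)
  as.numeric(fit$residuals)
}

# split a TwinCohort data.frame into per-structure stacks:
# list(type = list(Y = matrix families x k, A, Tm)) with twins first
.familyStacks <- function(cohort) {
  need <- c("family", "zygosity", "role", "phenotype")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  stacks <- list()
  for (fam in split(cohort, cohort$family)) {
    fam <- fam[order(fam$role != "twin"), , drop = FALSE]  # twins first
    nt <- sum(fam$role == "twin")
    if (nt != 2L)
      stop("family ", fam$family[1], " does not have exactly 2 twins")
    k <- nrow(fam)
    type <- paste0(fam$zygosity[1], k)
    stacks[[type]]$Y <- rbind(stacks[[type]]$Y, fam$phenotype)
    if (is.null(stacks[[type]]$A)) {
      rA <- if (fam$zygosity[1] == "MZ") 1 else 0.5
      A <- matrix(0.5, k, k); A[1, 2] <- A[2, 1] <- rA; diag(A) <- 1
      Tm <- diag(k); Tm[1, 2] <- Tm[2, 1] <- 1
      stacks[[type]]$A <- A
      stacks[[type]]$Tm <- Tm
      stacks[[type]]$J <- matrix(1, k, k)
      stacks[[type]]$k <- k
    }
  }
  stacks
}

.vcLogLik <- function(pars, stacks, comps) {
  sig <- setNames(rep(0, 4), c("A", "C", "T", "E"))
  sig[comps] <- pars[seq_along(comps)]
  mu <- pars[length(comps) + 1L]
  ll <- 0
  for (st in stacks) {
    S <- sig["A"] * st$A + sig["C"] * st$J + sig["T"] * st$Tm +
      sig["E"] * diag(st$k)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Z <- forwardsolve(t(ch), t(st$Y - mu))
    nf <- nrow(st$Y)
    ll <- ll - 0.5 * (nf * (st$k * log(2 * pi) + logdet) + sum(Z^2))
  }
  ll
}

#' Fit one twin variance-component model by maximum likelihood
#'
#' Direct per-family multivariate-normal likelihood with non-negativity
#' constraints on the variance components (L-BFGS-B). The phenotype
#' should already be residualized on covariates (see
#' \code{\link{residualize}}); a free mean is still estimated.
#'
#' @param cohort TwinCohort data.frame (columns family, zygosity, role,
#'   phenotype); every family must contain exactly one twin pair, plus
#'   optionally one sibling.
#' @param model model label: "ACTE", "ACE", "ATE", "CTE", "TE", "CE",
#'   "E".
#' @return A \linkS4class{VarianceComponents} (standardized components
#'   sum to 1).
#' @export
fitVarianceComponents <- function(cohort, model = "ACTE") {
  model <- toupper(model)
  if (!model %in% VC_MODELS)
    stop("model must be one of: ", paste(VC_MODELS, collapse = ", "))
  stacks <- .familyStacks(cohort)
  if (length(unique(cohort$family)) < 20L)
    stop("need at least 20 families")
  comps <- strsplit(model, "")[[1]]
  zygs <- substr(names(stacks), 1, 2)
  if (any(c("A", "C", "T") %in% comps) &&
      (!any(zygs == "MZ") || !any(zygs == "DZ")))
    stop("model ", model, " needs both MZ and DZ families")
  y <- cohort$phenotype
  v0 <- var(y)
  start <- c(rep(v0 / length(comps), length(comps)), mean(y))
  lower <- c(rep(0, length(comps)), -Inf)
  lower[match("E", comps)] <- 1e-8 * v0
  opt <- optim(start, function(p) -.vcLogLik(p, stacks, comps),
               method = "L-BFGS-B", lower = lower,
               control = list(maxit = 500))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("variance-component optimizer did not converge (code ",
         opt$convergence, "): ", opt$message)
  sig <- setNames(rep(0, 4), c("A", "C", "T", "E"))
  sig[comps] <- pmax(opt$par[seq_along(comps)], 0)
  tot <- sum(sig)
  npar <- length(comps) + 1L
  ll <- -opt$value
  new("VarianceComponents", model = model,
      a2 = sig[["A"]] / tot, c2 = sig[["C"]] / tot,
      t2 = sig[["T"]] / tot, e2 = sig[["E"]] / tot,
      totalVar = tot, loglik = ll, nParams = npar,
      aic = 2 * npar - 2 * ll)
}

#' AIC model selection over variance-component fits
#'
#' Lowest AIC wins; exact ties go to the model with fewer parameters.
#'
#' @param fits list of \linkS4class{VarianceComponents}.
#' @return The selected fit.
#' @export
selectModelAIC <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  aics <- vapply(fits, function(f) f@aic, numeric(1))
  npars <- vapply(fits, function(f) as.numeric(f@nParams), numeric(1))
  fits[[order(aics, npars)[1]]]
}

#' Likelihood-ratio test between nested variance-component models
#'
#' Chi-squared test on 2 * (loglik_full - loglik_reduced) with df equal
#' to the difference in free parameter counts. With components
#' constrained non-negative the boundary null makes this conservative.
#'
#' @param full,reduced \linkS4class{VarianceComponents}; the reduced
#'   model's components must be a subset of the full model's.
#' @return p-value.
#' @export
significanceLRT <- function(full, reduced) {
  cf <- strsplit(full@model, "")[[1]]
  cr <- strsplit(reduced@model, "")[[1]]
  if (!all(cr %in% cf) || length(cr) >= length(cf))
    stop("models are not strictly nested: ", reduced@model, " vs ",
         full@model)
  stat <- max(0, 2 * (full@loglik - reduced@loglik))
  df <- full@nParams - reduced@nParams
  pchisq(stat, df = df, lower.tail = FALSE)
}

# one sibling per family at most, chosen with a fixed seed
.selectOneSibling <- function(cohort, seed = 1) {
  keep <- .withSeed(seed, {
    unlist(lapply(split(seq_len(nrow(cohort)), cohort$family),
                  function(ix) {
      sibs <- ix[cohort$role[ix] == "sibling"]
      if (length(sibs) > 1L)
        ix <- c(ix[cohort$role[ix] == "twin"], sample(sibs, 1L))
      ix
    }), use.names = FALSE)
  })
  cohort[sort(keep), , drop = FALSE]
}

#' Per-feature heritability pipeline
#'
#' For each phenotype column: IQR outlier exclusion, residualization on
#' age and sex, fits of the full ACTE model family, AIC selection,
#' likelihood-ratio tests for the A and C components (full ACTE vs the
#' model dropping that component), and FDR correction across features.
#' Full-ACTE estimates are reported alongside the AIC-selected ones for
#' robustness checks.
#'
#' @param phenotypes data.frame with a subject column plus one numeric
#'   column per feature, or a numeric matrix with rownames = subject ids.
#' @param pedigree TwinCohort-style data.frame (subject, family,
#'   zygosity, role, age, sex). Families with several siblings keep one,
#'   chosen with a fixed seed.
#' @param q FDR level (default 0.05).
#' @param models model labels to fit (default the full family).
#' @param seed seed for the sibling draw.
#' @return data.frame, one row per feature: feature, model, h2, c2, t2,
#'   e2, h2Full (ACTE), pA, pC, pA_FDR, pC_FDR, n, plus a "failures"
#'   attribute naming features whose fits failed.
#' @export
heritabilityPipeline <- function(phenotypes, pedigree, q = 0.05,
                                 models = VC_MODELS, seed = 1) {
  if (is.matrix(phenotypes))
    phenotypes <- data.frame(subject = rownames(phenotypes),
                             phenotypes, check.names = FALSE)
  ped <- .selectOneSibling(pedigree, seed)
  feats <- setdiff(names(phenotypes), "subject")
  rows <- list(); failures <- character(0)
  for (ft in feats) {
    res <- tryCatch({
      df <- merge(ped, phenotypes[, c("subject", ft)], by = "subject")
      df$phenotype <- df[[ft]]
      df <- df[!is.na(df$phenotype) & !is.na(df$age) & !is.na(df$sex), ]
      keep <- excludeOutliersIQR(df$phenotype)$keep
      df <- df[keep, , drop = FALSE]
      # drop families broken by exclusion (must keep their twin pair)
      tw <- tapply(df$role == "twin", df$family, sum)
      df <- df[df$family %in% names(tw)[tw == 2L], , drop = FALSE]
      df$phenotype <- residualize(df$phenotype,
                                  cbind(age = df$age, sex = df$sex))
      fits <- lapply(models, function(m) fitVarianceComponents(df, m))
      names(fits) <- models
      best <- selectModelAIC(fits)
      full <- fits[["ACTE"]]
      pA <- if (!is.null(full) && "CTE" %in% models)
        significanceLRT(full, fits[["CTE"]]) else NA_real_
      pC <- if (!is.null(full) && "ATE" %in% models)
        significanceLRT(full, fits[["ATE"]]) else NA_real_
      data.frame(feature = ft, model = best@model, h2 = best@a2,
                 c2 = best@c2, t2 = best@t2, e2 = best@e2,
                 h2Full = if (is.null(full)) NA_real_ else full@a2,
                 pA = pA, pC = pC, n = nrow(df),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      failures <<- c(failures, paste0(ft, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$pA_FDR <- p.adjust(out$pA, method = "BH")
    out$pC_FDR <- p.adjust(out$pC, method = "BH")
  }
  attr(out, "failures") <- failures
  out
}
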