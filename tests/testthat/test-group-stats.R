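# Permutation GLM, effect sizes, FDR, PCA, CCA pipeline.

test_that("block permutations never split a family", {
  fam <- rep(sprintf("f%02d", 1:15), each = 2)
  blocks <- exchangeabilityBlocks(fam)
  perms <- shapeAsym:::.blockPermutations(blocks, 50, seed = 1)
  for (j in c(1, 25, 50)) {
    pm <- perms[, j]
    # co-twins must stay co-assigned: permuted values of a pair come
    # from one source pair, in order
    expect_true(all(fam[pm[seq(1, 30, 2)]] == fam[pm[seq(2, 30, 2)]]))
    expect_identical(sort(pm), 1:30)
  }
  # singleton blocks reduce to unrestricted permutations
  single <- exchangeabilityBlocks(rep(NA, 10))
  expect_identical(sort(shapeAsym:::.blockPermutations(single, 1,
                                                       seed = 2)[, 1]),
                   1:10)
})

test_that("permutation GLM is calibrated under the null and powered
           under signal", {
  rej <- vapply(1:300, function(i) {
    set.seed(i)
    fam <- rep(1:30, each = 2)
    y <- rnorm(60); x <- rnorm(60); z <- rnorm(60)
    glmPermutation(y, x, covariates = z,
                   blocks = exchangeabilityBlocks(fam),
                   nPerm = 199, seed = i)$p <= 0.05
  }, logical(1))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 300)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
  # injected group difference d = 1 at n = 200
  set.seed(77)
  g <- rep(0:1, each = 100)
  y <- g + rnorm(200)
  fit <- glmPermutation(y, g, nPerm = 2000, seed = 1)
  expect_lt(fit$p, 0.001)
  expect_equal(fit$coefficient, 1, tolerance = 0.3)
  expect_error(glmPermutation(y, rep(1, 200)), "rank-deficient")
})

test_that("Cohen's d follows its closed form", {
  set.seed(3)
  a <- rnorm(50, 1, 1); b <- rnorm(50, 0, 1)
  expect_equal(cohensD(a, b), -cohensD(b, a))
  expect_equal(cohensD(c(0, 1, 2), c(1, 2, 3)), -1)   # pooled SD = 1
  expect_equal(cohensD(a, a), 0)
  expect_error(cohensD(1, 1:3), ">= 2")
})

test_that("Benjamini-Hochberg rejections match the step-up rule", {
  r <- fdrBH(c(0.01, 0.02, 0.5), q = 0.05)
  expect_identical(r$reject, c(TRUE, TRUE, FALSE))
  expect_equal(r$adjusted, c(0.03, 0.03, 0.5))
  expect_false(any(fdrBH(rep(1, 5))$reject))
  expect_true(fdrBH(0.04)$reject)
  expect_length(fdrBH(numeric(0))$reject, 0L)
  expect_error(fdrBH(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("PCA reduction stops at the variance target", {
  set.seed(9)
  n <- 300
  fac <- matrix(rnorm(n * 4), n, 4)
  # four equal-strength factors, each loading its own block of three
  # measures: every PC explains ~25%, so 3 PCs cannot reach 80%
  load <- kronecker(diag(4), matrix(1, 1, 3))
  x <- fac %*% load + matrix(rnorm(n * 12, 0, 0.05), n, 12)
  red <- pcaReduce(x, 0.80)
  expect_identical(red$m, 4L)
  expect_identical(pcaReduce(x, 1.0)$m, 12L)
  xna <- x; xna[1, 1] <- NA
  expect_error(pcaReduce(xna), "complete cases")
  # isotropic noise spreads variance evenly
  iso <- pcaReduce(matrix(rnorm(2000 * 8), 2000, 8), 1.0)
  expect_lt(max(iso$explained) / min(iso$explained), 1.3)
})

test_that("canonical correlations match stats::cancor and are affine
           invariant", {
  set.seed(4)
  x <- matrix(rnorm(120 * 5), 120, 5)
  y <- matrix(rnorm(120 * 3), 120, 3)
  cc <- shapeAsym:::.cancorCore(scale(x, scale = FALSE),
                                scale(y, scale = FALSE))
  ref <- cancor(x, y)
  expect_equal(cc$cor, ref$cor, tolerance = 1e-10)
  # invertible affine transform of a block leaves correlations unchanged
  A <- matrix(rnorm(25), 5, 5) + diag(5)
  cc2 <- shapeAsym:::.cancorCore(scale(x %*% A, scale = FALSE),
                                 scale(y, scale = FALSE))
  expect_equal(cc2$cor, cc$cor, tolerance = 1e-9)
})

test_that("CCA pipeline flags a planted SAS-cognition mode", {
  set.seed(1)
  n <- 250
  sas <- matrix(rnorm(n * 11), n, 11,
                dimnames = list(NULL, paste0("L", 1:11)))
  fac <- 0.5 * sas[, 4] + sqrt(0.75) * rnorm(n)
  cog <- sapply(1:13, function(j) 0.6 * fac + 0.8 * rnorm(n))
  res <- ccaPipeline(sas, cog, nPerm = 999, nBoot = 300, seed = 3)
  expect_lt(res@pFWER[1], 0.05)
  expect_true(all(diff(res@cancor) <= 1e-12))
  expect_true(all(res@cancor >= 0 & res@cancor <= 1))
  expect_true(res@xLoadings["L4", "pFDR"] < 0.05)
  expect_identical(which.max(abs(res@xLoadings$loading)), 4L)
  # duplicating the block yields a perfect first canonical correlation
  dup <- ccaPipeline(cog, cog, nPerm = 49, nBoot = 2, seed = 1,
                     varianceTarget = 0.6)
  expect_equal(dup@cancor[1], 1, tolerance = 1e-8)
  expect_error(ccaPipeline(sas[1:10, ], cog[1:10, ]), "more subjects")
})

test_that("CCA permutation p-values are invariant to joint subject
           reordering", {
  set.seed(6)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4); y <- matrix(rnorm(n * 3), n, 3)
  r1 <- ccaPipeline(x, y, nPerm = 199, nBoot = 2, seed = 5,
                    varianceTarget = 1)
  pm <- sample(n)
  r2 <- ccaPipeline(x[pm, ], y[pm, ], nPerm = 199, nBoot = 2, seed = 5,
                    varianceTarget = 1)
  expect_equal(r1@cancor, r2@cancor, tolerance = 1e-9)
  # p-values agree up to permutation Monte-Carlo noise
  expect_lt(max(abs(r1@pFWER - r2@pFWER)), 0.08)
})
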