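# A minimal hand-built design: one intercept plus optional extra blocks.
bareDesign <- function(y, blocks = list()) {
  n <- length(y)
  blocks <- c(list(intercept = list(
    name = "intercept", X = matrix(1, n, 1, dimnames = list(NULL, "(Int)")),
    kind = "fixed_factor", df = 5)), blocks)
  computePriorScales(list(y = y, blocks = blocks, meta = list(varY = var(y))))
}

test_that("prior scales follow the variance-share rule", {
  set.seed(1)
  y <- rnorm(50)
  Xr <- matrix(rep(diag(5), 10), 50, 5, byrow = TRUE,
               dimnames = list(NULL, paste0("g", 1:5)))
  Xc <- scale(matrix(rnorm(50 * 100), 50, 100))  # column variances exactly 1
  colnames(Xc) <- paste0("f", 1:100)
  d <- list(y = y,
            blocks = list(
              grp = list(name = "grp", X = Xr, kind = "random_factor",
                         r2 = 0.1, df = 5),
              coefs = list(name = "coefs", X = Xc,
                           kind = "coefficient_matrix", r2 = 0.3, df = 5)),
            meta = list())
  d1 <- computePriorScales(d, varY = 1)
  expect_equal(d1$blocks$grp$S, 0.7)                 # 1 * 0.1 * (5+2) / 1
  expect_equal(d1$blocks$coefs$S, 0.021)             # 0.3 * 7 / 100
  expect_equal(d1$residual$S, 3.5)                   # 0.5 * 7
  # the literal one-minus-R2 reading stays available as a switch
  d2 <- computePriorScales(d, varY = 1, scaleRule = "one-minus-r2")
  expect_equal(d2$blocks$grp$S, 0.9 * 7)
  expect_equal(d2$residual$S, 0.5 * 7)
  # constant designs have no defined scale
  dBad <- d
  dBad$blocks$coefs$X <- matrix(1, 50, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(computePriorScales(dBad, varY = 1), "constant design")
})

test_that("an intercept-only chain recovers the sample mean", {
  set.seed(4)
  y <- rnorm(80, mean = 7)
  fit <- runGibbs(bareDesign(y), chainConfig(4000, 500, 2, seed = 1))
  mu <- coefMeans(fit, "intercept")
  tol <- 3 * coefSDs(fit, "intercept") / sqrt(fit@nRetained / 20)
  expect_lt(abs(mu - mean(y)), tol)
})

test_that("with clamped variances the sampler matches the closed-form ridge", {
  set.seed(42)
  n <- 60; p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.vector(X %*% rnorm(p, 0, 0.5) + rnorm(n))
  ve <- 1; vb <- 0.25
  d <- list(y = y,
            blocks = list(coefs = list(name = "coefs", X = X,
                                       kind = "coefficient_matrix",
                                       r2 = 0.3, df = 5)),
            meta = list(varY = var(y)))
  d <- computePriorScales(d)
  fit <- runGibbs(d, chainConfig(20000, 2000, 2, seed = 7),
                  fixVariances = list(coefs = vb, resid = ve))
  bhat <- coefMeans(fit, "coefs")
  ridge <- as.vector(solve(crossprod(X) + diag(ve / vb, p), crossprod(X, y)))
  # conservative Monte-Carlo SE: posterior SD over sqrt(ESS), ESS >= nRet/20
  mcse <- coefSDs(fit, "coefs") / sqrt(fit@nRetained / 20)
  expect_true(all(abs(bhat - ridge) < 3 * mcse))
  expect_lt(max(abs(bhat - ridge)), 0.05)
})

test_that("the retained-sample count is exact for any chain settings", {
  y <- rnorm(20)
  for (cc in list(c(100, 30, 7), c(64, 0, 5), c(1000, 999, 1),
                  c(500, 123, 20))) {
    fit <- runGibbs(bareDesign(y),
                    chainConfig(cc[1], cc[2], cc[3], seed = 1))
    expect_identical(fit@nRetained, as.integer((cc[1] - cc[2]) %/% cc[3]))
    expect_equal(nrow(fit@varDraws), fit@nRetained)
  }
  expect_error(chainConfig(100, 100, 5), "burnIn")
  expect_error(chainConfig(100, 98, 5), "retain")
})

test_that("chains are bit-reproducible given the seed", {
  set.seed(2)
  y <- rnorm(40)
  X <- matrix(rnorm(40 * 15), 40, 15, dimnames = list(NULL, paste0("f", 1:15)))
  d <- bareDesign(y, list(coefs = list(name = "coefs", X = X,
                                       kind = "coefficient_matrix",
                                       r2 = 0.3, df = 5)))
  f1 <- runGibbs(d, chainConfig(600, 100, 2, seed = 9))
  f2 <- runGibbs(d, chainConfig(600, 100, 2, seed = 9))
  expect_identical(coefMeans(f1, "coefs"), coefMeans(f2, "coefs"))
  expect_identical(f1@varDraws, f2@varDraws)
  f3 <- runGibbs(d, chainConfig(600, 100, 2, seed = 10))
  expect_false(identical(coefMeans(f1, "coefs"), coefMeans(f3, "coefs")))
})

test_that("shifting the response moves only the intercept", {
  set.seed(3)
  y <- rnorm(50)
  X <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(NULL, paste0("f", 1:10)))
  blk <- list(coefs = list(name = "coefs", X = X,
                           kind = "coefficient_matrix", r2 = 0.3, df = 5))
  d1 <- bareDesign(y, blk)
  d2 <- bareDesign(y + 100, blk)
  # keep identical priors so the chains are coupled draw for draw
  d2$blocks <- d1$blocks
  d2$residual <- d1$residual
  f1 <- runGibbs(d1, chainConfig(800, 200, 2, seed = 5))
  f2 <- runGibbs(d2, chainConfig(800, 200, 2, seed = 5))
  expect_equal(coefMeans(f1, "coefs"), coefMeans(f2, "coefs"),
               tolerance = 1e-8)
  expect_equal(unname(coefMeans(f2, "intercept") - coefMeans(f1, "intercept")),
               100, tolerance = 1e-6)
})

test_that("a consistent row permutation permutes nothing but the labels", {
  set.seed(6)
  n <- 45
  y <- rnorm(n)
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  blkOf <- function(M) list(coefs = list(name = "coefs", X = M,
                                         kind = "coefficient_matrix",
                                         r2 = 0.3, df = 5))
  perm <- sample(n)
  f1 <- runGibbs(bareDesign(y, blkOf(X)), chainConfig(600, 100, 2, seed = 3))
  f2 <- runGibbs(bareDesign(y[perm], blkOf(X[perm, ])),
                 chainConfig(600, 100, 2, seed = 3))
  expect_equal(coefMeans(f1, "coefs"), coefMeans(f2, "coefs"),
               tolerance = 1e-10)
})

test_that("designs reproduce the per-population effect layout", {
  fx <- sharedFixture()
  dTE <- buildDesign(fx$pre$phenotypes, model = "M", population = "TE",
                     response = "Phe", clr = fx$pre$clr$S3, timepoint = "S3")
  expect_setequal(names(dTE$blocks),
                  c("intercept", "sire", "cg", "line", "pen", "micro"))
  dNU <- buildDesign(fx$pre$phenotypes, model = "G", population = "NU",
                     response = "Phe", geno = fx$pre$genotypes)
  expect_setequal(names(dNU$blocks),
                  c("intercept", "cg", "sex", "litter", "geno"))
  expect_false("sire" %in% names(dNU$blocks))
  dMG <- buildDesign(fx$pre$phenotypes, model = "MG", population = "NU",
                     response = "PheAdg", clr = fx$pre$clr$S2,
                     geno = fx$pre$genotypes, timepoint = "S2")
  expect_true(all(c("micro", "geno") %in% names(dMG$blocks)))
  expect_false("sire" %in% names(dMG$blocks))
  # genotype columns are centred by training allele frequencies
  expect_true(all(abs(colMeans(dMG$blocks$geno$X)) < 1e-10))

  # an individual without a microbiome sample is named in the error
  victim <- fx$pre$phenotypes$id[fx$pre$phenotypes$population == "NU"][1]
  clrCut <- fx$pre$clr$S2[setdiff(rownames(fx$pre$clr$S2), victim), ]
  expect_error(buildDesign(fx$pre$phenotypes, model = "M",
                           population = "NU", response = "Phe",
                           clr = clrCut, timepoint = "S2"),
               victim)
})

test_that("posterior variance fractions recover a known genomic share", {
  set.seed(13)
  n <- 800; p <- 400
  Z <- matrix(rbinom(n * p, 2, rep(runif(p, 0.1, 0.4), each = n)), n, p,
              dimnames = list(sprintf("i%03d", 1:n), paste0("s", 1:p)))
  Zc <- scale(Z, scale = FALSE)
  g <- rnorm(p)
  u <- as.vector(Zc %*% g)
  u <- u / sd(u) * sqrt(0.4)
  y <- u + rnorm(n, 0, sqrt(0.6))
  d <- bareDesign(y, list(geno = list(name = "geno", X = Zc,
                                      kind = "coefficient_matrix",
                                      r2 = 0.3, df = 5)))
  fit <- runGibbs(d, chainConfig(2500, 500, 5, seed = 2))
  frac <- varSummary(fit)$varFrac[varSummary(fit)$parameter == "geno"]
  expect_lt(abs(frac - 0.4), 0.1)
})

test_that("omic predictions are the linear map of the posterior means", {
  fx <- sharedFixture()
  d <- buildDesign(fx$pre$phenotypes, model = "MG", population = "NU",
                   response = "Phe", clr = fx$pre$clr$S3,
                   geno = fx$pre$genotypes, timepoint = "S3")
  fit <- runGibbs(d, chainConfig(400, 100, 2, seed = 1))
  vids <- fx$pre$phenotypes$id[fx$pre$phenotypes$population == "TE"]
  clrVal <- fx$pre$clr$S3[vids, , drop = FALSE]
  genoVal <- fx$pre$genotypes[, vids]
  pred <- predictOmic(fit, clr = clrVal, geno = genoVal)
  m <- coefMeans(fit, "micro")
  g <- coefMeans(fit, "geno")
  Zv <- sweep(t(genoCalls(genoVal))[, names(g)], 2, fit@meta$snpCenter)
  manual <- as.vector(clrVal[, names(m)] %*% m) + as.vector(Zv %*% g)
  expect_equal(unname(pred[vids]), manual, tolerance = 1e-12)
  expect_identical(names(pred), vids)
  # feature mismatch is an error
  expect_error(predictOmic(fit, clr = clrVal[, -(1:3)], geno = genoVal),
               "lacks training OTU")
  # fits without omic blocks cannot predict across populations
  plain <- runGibbs(bareDesign(rnorm(30)), chainConfig(200, 50, 2, seed = 1))
  expect_error(predictOmic(plain), "no omic coefficient block")
})

test_that("non-finite responses are rejected", {
  d <- bareDesign(rnorm(30))
  d$y[4] <- NA
  expect_error(runGibbs(d, chainConfig(100, 10, 1, seed = 1)), "non-finite")
})
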