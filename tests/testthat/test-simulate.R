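test_that("pedigree has the configured family structure and is deterministic", {
  cfg <- simConfig(nSires = 28, progenyPerSireNU = 27, progenyPerSireTE = 41,
                   seed = 2)
  ped <- generatePedigree(cfg)
  expect_equal(sum(ped$population == "NU"), 28 * 27)
  expect_equal(sum(ped$population == "TE"), 28 * 41)
  expect_setequal(unique(ped$sire), sprintf("S%02d", 1:28))

  one <- generatePedigree(simConfig(nSires = 1, progenyPerSireNU = 1,
                                    progenyPerSireTE = 1, nCgNU = 1,
                                    nCgTE = 1, seed = 1))
  expect_equal(nrow(one), 2)
  expect_true(all(one$sire == "S01"))

  expect_identical(generatePedigree(cfg), generatePedigree(cfg))
})

test_that("pens are single-sire single-sex groups within the size cap", {
  cfg <- tinyCfg(seed = 7, penSize = 5)
  ped <- generatePedigree(cfg)
  byPen <- split(ped, ped$pen)
  for (p in byPen) {
    expect_lte(nrow(p), 5)
    expect_length(unique(p$sire), 1)
    expect_length(unique(p$sex), 1)
    expect_length(unique(p$population), 1)
  }
})

test_that("the only cross-population pedigree links run through the sires", {
  ped <- generatePedigree(tinyCfg(seed = 3))
  nu <- ped[ped$population == "NU", ]
  te <- ped[ped$population == "TE", ]
  expect_length(intersect(nu$dam, te$dam), 0)
  expect_length(intersect(nu$id, te$id), 0)
  expect_setequal(nu$sire, te$sire)  # shared founders
})

test_that("gene dropping is Mendelian-consistent", {
  cfg <- tinyCfg(seed = 21, nSires = 2, progenyPerSireNU = 150,
                 progenyPerSireTE = 150, nSnps = 80, missingRate = 0)
  ped <- generatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  founders <- S4Vectors::metadata(g)$founders
  S <- founders$sireGeno[, ped$sire, drop = FALSE]
  D <- founders$damGeno[, ped$dam, drop = FALSE]
  G <- genoCalls(g)[, ped$id, drop = FALSE]

  expect_true(all(G %in% 0:2))
  # forced transmissions
  expect_true(all(G[S == 0 & D == 0] == 0))
  expect_true(all(G[S == 2 & D == 2] == 2))
  # 1 x 1 matings: offspring allele count is Binomial(2, 1/2)
  het <- S == 1 & D == 1
  nCell <- sum(het)
  expect_gt(nCell, 1000)
  se <- sqrt(0.5 / nCell)
  expect_lt(abs(mean(G[het]) - 1), 3 * se)
})

test_that("OTU counts close to the sequencing depth and reproduce exactly", {
  fx <- sharedFixture()
  for (tp in c("S1", "S2", "S3")) {
    expect_true(all(colSums(otuCounts(fx$ds$microbiome[[tp]])) == 2000))
  }
  cfg <- tinyCfg(seed = 11)
  ped <- generatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  again <- simulateMicrobiome(ped, g, cfg)
  expect_identical(otuCounts(again$S2), otuCounts(fx$ds$microbiome$S2))
})

test_that("with no structure, relative abundances follow the softmax of baselines", {
  cfg <- tinyCfg(seed = 31, nSires = 3, progenyPerSireNU = 30,
                 progenyPerSireTE = 30, nOtus = 40, seqDepth = 3000,
                 microH2 = 0, microPenVar = 0, microNoiseVar = 0)
  ped <- generatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  micro <- simulateMicrobiome(ped, g, cfg)
  base <- micro$truth$baseline
  p <- exp(base - max(base)) / sum(exp(base - max(base)))
  cnt <- otuCounts(micro$S1)
  reads <- sum(cnt)
  phat <- rowSums(cnt) / reads
  se <- sqrt(p * (1 - p) / reads)
  # simultaneous multinomial bound over 40 OTUs (Bonferroni at ~0.004)
  expect_true(all(abs(phat - p) < 3.9 * se))
})

test_that("phenotypes with all signal off are pure residual noise", {
  cfg <- tinyCfg(seed = 51, nSires = 6, progenyPerSireNU = 40,
                 progenyPerSireTE = 40,
                 h2 = 0, b2 = c(S1 = 0, S2 = 0, S3 = 0),
                 varCg = 0, varPen = 0, varLitter = 0,
                 sexLineShift = c(0, 0))
  ds <- simulateDataset(cfg)
  for (pop in c("NU", "TE")) {
    idx <- ds$phenotypes$population == pop
    expect_equal(var(ds$phenotypes$y[idx]), 1, tolerance = 1e-8)
    # y is uncorrelated with the raw genomic score
    calls <- genoCalls(ds$genotypes)[, ds$phenotypes$id[idx]]
    mu <- rowMeans(calls, na.rm = TRUE)
    calls[is.na(calls)] <- mu[row(calls)[is.na(calls)]]
    u <- as.vector(crossprod(calls, ds$truth$snpEffects[[pop]]))
    expect_lt(abs(cor(ds$phenotypes$y[idx], u)), 3 / sqrt(sum(idx)))
  }
})

test_that("realised variance fractions match the configuration at scale", {
  cfg <- simConfig(seed = 41, nSnps = 300, nOtus = 120, seqDepth = 3000)
  ds <- simulateDataset(cfg)   # 28 x (27 + 41) = 1904 individuals
  rf <- ds$truth$realizedFractions
  expected <- c(cg = 0.10, group = NA, u = 0.3, mS1 = 0, mS2 = 0.10,
                mS3 = 0.25)
  for (pop in c("NU", "TE")) {
    sub <- rf[rf$population == pop, ]
    frac <- setNames(sub$fraction, sub$component)
    expected["group"] <- 0.05
    for (cc in names(expected)) {
      expect_lt(abs(frac[[cc]] - expected[[cc]]), 0.05)
    }
  }
  # regression of the phenotype on true breeding values has unit slope
  u <- ds$truth$breedingValues[ds$phenotypes$id]
  for (pop in c("NU", "TE")) {
    idx <- ds$phenotypes$population == pop
    slope <- coef(lm(ds$phenotypes$y[idx] ~ u[idx]))[2]
    expect_equal(unname(slope), 1, tolerance = 0.1)
    expect_lt(abs(var(u[idx]) / var(ds$phenotypes$y[idx]) - 0.3), 0.05)
  }
})

test_that("microbial time-point weights honour the configured gradient", {
  ds <- sharedFixture()$ds
  w <- ds$truth$microWeights
  expect_true(all(w[, "S1"] == 0))
  comp <- ds$truth$components
  for (pop in c("NU", "TE")) {
    idx <- ds$phenotypes$population == pop
    v <- c(var(comp$mS1[idx]), var(comp$mS2[idx]), var(comp$mS3[idx]))
    expect_true(all(diff(v) >= 0))
    expect_equal(v[1], 0)
  }
})

test_that("cross-system genetic correlation of 1 means shared SNP effects", {
  cfg <- tinyCfg(seed = 61, rgCrossSystem = 1)
  ds <- simulateDataset(cfg)
  expect_identical(ds$truth$snpEffects$NU, ds$truth$snpEffects$TE)
})

test_that("a dataset round-trips through the documented file set", {
  ds <- sharedFixture()$ds
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("pedigree.tsv", "genotypes.tsv", "otu_S1.tsv", "otu_S2.tsv",
           "otu_S3.tsv", "phenotypes.tsv", "truth.json")))))
  back <- readDataset(dir)
  expect_equal(back$pedigree, ds$pedigree)
  expect_equal(back$phenotypes$y, ds$phenotypes$y)
  expect_identical(otuCounts(back$microbiome$S3),
                   otuCounts(ds$microbiome$S3))
  expect_equal(genoCalls(back$genotypes), genoCalls(ds$genotypes))
  expect_equal(unlist(back$truth$otuEffects),
               unname(ds$truth$otuEffects), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("configuration errors are rejected up front", {
  expect_error(simConfig(penSize = 0), "positive")
  expect_error(simConfig(progenyPerSireNU = 0), "positive")
  expect_error(simConfig(h2 = 0.6, b2 = c(S1 = 0, S2 = 0.2, S3 = 0.4)),
               "must be < 1")
  expect_error(
    simulatePhenotypes(sharedFixture()$ds$pedigree,
                       sharedFixture()$ds$genotypes,
                       sharedFixture()$ds$microbiome[c("S1", "S2")],
                       tinyCfg(seed = 11)),
    "S3")
})
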