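test_that("SNP QC applies the call-rate, MAF and autosomal rules exactly", {
  n <- 100
  calls <- t(cbind(snp1 = snpColumn(n, 0.95, 0.30),
                   snp2 = snpColumn(n, 0.85, 0.30),
                   snp3 = snpColumn(n, 0.95, 0.02),
                   snp4 = snpColumn(n, 0.95, 0.30),
                   snp5 = snpColumn(n, 0.95, 0.30)))
  colnames(calls) <- sprintf("ind%03d", seq_len(n))
  g <- GenotypeMatrix(calls, autosomal = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  out <- snpQC(g, minCallRate = 0.90, minMaf = 0.05)
  expect_setequal(rownames(out), c("snp1", "snp5"))
  rep <- qcReport(out)
  expect_equal(rep$retained, 2)
  expect_equal(rep$lowCallRate, 1)
  expect_equal(rep$lowMaf, 1)
  expect_equal(rep$nonAutosomal, 1)
  # surviving missing entries are mean-imputed
  expect_false(anyNA(genoCalls(out)))
  expect_equal(rep$imputed, sum(is.na(calls[c(1, 5), ])))
  # boundary: MAF 0.04 is removed, call rate exactly 0.90 is kept
  oneSnp <- function(cr, maf) {
    m <- t(cbind(a = snpColumn(n, cr, maf)))
    colnames(m) <- sprintf("ind%03d", seq_len(n))
    GenotypeMatrix(m)
  }
  expect_error(snpQC(oneSnp(1, 0.04), minMaf = 0.05), "removed every SNP")
  expect_equal(nrow(snpQC(oneSnp(0.90, 0.3))), 1)
})

test_that("raising the MAF threshold never increases the retained count", {
  g <- sharedFixture()$ds$genotypes
  kept <- vapply(c(0.02, 0.05, 0.08, 0.12, 0.16),
                 function(m) nrow(snpQC(g, minMaf = m)), numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("sparse-OTU filtering keeps totals at or above the threshold", {
  cnt <- t(matrix(c(1000, 500, 799, 400, 600, 600), nrow = 2,
                  dimnames = list(c("s1", "s2"), c("A", "B", "C"))))
  tb <- OtuTable(cnt, "S1")   # totals: A 1500, B 1199, C 1200
  kept <- filterSparseOtus(tb, 1200)
  expect_setequal(rownames(kept), c("A", "C"))
  expect_equal(ncol(kept), 2)
  expect_identical(otuCounts(filterSparseOtus(tb, 0)), otuCounts(tb))
  expect_error(filterSparseOtus(tb, 5000), "removed every OTU")
  # filtering is idempotent at a fixed threshold
  expect_identical(otuCounts(filterSparseOtus(kept, 1200)), otuCounts(kept))
})

test_that("rarefaction hits the depth exactly and handles edge cases", {
  tb <- sharedFixture()$ds$microbiome$S1
  r <- rarefyCounts(tb, depth = 1500, seed = 3)
  expect_true(all(colSums(otuCounts(r)) == 1500))
  expect_identical(otuCounts(rarefyCounts(tb, 1500, seed = 3)),
                   otuCounts(r))
  # a sample already at depth is returned unchanged
  expect_identical(otuCounts(rarefyCounts(r, 1500, seed = 99)),
                   otuCounts(r))
  # single-OTU sample keeps everything in that OTU
  one <- OtuTable(matrix(20000L, 1, 1, dimnames = list("A", "s")), "S1")
  expect_equal(unname(otuCounts(rarefyCounts(one, 10000))[1, 1]), 10000)
  # shallow samples are dropped with a warning; all-shallow errors
  mix <- OtuTable(matrix(c(50L, 50L, 2000L, 2000L), 2,
                         dimnames = list(c("A", "B"), c("lo", "hi"))), "S1")
  expect_warning(out <- rarefyCounts(mix, 1000, seed = 1), "dropped")
  expect_equal(colnames(out), "hi")
  expect_error(suppressWarnings(rarefyCounts(mix, 1e6)), "below the")
})

test_that("CLR transform matches hand-computed values and its invariances", {
  tb <- OtuTable(matrix(c(4L, 4L, 2L, 8L), 2,
                        dimnames = list(c("A", "B"), c("s1", "s2"))), "S2")
  clr <- clrTransform(tb)
  expect_equal(unname(clr["s1", ]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(clr["s2", ]), c(-log(2), log(2)), tolerance = 1e-12)
  expect_equal(attr(clr, "timepoint"), "S2")

  big <- clrTransform(sharedFixture()$ds$microbiome$S3)
  expect_true(all(abs(rowSums(big)) < 1e-10 * ncol(big)))

  # scale invariance on all-positive rows
  pos <- matrix(c(3L, 6L, 9L, 2L, 4L, 10L), 3)
  dimnames(pos) <- list(c("A", "B", "C"), c("s1", "s2"))
  expect_equal(clrTransform(OtuTable(pos, "S1")),
               clrTransform(OtuTable(pos * 7L, "S1")),
               tolerance = 1e-12, ignore_attr = TRUE)

  # the pseudocount touches zero cells only
  z <- OtuTable(matrix(c(0L, 2L, 8L), 3, 1,
                       dimnames = list(c("A", "B", "C"), "s")), "S1")
  expect_equal(unname(clrTransform(z)["s", ]),
               as.vector(log(c(0.5, 2, 8)) - mean(log(c(0.5, 2, 8)))),
               tolerance = 1e-12)
  expect_error(clrTransform(OtuTable(matrix(0L, 2, 1,
                                            dimnames = list(c("A", "B"), "s")),
                                     "S1")),
               "all-zero")
})

test_that("feature spaces align to the ordered intersection", {
  m1 <- matrix(1L, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  m2 <- matrix(1L, 3, 2, dimnames = list(c("B", "C", "D"), c("t1", "t2")))
  out <- alignFeatureSpaces(list(OtuTable(m1, "S1"), OtuTable(m2, "S2")))
  expect_equal(rownames(out[[1]]), c("B", "C"))
  expect_equal(rownames(out[[2]]), c("B", "C"))
  expect_equal(attr(out, "dropped")[[1]], "A")
  m3 <- matrix(1L, 2, 2, dimnames = list(c("X", "Y"), c("u1", "u2")))
  expect_error(alignFeatureSpaces(list(OtuTable(m1, "S1"),
                                       OtuTable(m3, "S2"))),
               "empty intersection")
  same <- alignFeatureSpaces(list(OtuTable(m1, "S1"), OtuTable(m1, "S3")))
  expect_identical(otuCounts(same[[1]]), m1)
})

test_that("centre-scaling standardises within each population", {
  p <- data.frame(id = sprintf("i%02d", 1:40),
                  y = c(rnorm(20, 10, 2), rnorm(20, -5, 0.5)),
                  population = rep(c("NU", "TE"), each = 20))
  out <- centerScale(p)
  for (pop in c("NU", "TE")) {
    expect_equal(mean(out$Phe[out$population == pop]), 0, tolerance = 1e-12)
    expect_equal(sd(out$Phe[out$population == pop]), 1, tolerance = 1e-12)
  }
  pc <- p
  pc$y[pc$population == "NU"] <- 3
  expect_error(centerScale(pc), "constant")
})

test_that("phenotype adjustment removes known systematic effects", {
  set.seed(8)
  n <- 120
  p <- data.frame(id = sprintf("i%03d", 1:n),
                  population = "NU",
                  cg = sample(c("cg1", "cg2", "cg3"), n, replace = TRUE),
                  sex = sample(c("M", "F"), n, replace = TRUE))
  base <- rnorm(n)
  p$y <- base + 5 * (p$cg == "cg2") + 1.5 * (p$sex == "M")
  out <- adjustPhenotypes(centerScale(p))
  # group means equalised
  mns <- tapply(out$PheAdg, p$cg, mean)
  expect_lt(max(mns) - min(mns), 1e-10)
  # adjusted values track the structural-effect-free signal better
  expect_gt(cor(out$PheAdg, base), cor(out$Phe, base))
  # no factor structure: PheAdg is just the centred Phe
  flat <- data.frame(id = p$id, population = "NU", cg = "one", sex = "all",
                     y = p$y)
  outFlat <- adjustPhenotypes(centerScale(flat))
  expect_equal(outFlat$PheAdg, outFlat$Phe - mean(outFlat$Phe),
               tolerance = 1e-12)
  expect_error(adjustPhenotypes(p[, c("id", "population", "cg", "sex", "y")]),
               "centerScale")
})

test_that("the full preprocessing chain is reproducible and reports QC", {
  ds <- sharedFixture()$ds
  a <- suppressWarnings(preprocessDataset(ds, depth = 1700, seed = 5))
  b <- suppressWarnings(preprocessDataset(ds, depth = 1700, seed = 5))
  expect_identical(a$clr, b$clr)
  expect_equal(genoCalls(a$genotypes), genoCalls(b$genotypes))
  expect_true(a$report$snp$retained > 0)
  expect_true(all(vapply(a$report$otu, function(x) x$samplesRetained > 0,
                         logical(1))))
})
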