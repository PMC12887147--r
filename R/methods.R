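#' @include AllGenerics.R
NULL

## ---- Constructors --------------------------------------------------------

#' Build a simulation configuration
#'
#' See [SimConfig-class] for the meaning of every field. Defaults encode the
#' study design the generator emulates (28 sire families, pens of 20,
#' 66/12 contemporary groups, microbial signal absent at weaning and
#' strongest at off-test) at a desk-scale marker/OTU panel.
#'
#' @param nSires,progenyPerSireNU,progenyPerSireTE family structure.
#' @param nSnps,nOtus panel sizes (full scale: 42529 and 3001).
#' @param nCgNU,nCgTE,nMaternalLines,penSize,litterSize management structure.
#' @param h2 additive genomic variance fraction.
#' @param b2 named microbial variance fractions per time point.
#' @param varPen,varLitter,varCg grouped-effect variance fractions.
#' @param rgCrossSystem between-system genetic correlation of the trait.
#' @param microH2,heritableOtuFrac,microPenVar,microNoiseVar latent
#'   log-abundance variance structure of the microbiome.
#' @param seqDepth reads per sample.
#' @param missingRate,nonAutosomalFrac genotype QC exercise knobs.
#' @param sexLineShift fixed shifts for sex (NU) and maternal line (TE).
#' @param seed integer seed driving every generator stage.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSires = 4, progenyPerSireNU = 6, progenyPerSireTE = 8,
#'                  nSnps = 50, nOtus = 30, nCgNU = 3, nCgTE = 2)
#' cfg
#' @export
simConfig <- function(nSires = 28, progenyPerSireNU = 27,
                      progenyPerSireTE = 41,
                      nSnps = 1000, nOtus = 300,
                      nCgNU = 66, nCgTE = 12, nMaternalLines = 2,
                      penSize = 20, litterSize = 10,
                      h2 = 0.3, b2 = c(S1 = 0, S2 = 0.10, S3 = 0.25),
                      varPen = 0.05, varLitter = 0.05, varCg = 0.10,
                      rgCrossSystem = 0.8,
                      microH2 = 0.25, heritableOtuFrac = 0.3,
                      microPenVar = 0.1, microNoiseVar = 0.65,
                      seqDepth = 12000, missingRate = 0.01,
                      nonAutosomalFrac = 0, sexLineShift = c(0.25, 0.2),
                      seed = 1L) {
  b2 <- b2[c("S1", "S2", "S3")]
  new("SimConfig",
      nSires = as.integer(nSires),
      progenyPerSireNU = as.integer(progenyPerSireNU),
      progenyPerSireTE = as.integer(progenyPerSireTE),
      nSnps = as.integer(nSnps), nOtus = as.integer(nOtus),
      nCgNU = as.integer(nCgNU), nCgTE = as.integer(nCgTE),
      nMaternalLines = as.integer(nMaternalLines),
      penSize = as.integer(penSize), litterSize = as.integer(litterSize),
      h2 = h2, b2 = b2, varPen = varPen, varLitter = varLitter,
      varCg = varCg, rgCrossSystem = rgCrossSystem,
      microH2 = microH2, heritableOtuFrac = heritableOtuFrac,
      microPenVar = microPenVar, microNoiseVar = microNoiseVar,
      seqDepth = as.integer(seqDepth), missingRate = missingRate,
      nonAutosomalFrac = nonAutosomalFrac, sexLineShift = sexLineShift,
      seed = as.integer(seed))
}

#' Construct an OTU count table
#'
#' @param counts integer matrix, OTUs in rows, samples in columns, with
#'   unique dimnames.
#' @param timepoint `"S1"`, `"S2"` or `"S3"`.
#' @return An [OtuTable-class].
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 7L), 2, dimnames = list(c("OTU1", "OTU2"),
#'                                                   c("a", "b")))
#' OtuTable(m, "S2")
#' @export
OtuTable <- function(counts, timepoint = "S1") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(assays = list(counts = counts))
  metadata(se)$timepoint <- timepoint
  new("OtuTable", se)
}

#' Construct a SNP allele-count matrix
#'
#' @param calls numeric matrix, SNPs in rows, individuals in columns;
#'   entries 0/1/2 or `NA`.
#' @param autosomal logical per-SNP flag (default all `TRUE`).
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(calls, autosomal = rep(TRUE, nrow(calls))) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  se <- SummarizedExperiment(
    assays = list(calls = calls),
    rowData = DataFrame(autosomal = as.logical(autosomal)))
  new("GenotypeMatrix", se)
}

#' Build Gibbs chain settings
#'
#' @param nIter,burnIn,thin,seed see [ChainConfig-class]. Defaults are the
#'   desk-scale chain (6000/1000/5); the study-scale chain is
#'   `chainConfig(100000, 30000, 20)`.
#' @return A validated [ChainConfig-class].
#' @export
chainConfig <- function(nIter = 6000, burnIn = 1000, thin = 5, seed = 1L) {
  new("ChainConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed))
}

## ---- Accessor methods ----------------------------------------------------

#' @rdname accessors
setMethod("otuCounts", "OtuTable", function(x) assay(x, "counts"))

#' @rdname accessors
setMethod("timePoint", "OtuTable", function(x) metadata(x)$timepoint)

#' @rdname accessors
setMethod("genoCalls", "GenotypeMatrix", function(x) assay(x, "calls"))

#' @rdname accessors
setMethod("callRate", "GenotypeMatrix", function(x) {
  g <- assay(x, "calls")
  setNames(rowMeans(!is.na(g)), rownames(g))
})

#' @rdname accessors
setMethod("minorAlleleFreq", "GenotypeMatrix", function(x) {
  g <- assay(x, "calls")
  p <- rowMeans(g, na.rm = TRUE) / 2
  setNames(pmin(p, 1 - p), rownames(g))
})

#' @rdname accessors
setMethod("isAutosomal", "GenotypeMatrix", function(x) {
  setNames(rowData(x)$autosomal, rownames(x))
})

#' @rdname accessors
setMethod("qcReport", "GenotypeMatrix", function(x) metadata(x)$qc)

#' @rdname accessors
setMethod("varSummary", "PosteriorSummary", function(x) x@variances)

#' @rdname accessors
setMethod("coefMeans", "PosteriorSummary", function(x, block) {
  blk <- x@blocks[[block]]
  if (is.null(blk)) stop("no effect block named '", block, "'")
  setNames(blk$coefMean, blk$colnames)
})

#' @rdname accessors
setMethod("coefSDs", "PosteriorSummary", function(x, block) {
  blk <- x@blocks[[block]]
  if (is.null(blk)) stop("no effect block named '", block, "'")
  setNames(blk$coefSD, blk$colnames)
})

#' @rdname accessors
setMethod("foldResults", "CvResult", function(x) x@folds)

#' @rdname accessors
setMethod("meanAccuracy", "CvResult", function(x) mean(x@folds$r, na.rm = TRUE))

#' @rdname accessors
setMethod("accuracySD", "CvResult", function(x) sd(x@folds$r, na.rm = TRUE))

#' @rdname accessors
setMethod("meanRMSE", "CvResult", function(x) mean(x@folds$rmse, na.rm = TRUE))

#' @rdname accessors
setMethod("rmseSD", "CvResult", function(x) sd(x@folds$rmse, na.rm = TRUE))

#' @rdname accessors
setMethod("nullValues", "NullDistribution", function(x) x@values)

#' @rdname accessors
setMethod("nullPercentiles", "NullDistribution", function(x) x@percentiles)

## ---- show methods --------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSires, "sires;",
      object@nSires * object@progenyPerSireNU, "NU +",
      object@nSires * object@progenyPerSireTE, "TE progeny;",
      object@nSnps, "SNPs;", object@nOtus, "OTUs\n")
  cat("  variance fractions: h2 =", object@h2,
      "| b2 =", paste(names(object@b2), object@b2, sep = ":",
                      collapse = " "),
      "| cg =", object@varCg, "| pen =", object@varPen,
      "| litter =", object@varLitter, "\n")
  cat("  rg(NU,TE) =", object@rgCrossSystem,
      "| depth =", object@seqDepth, "| seed =", object@seed, "\n")
})

setMethod("show", "OtuTable", function(object) {
  cat("OtuTable (", timePoint(object), "): ", nrow(object), " OTUs x ",
      ncol(object), " samples\n", sep = "")
  callNextMethod()
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix: ", nrow(object), " SNPs x ", ncol(object),
      " individuals\n", sep = "")
  callNextMethod()
})

setMethod("show", "ChainConfig", function(object) {
  cat("ChainConfig: nIter =", object@nIter, "burnIn =", object@burnIn,
      "thin =", object@thin, "seed =", object@seed,
      "| retained =", (object@nIter - object@burnIn) %/% object@thin, "\n")
})

setMethod("show", "PosteriorSummary", function(object) {
  m <- object@meta
  cat("PosteriorSummary: model", m$model, "| population", m$population,
      "| response", m$response,
      if (!is.null(m$timepoint)) paste("| timepoint", m$timepoint), "\n")
  cat("  blocks:", paste(names(object@blocks), collapse = ", "), "\n")
  cat("  retained samples:", object@nRetained, "\n")
  print(object@variances, digits = 4)
})

setMethod("show", "FoldPlan", function(object) {
  ntr <- vapply(object@folds, function(f) length(f$train), integer(1))
  nva <- vapply(object@folds, function(f) length(f$validation), integer(1))
  cat("FoldPlan", object@strategy, object@direction, ":",
      length(object@folds), "folds; training sizes",
      paste(range(ntr), collapse = "-"), "; validation sizes",
      paste(range(nva), collapse = "-"), "\n")
})

setMethod("show", "CvResult", function(object) {
  cat("CvResult:", object@direction, "model", object@model,
      "timepoint", object@timepoint, "response", object@response,
      "strategy", object@strategy, "\n")
  cat(sprintf("  mean r = %.3f (SD %.3f), mean RMSE = %.3f (SD %.3f), %d folds\n",
              meanAccuracy(object), accuracySD(object),
              meanRMSE(object), rmseSD(object), nrow(object@folds)))
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution (", object@strategy, " structure): ", object@nPerm,
      " permutations; mean r = ", sprintf("%.4f", mean(object@values)),
      "\n  percentiles: ",
      paste(names(object@percentiles),
            sprintf("%.4f", object@percentiles), collapse = ", "),
      "\n", sep = "")
})
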