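#' @include sirelink-package.R
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---- Simulation configuration -------------------------------------------

#' Configuration of the synthetic two-system study
#'
#' Holds every knob of the synthetic-data generator: family structure of the
#' two sire-linked populations (a purebred nucleus, NU, and a crossbred
#' terminal population, TE), marker and OTU panel sizes, and the variance
#' budget of the generative phenotype model. Defaults mirror the design of
#' the real study the generator emulates: 28 founding sires, ~27 nucleus and
#' ~41 terminal progeny per sire, pens of 20 single-sire single-sex animals,
#' 66 nucleus and 12 terminal contemporary groups, and a microbial variance
#' share that is zero at weaning (S1) and grows towards off-test (S3).
#'
#' @slot nSires number of founding sires shared by the two populations.
#' @slot progenyPerSireNU,progenyPerSireTE progeny per sire family.
#' @slot nSnps,nOtus marker and OTU panel sizes (desk-scale defaults; the
#'   full-scale study used 42529 SNPs and 3001 OTUs).
#' @slot nCgNU,nCgTE number of contemporary-group levels per population.
#' @slot nMaternalLines number of commercial dam lines in TE.
#' @slot penSize maximum animals per single-sire, single-sex pen.
#' @slot litterSize nominal litter size used to group progeny by dam.
#' @slot h2 additive genomic variance fraction of the trait.
#' @slot b2 named vector (S1, S2, S3): microbial variance fraction of the
#'   trait contributed by each sampling time point.
#' @slot varPen,varLitter,varCg variance fractions of the grouped
#'   environmental effects (pen applies to TE, litter to NU).
#' @slot rgCrossSystem genetic correlation of the trait between systems;
#'   implemented by mixing shared and system-specific SNP effects.
#' @slot microH2 fraction of latent log-abundance variance under host
#'   genetic control for heritable OTUs.
#' @slot heritableOtuFrac fraction of OTUs with a host-genetic component.
#' @slot microPenVar,microNoiseVar latent log-abundance variance of the pen
#'   effect and of individual noise.
#' @slot seqDepth sequencing depth per sample (multinomial total).
#' @slot missingRate genotype missingness rate (for QC exercises).
#' @slot nonAutosomalFrac fraction of SNPs flagged non-autosomal.
#' @slot sexLineShift fixed-effect shifts for sex (NU) and maternal line (TE),
#'   in trait SD units.
#' @slot seed integer seed; all generator stages derive their streams from it.
#'
#' @seealso [simConfig()] for the user-facing constructor,
#'   [simulateDataset()] for the generator itself.
#' @export
setClass("SimConfig",
  representation(
    nSires = "integer", progenyPerSireNU = "integer",
    progenyPerSireTE = "integer",
    nSnps = "integer", nOtus = "integer",
    nCgNU = "integer", nCgTE = "integer",
    nMaternalLines = "integer", penSize = "integer", litterSize = "integer",
    h2 = "numeric", b2 = "numeric",
    varPen = "numeric", varLitter = "numeric", varCg = "numeric",
    rgCrossSystem = "numeric",
    microH2 = "numeric", heritableOtuFrac = "numeric",
    microPenVar = "numeric", microNoiseVar = "numeric",
    seqDepth = "integer", missingRate = "numeric",
    nonAutosomalFrac = "numeric", sexLineShift = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(
    nSires = object@nSires, progenyPerSireNU = object@progenyPerSireNU,
    progenyPerSireTE = object@progenyPerSireTE, nSnps = object@nSnps,
    nOtus = object@nOtus, nCgNU = object@nCgNU, nCgTE = object@nCgTE,
    nMaternalLines = object@nMaternalLines, penSize = object@penSize,
    litterSize = object@litterSize, seqDepth = object@seqDepth
  )
  if (any(counts < 1L))
    msg <- c(msg, paste("counts must be positive:",
                        paste(names(counts)[counts < 1L], collapse = ", ")))
  fr <- c(object@h2, object@b2, object@varPen, object@varLitter, object@varCg,
          object@microH2, object@heritableOtuFrac, object@missingRate,
          object@nonAutosomalFrac)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "all variance fractions and rates must lie in [0, 1]")
  if (!identical(sort(names(object@b2)), c("S1", "S2", "S3")))
    msg <- c(msg, "b2 must be named S1, S2, S3")
  if (object@h2 + max(object@b2) + object@varPen + object@varLitter >= 1)
    msg <- c(msg, "h2 + max(b2) + varPen + varLitter must be < 1")
  if (abs(object@rgCrossSystem) > 1)
    msg <- c(msg, "rgCrossSystem must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

## ---- Observation containers ---------------------------------------------

#' OTU count table for one sampling time point
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one integer `counts`
#' assay (OTUs in rows, samples in columns, following the classic OTU-table
#' orientation) and the sampling time point (`"S1"`, `"S2"` or `"S3"`) in its
#' metadata. Construct with [OtuTable()]; access with [otuCounts()] and
#' [timePoint()].
#'
#' @export
setClass("OtuTable", contains = "SummarizedExperiment")

setValidity("OtuTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(cnt) || any(!is.finite(cnt)))
    msg <- c(msg, "counts must be finite and non-missing")
  else if (any(cnt < 0))
    msg <- c(msg, "counts must be non-negative")
  else if (any(cnt != round(cnt)))
    msg <- c(msg, "counts must be integers")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "OTU ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  tp <- S4Vectors::metadata(object)$timepoint
  if (is.null(tp) || !tp %in% c("S1", "S2", "S3"))
    msg <- c(msg, "metadata timepoint must be one of S1, S2, S3")
  if (length(msg)) msg else TRUE
})

#' SNP allele-count matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `calls` assay
#' (SNPs in rows, individuals in columns; entries 0/1/2, `NA` for missing,
#' possibly fractional after mean imputation) and a logical `autosomal`
#' column in its `rowData`. Construct with [GenotypeMatrix()]; access with
#' [genoCalls()], [callRate()], [minorAlleleFreq()] and [isAutosomal()].
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  g <- SummarizedExperiment::assay(object, "calls")
  rng <- range(g, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msg <- c(msg, "allele counts must lie in [0, 2] (or NA)")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "individual ids must be present and unique")
  if (!"autosomal" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must carry an 'autosomal' flag")
  if (length(msg)) msg else TRUE
})

## ---- Model-fit containers -----------------------------------------------

#' Gibbs chain settings
#'
#' @slot nIter total iterations of the single chain.
#' @slot burnIn iterations discarded before retention starts.
#' @slot thin retain every `thin`-th post-burn-in draw.
#' @slot seed integer RNG seed for the chain.
#'
#' The study-scale settings are 100000 / 30000 / 20; the package default
#' ([chainConfig()]) is a shorter desk-scale chain of 6000 / 1000 / 5 suited
#' to the cross-validation factorial.
#'
#' @export
setClass("ChainConfig",
  representation(nIter = "integer", burnIn = "integer", thin = "integer",
                 seed = "integer"))

setValidity("ChainConfig", function(object) {
  msg <- character()
  if (object@burnIn >= object@nIter) msg <- c(msg, "burnIn must be < nIter")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@burnIn < 0L) msg <- c(msg, "burnIn must be >= 0")
  if ((object@nIter - object@burnIn) %/% object@thin < 1L)
    msg <- c(msg, "chain settings retain no samples")
  if (length(msg)) msg else TRUE
})

#' Posterior summary of one Bayesian Ridge Regression fit
#'
#' Posterior means and SDs of every effect block, retained draws of every
#' variance parameter, and the metadata needed to apply the omic solutions
#' to a validation population (feature ids and training centering constants).
#'
#' @slot blocks named list; one element per effect block with entries
#'   `name`, `kind` (`"fixed_factor"`, `"random_factor"`,
#'   `"coefficient_matrix"`), `colnames`, `coefMean`, `coefSD`.
#' @slot variances data.frame with one row per variance parameter
#'   (each block variance plus the residual): posterior mean, SD, the
#'   prior scale/df used, and the implied variance fraction for omic blocks.
#' @slot varDraws matrix of retained variance draws (columns named).
#' @slot nRetained number of retained draws, `floor((nIter-burnIn)/thin)`.
#' @slot chain the [ChainConfig-class] used.
#' @slot meta list: model kind, population, response, time point, training
#'   ids, SNP centering constants, feature id vectors, var(y).
#' @export
setClass("PosteriorSummary",
  representation(blocks = "list", variances = "data.frame",
                 varDraws = "matrix", nRetained = "integer",
                 chain = "ChainConfig", meta = "list"))

setValidity("PosteriorSummary", function(object) {
  msg <- character()
  if (object@nRetained < 1L) msg <- c(msg, "no retained samples")
  if (nrow(object@variances) &&
      any(object@variances$postMean <= 0, na.rm = TRUE))
    msg <- c(msg, "posterior variance means must be strictly positive")
  if (length(msg)) msg else TRUE
})

## ---- Cross-validation containers ----------------------------------------

#' A cross-population fold plan
#'
#' @slot strategy `"SSt"` (sire-stratified), `"SOut"` (sire family left out)
#'   or `"SNull"` (permutation null built on one of the former).
#' @slot direction `"NU-TE"` or `"TE-NU"` (training-validation order).
#' @slot folds list; each element has `train` (ids in the training
#'   population), `validation` (ids in the opposite population) and `meta`
#'   (excluded sire for SOut, repeat index for SSt).
#' @slot seed seed used to draw the folds.
#' @export
setClass("FoldPlan",
  representation(strategy = "character", direction = "character",
                 folds = "list", seed = "integer"))

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (!object@strategy %in% c("SSt", "SOut", "SNull"))
    msg <- c(msg, "strategy must be SSt, SOut or SNull")
  if (!object@direction %in% c("NU-TE", "TE-NU"))
    msg <- c(msg, "direction must be NU-TE or TE-NU")
  for (f in object@folds) {
    if (length(intersect(f$train, f$validation)))
      msg <- c(msg, "training and validation ids overlap")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Result of one scenario x strategy cross-validation run
#'
#' @slot direction,model,timepoint,response the scenario coordinates.
#' @slot strategy sampling strategy the folds came from.
#' @slot folds data.frame with one row per fold: `fold`, `r`, `rmse`,
#'   `nTrain`, `nValidation` (undefined correlations are `NA`).
#' @slot seed base seed of the run.
#' @export
setClass("CvResult",
  representation(direction = "character", model = "character",
                 timepoint = "character", response = "character",
                 strategy = "character", folds = "data.frame",
                 seed = "integer"))

#' Empirical null distribution of prediction accuracy
#'
#' @slot values per-permutation Pearson correlations between predictions
#'   from permuted-training fits and the unshuffled validation phenotypes.
#' @slot percentiles named numeric (at least `"90%"` and `"95%"`).
#' @slot strategy base strategy whose family structure was preserved.
#' @slot nPerm number of permutations.
#' @export
setClass("NullDistribution",
  representation(values = "numeric", percentiles = "numeric",
                 strategy = "character", nPerm = "integer"))

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@values) != object@nPerm)
    msg <- c(msg, "length(values) must equal nPerm")
  pp <- object@percentiles
  if (length(pp) > 1 && is.unsorted(pp[order(names(pp))]))
    msg <- c(msg, "percentiles must be monotone")
  if (length(msg)) msg else TRUE
})
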