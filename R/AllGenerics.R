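#' @include AllClasses.R
NULL

#' Accessors for sirelink containers
#'
#' Small accessor layer over the S4 containers: prefer these to direct slot
#' or assay access.
#'
#' * `otuCounts(x)`: integer count matrix (OTUs x samples) of an [OtuTable-class].
#' * `timePoint(x)`: sampling time point label of an [OtuTable-class].
#' * `genoCalls(x)`: allele-count matrix (SNPs x individuals) of a
#'   [GenotypeMatrix-class].
#' * `callRate(x)`: per-SNP fraction of non-missing calls.
#' * `minorAlleleFreq(x)`: per-SNP minor allele frequency (non-missing calls).
#' * `isAutosomal(x)`: per-SNP autosomal flag.
#' * `qcReport(x)`: QC bookkeeping attached by [snpQC()] (or `NULL`).
#' * `varSummary(x)`: variance-parameter posterior summary of a
#'   [PosteriorSummary-class].
#' * `coefMeans(x, block)` / `coefSDs(x, block)`: posterior coefficient
#'   summaries of one effect block.
#' * `foldResults(x)`: per-fold accuracy table of a [CvResult-class].
#' * `meanAccuracy(x)`, `accuracySD(x)`, `meanRMSE(x)`, `rmseSD(x)`:
#'   aggregates over folds (undefined folds dropped).
#' * `nullValues(x)`, `nullPercentiles(x)`: contents of a
#'   [NullDistribution-class].
#'
#' @param x the container.
#' @param block block name for coefficient accessors.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))
#' @rdname accessors
#' @export
setGeneric("timePoint", function(x) standardGeneric("timePoint"))
#' @rdname accessors
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))
#' @rdname accessors
#' @export
setGeneric("callRate", function(x) standardGeneric("callRate"))
#' @rdname accessors
#' @export
setGeneric("minorAlleleFreq", function(x) standardGeneric("minorAlleleFreq"))
#' @rdname accessors
#' @export
setGeneric("isAutosomal", function(x) standardGeneric("isAutosomal"))
#' @rdname accessors
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))
#' @rdname accessors
#' @export
setGeneric("varSummary", function(x) standardGeneric("varSummary"))
#' @rdname accessors
#' @export
setGeneric("coefMeans", function(x, block) standardGeneric("coefMeans"))
#' @rdname accessors
#' @export
setGeneric("coefSDs", function(x, block) standardGeneric("coefSDs"))
#' @rdname accessors
#' @export
setGeneric("foldResults", function(x) standardGeneric("foldResults"))
#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @rdname accessors
#' @export
setGeneric("accuracySD", function(x) standardGeneric("accuracySD"))
#' @rdname accessors
#' @export
setGeneric("meanRMSE", function(x) standardGeneric("meanRMSE"))
#' @rdname accessors
#' @export
setGeneric("rmseSD", function(x) standardGeneric("rmseSD"))
#' @rdname accessors
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))
#' @rdname accessors
#' @export
setGeneric("nullPercentiles", function(x) standardGeneric("nullPercentiles"))
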