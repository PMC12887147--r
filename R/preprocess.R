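#' @include simulate.R
NULL

#' SNP quality control
#'
#' Retains autosomal SNPs with call rate >= `minCallRate` and minor allele
#' frequency >= `minMaf` (the conventional 0.90 / 0.05 defaults), then
#' mean-imputes any remaining missing calls per SNP — a neutral choice for
#' ridge-type models. Removal counts per criterion are attached as a QC
#' report (see [qcReport()]): `nonAutosomal`, `lowCallRate`, `lowMaf` count
#' SNPs failing each rule (a SNP may fail several), `removed`/`retained` the
#' net effect, `imputed` the number of imputed cells.
#'
#' @param g a [GenotypeMatrix-class].
#' @param minCallRate minimum fraction of non-missing calls.
#' @param minMaf minimum minor allele frequency.
#' @return the filtered, imputed [GenotypeMatrix-class].
#' @export
snpQC <- function(g, minCallRate = 0.90, minMaf = 0.05) {
  cr <- callRate(g)
  maf <- minorAlleleFreq(g)
  auto <- isAutosomal(g)
  keep <- auto & cr >= minCallRate & !is.na(maf) & maf >= minMaf
  if (!any(keep))
    stop("SNP QC removed every SNP (minCallRate = ", minCallRate,
         ", minMaf = ", minMaf, ")")
  out <- g[keep, ]
  calls <- assay(out, "calls")
  nImp <- sum(is.na(calls))
  if (nImp > 0) {
    mu <- rowMeans(calls, na.rm = TRUE)
    calls[is.na(calls)] <- mu[row(calls)[is.na(calls)]]
    SummarizedExperiment::assay(out, "calls") <- calls
  }
  metadata(out)$qc <- list(
    nonAutosomal = sum(!auto),
    lowCallRate = sum(cr < minCallRate),
    lowMaf = sum(is.na(maf) | maf < minMaf),
    removed = sum(!keep), retained = sum(keep), imputed = nImp,
    minCallRate = minCallRate, minMaf = minMaf)
  out
}

#' Drop sparse OTUs
#'
#' Removes OTUs whose total observation count across all samples is below
#' `minTotal` (retention is `>=`). The full-scale study threshold is 1200;
#' [scaleMinTotal()] rescales it to a smaller synthetic table.
#'
#' @param t an [OtuTable-class].
#' @param minTotal minimum total count for an OTU to be retained.
#' @return the filtered [OtuTable-class]; the sample set is unchanged.
#' @export
filterSparseOtus <- function(t, minTotal) {
  totals <- rowSums(otuCounts(t))
  keep <- totals >= minTotal
  if (!any(keep))
    stop("minimum total count ", minTotal, " removed every OTU (max total ",
         max(totals), ")")
  t[keep, ]
}

#' Depth-scaled sparse-OTU threshold
#'
#' The printed minimum-total threshold of 1200 belongs to a study of ~1910
#' samples rarefied to 10,000 reads; for a synthetic table with a different
#' total read mass the comparable threshold scales proportionally.
#'
#' @param t an [OtuTable-class].
#' @param fullScaleMin threshold at full scale (default 1200).
#' @param fullScaleReads total read mass it refers to (default 1910 x 10000).
#' @return integer threshold, at least 1.
#' @export
scaleMinTotal <- function(t, fullScaleMin = 1200, fullScaleReads = 1.91e7) {
  max(1L, as.integer(round(fullScaleMin * sum(otuCounts(t)) / fullScaleReads)))
}

#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (via [vegan::rrarefy()]); samples with fewer than `depth` reads are
#' dropped with a warning rather than partially kept. Deterministic given
#' `seed`. Rarefying an already-rarefied table at the same depth is the
#' identity.
#'
#' @param t an [OtuTable-class].
#' @param depth target reads per sample (study default 10000).
#' @param seed RNG seed.
#' @return the rarefied [OtuTable-class].
#' @export
rarefyCounts <- function(t, depth = 10000, seed = 1L) {
  stopifnot(depth > 0)
  totals <- colSums(otuCounts(t))
  keep <- totals >= depth
  if (!any(keep))
    stop("every sample is below the rarefaction depth ", depth)
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(head(colnames(t)[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ...")
  t <- t[, keep]
  set.seed(seed)
  rar <- t(vegan::rrarefy(t(otuCounts(t)), sample = depth))
  OtuTable(rar, timepoint = timePoint(t))
}

#' Centered-log-ratio transform of an OTU table
#'
#' Per sample: add `pseudocount` to zero cells only (positive counts are
#' preserved exactly), take logs, and center by the sample's mean log, so
#' every row of the result sums to zero. The transform is scale-invariant
#' for all-positive samples.
#'
#' @param t an [OtuTable-class].
#' @param pseudocount value substituted for zero counts (default 0.5).
#' @return numeric matrix, samples x OTUs, with a `"timepoint"` attribute.
#' @export
clrTransform <- function(t, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  out <- .clrCore(t(otuCounts(t)), pseudocount)
  attr(out, "timepoint") <- timePoint(t)
  out
}

#' Restrict OTU tables to their common feature space
#'
#' Omic coefficients only transfer between tables that share columns; this
#' restricts every table to the intersection of OTU ids, in the order they
#' appear in the first table, and reports what was dropped.
#'
#' @param tables list of [OtuTable-class] objects (>= 2).
#' @return list of restricted tables, with a `"dropped"` attribute naming
#'   the per-table discarded ids.
#' @export
alignFeatureSpaces <- function(tables) {
  stopifnot(length(tables) >= 2)
  common <- rownames(tables[[1]])
  for (tb in tables[-1]) common <- intersect(common, rownames(tb))
  if (!length(common))
    stop("the OTU id sets have an empty intersection")
  dropped <- lapply(tables, function(tb) setdiff(rownames(tb), common))
  out <- lapply(tables, function(tb) tb[common, ])
  attr(out, "dropped") <- dropped
  out
}

#' Centre-scale phenotypes within population
#'
#' Adds a `Phe` column: `(y - mean) / sd`, computed within each production
#' system, so cross-system predictions are compared on each system's own
#' scale.
#'
#' @param p phenotype data.frame with columns `y` and `population`.
#' @return `p` with a `Phe` column.
#' @export
centerScale <- function(p) {
  stopifnot(is.numeric(p$y))
  p$Phe <- NA_real_
  for (pop in unique(p$population)) {
    idx <- p$population == pop
    s <- sd(p$y[idx])
    if (!is.finite(s) || s == 0)
      stop("phenotype is constant within population ", pop)
    p$Phe[idx] <- (p$y[idx] - mean(p$y[idx])) / s
  }
  p
}

#' Adjust phenotypes for population-specific systematic effects
#'
#' Adds a `PheAdg` column: within each population, `Phe` is regressed by
#' ordinary least squares on the system's systematic factors — contemporary
#' group plus maternal line and pen in TE, contemporary group plus sex in
#' NU — and the fitted effects are subtracted and the remainder re-centred.
#' Confounded (aliased) factor levels are resolved by the least-squares
#' projection, with a warning.
#'
#' @param p phenotype data.frame carrying `Phe` (see [centerScale()]) and
#'   the factor columns `cg`, `sex`, `line`, `pen`.
#' @return `p` with a `PheAdg` column.
#' @export
adjustPhenotypes <- function(p) {
  if (is.null(p$Phe)) stop("run centerScale() first: no Phe column")
  p$PheAdg <- NA_real_
  for (pop in unique(p$population)) {
    idx <- p$population == pop
    pp <- p[idx, ]
    terms <- if (pop == "TE") c("cg", "line", "pen") else c("cg", "sex")
    terms <- terms[vapply(terms,
                          function(tt) length(unique(pp[[tt]])) > 1,
                          logical(1))]
    if (!length(terms)) {
      p$PheAdg[idx] <- pp$Phe - mean(pp$Phe)
      next
    }
    for (tt in terms) pp[[tt]] <- factor(pp[[tt]])
    fml <- as.formula(paste("Phe ~", paste(terms, collapse = " + ")))
    fit <- lm(fml, data = pp)
    if (anyNA(coef(fit)))
      warning("aliased factor levels in ", pop,
              " adjustment; least-squares projection used")
    res <- residuals(fit)
    p$PheAdg[idx] <- res - mean(res)
  }
  p
}

#' Preprocess a simulated or loaded dataset end to end
#'
#' Applies the full preprocessing chain in the study's order: SNP QC; per
#' time point, sparse-OTU filtering (threshold auto-scaled via
#' [scaleMinTotal()] unless given) followed by rarefaction and the CLR
#' transform; and phenotype centre-scaling plus systematic-effect
#' adjustment.
#'
#' @param ds dataset list from [simulateDataset()] or [readDataset()].
#' @param minTotal sparse-OTU threshold; `NULL` to auto-scale per table.
#' @param depth rarefaction depth.
#' @param pseudocount CLR zero replacement.
#' @param minCallRate,minMaf SNP QC thresholds.
#' @param seed seed for rarefaction.
#' @return list: `clr` (list of samples x OTUs matrices per time point),
#'   `genotypes` (QC'ed [GenotypeMatrix-class]), `phenotypes` (data.frame
#'   with `Phe`, `PheAdg`), `report` (QC counts and per-table OTU/sample
#'   retention).
#' @export
preprocessDataset <- function(ds, minTotal = NULL, depth = 10000,
                              pseudocount = 0.5, minCallRate = 0.90,
                              minMaf = 0.05, seed = 1L) {
  geno <- snpQC(ds$genotypes, minCallRate = minCallRate, minMaf = minMaf)
  clr <- list()
  tabReport <- list()
  for (tp in names(ds$microbiome)) {
    tb <- ds$microbiome[[tp]]
    mt <- if (is.null(minTotal)) scaleMinTotal(tb) else minTotal
    fl <- filterSparseOtus(tb, mt)
    rr <- rarefyCounts(fl, depth = depth, seed = seed)
    clr[[tp]] <- clrTransform(rr, pseudocount = pseudocount)
    tabReport[[tp]] <- list(minTotal = mt,
                            otusRetained = nrow(rr),
                            otusDropped = nrow(tb) - nrow(fl),
                            samplesRetained = ncol(rr),
                            samplesDropped = ncol(tb) - ncol(rr))
  }
  phen <- adjustPhenotypes(centerScale(ds$phenotypes))
  list(clr = clr, genotypes = geno, phenotypes = phen,
       report = list(snp = qcReport(geno), otu = tabReport))
}
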