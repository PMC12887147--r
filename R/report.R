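#' @include io.R
NULL

#' Write preprocessed model inputs to plain-text files
#'
#' Emits the model-ready artefacts of [preprocessDataset()]:
#' `clr_S1.tsv`/`clr_S2.tsv`/`clr_S3.tsv` (samples x OTUs real matrices),
#' `genotypes.qc.tsv` (post-QC, imputed allele counts, individuals x SNPs),
#' `phenotypes.derived.tsv` (adds the `Phe` and `PheAdg` columns) and
#' `qc_report.json` (counts removed per rule and per-table OTU/sample
#' retention).
#'
#' @param pre output of [preprocessDataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
writePreprocessed <- function(pre, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (tp in names(pre$clr)) {
    p <- file.path(dir, sprintf("clr_%s.tsv", tp))
    m <- pre$clr[[tp]]
    dt <- data.table::data.table(sample = rownames(m))
    for (j in colnames(m)) dt[[j]] <- m[, j]
    data.table::fwrite(dt, p, sep = "\t", quote = FALSE)
    paths[paste0("clr_", tp)] <- p
  }
  paths["genotypes"] <- file.path(dir, "genotypes.qc.tsv")
  writeGenotypes(pre$genotypes, paths["genotypes"])
  paths["phenotypes"] <- file.path(dir, "phenotypes.derived.tsv")
  data.table::fwrite(pre$phenotypes, paths["phenotypes"], sep = "\t",
                     na = "NA", quote = FALSE)
  paths["qc"] <- file.path(dir, "qc_report.json")
  jsonlite::write_json(pre$report, paths["qc"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write a markdown narrative of cross-validation results
#'
#' Renders the accuracy-versus-null summary (see [assembleSummary()]) as a
#' small markdown report: one table row per scenario with SSt/SOut
#' accuracies, the null mean and its 90th/95th percentiles, and the
#' dual-threshold significance flag. Numbers are printed to 3 decimals,
#' matching the reporting precision of this literature; full precision
#' lives in the CSV outputs of [runPipeline()].
#'
#' @param results list of [CvResult-class] objects.
#' @param nulls named list of [NullDistribution-class] objects keyed by
#'   `"direction|model|timepoint|response"`.
#' @param path output markdown file.
#' @param flaggedOnly restrict to significant rows.
#' @return invisibly, `path`.
#' @export
writeReport <- function(results, nulls = list(), path,
                        flaggedOnly = FALSE) {
  tab <- assembleSummary(results, nulls, flaggedOnly = flaggedOnly)
  f3 <- function(x) ifelse(is.na(x), "--", sprintf("%.3f", x))
  lines <- c(
    "# Cross-system prediction accuracy versus empirical null",
    "",
    sprintf("%d scenario(s); strategies: %s.", nrow(tab),
            paste(sort(unique(vapply(results, function(x) x@strategy,
                                     character(1)))), collapse = ", ")),
    "",
    "| Direction | Model | Time | Response | Acc-SOut | Acc-SSt | Acc-SNull | SNull 90% | SNull 95% | Significant |",
    "|---|---|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s | %s | %s | %s | %s |",
      tab$direction[i], tab$model[i], tab$timepoint[i], tab$response[i],
      f3(tab$AccSOut[i]), f3(tab$AccSSt[i]), f3(tab$AccSNull[i]),
      f3(tab$AccSNull90[i]), f3(tab$AccSNull95[i]),
      ifelse(is.na(tab$significant[i]), "--",
             ifelse(tab$significant[i], "yes", "no"))))
  }
  lines <- c(lines, "",
             paste("A scenario is flagged significant only when both the",
                   "sire-stratified and sire-out accuracies exceed the 95th",
                   "percentile of its permutation null."))
  writeLines(lines, path)
  invisible(path)
}
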