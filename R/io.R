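#' @include evaluate.R
NULL

#' Read a classic OTU table
#'
#' Parses the classic tab-separated OTU-table layout: rows are OTUs,
#' columns are samples, and the first header cell is `#OTU ID`. Counts are
#' validated to be non-negative integers and ids to be unique; violations
#' raise an error naming the offending row/column.
#'
#' @param path file path.
#' @param timepoint time-point label to attach (`"S1"`, `"S2"`, `"S3"`).
#' @return An [OtuTable-class].
#' @export
loadOtuTable <- function(path, timepoint = "S1") {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = NULL)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicate OTU id(s): ",
         paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  m <- as.matrix(dt[, -1])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id(s) in ", path)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at OTU '", ids[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "'")
  rownames(m) <- ids
  OtuTable(m, timepoint = timepoint)
}

#' Write a classic OTU table
#'
#' @param t an [OtuTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeOtuTable <- function(t, path) {
  m <- otuCounts(t)
  dt <- data.table::data.table(`#OTU ID` = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix
#'
#' Two dialects:
#' * `"tsv"`: first column individual id, remaining columns one per SNP,
#'   entries 0/1/2/NA (individuals x SNPs on disk).
#' * `"plink_raw"`: PLINK `.raw`-style additive export — whitespace
#'   separated, header `FID IID PAT MAT SEX PHENOTYPE` followed by SNP
#'   columns, `NA` for missing; `IID` is used as the individual id.
#'
#' Entries outside {0, 1, 2, NA} raise an error.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @param autosomal optional logical per-SNP flag (default all `TRUE`).
#' @return A [GenotypeMatrix-class] (SNPs x individuals).
#' @export
loadGenotypes <- function(path, dialect = c("tsv", "plink_raw"),
                          autosomal = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            na.strings = "NA")
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1])
  } else {
    dt <- data.table::fread(path, header = TRUE, na.strings = "NA")
    metaCols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(metaCols %in% colnames(dt)))
      stop("not a PLINK .raw-dialect file: missing ",
           paste(setdiff(metaCols, colnames(dt)), collapse = ", "))
    ids <- as.character(dt[["IID"]])
    m <- as.matrix(dt[, setdiff(colnames(dt), metaCols), with = FALSE])
  }
  if (anyDuplicated(ids)) stop("duplicate individual id(s) in ", path)
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & !m %in% c(0, 1, 2), arr.ind = TRUE)
  if (nrow(bad))
    stop("allele count outside {0,1,2,NA} at individual '", ids[bad[1, 1]],
         "', SNP '", colnames(m)[bad[1, 2]], "'")
  calls <- t(m)
  colnames(calls) <- ids
  if (is.null(autosomal)) autosomal <- rep(TRUE, nrow(calls))
  GenotypeMatrix(calls, autosomal = autosomal)
}

#' Write a genotype matrix
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path.
#' @param dialect `"tsv"` (individuals x SNPs, id column first) or
#'   `"plink_raw"`.
#' @return invisibly, `path`.
#' @export
writeGenotypes <- function(g, path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  m <- t(genoCalls(g))
  if (dialect == "tsv") {
    dt <- data.table::data.table(id = rownames(m))
    for (j in colnames(m)) dt[[j]] <- m[, j]
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  } else {
    dt <- data.table::data.table(FID = rownames(m), IID = rownames(m),
                                 PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9)
    for (j in colnames(m)) dt[[j]] <- m[, j]
    data.table::fwrite(dt, path, sep = " ", na = "NA", quote = FALSE)
  }
  invisible(path)
}

## ---- Pipeline ------------------------------------------------------------

#' Default pipeline configuration
#'
#' Every stage parameter defaults to its study-scale value (QC thresholds
#' 0.90/0.05, sparse-OTU threshold auto-scaled from 1200, rarefaction depth
#' 10000, prior shares 0.1/0.3/0.5 with df 5) except the chain and the
#' simulated population sizes, which default to desk scale.
#'
#' @return nested configuration list understood by [runPipeline()].
#' @export
defaultPipelineConfig <- function() {
  list(
    sim = list(nSires = 10, progenyPerSireNU = 14, progenyPerSireTE = 18,
               nSnps = 300, nOtus = 120, nCgNU = 8, nCgTE = 4,
               seqDepth = 4000, seed = 1),
    input = NULL,  # alternatively: list(dir = "path/to/dataset")
    preprocess = list(minTotal = NULL, depth = NULL, pseudocount = 0.5,
                      minCallRate = 0.90, minMaf = 0.05, write = FALSE),
    chain = list(nIter = 2000, burnIn = 500, thin = 5),
    cv = list(kExclude = 10, nRepeats = 4, nPerm = 0),
    scenarios = list(list(direction = "NU-TE", model = "M",
                          timepoint = "S3", response = "Phe",
                          strategies = c("SSt", "SOut"))),
    seed = 1)
}

.mergeConfig <- function(usr) {
  cfg <- defaultPipelineConfig()
  for (nm in names(usr)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(usr[[nm]]) &&
                     !nm %in% c("scenarios", "input"))
      modifyList(cfg[[nm]], usr[[nm]]) else usr[[nm]]
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [defaultPipelineConfig()]; the rest
#' keep their defaults, so a config round-trips through serialisation.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  .mergeConfig(yaml::read_yaml(path))
}

#' Run the full prediction pipeline
#'
#' Simulate (or load) -> preprocess -> cross-validate every requested
#' scenario under its strategies (with optional permutation nulls) ->
#' write `cv_results.csv` (one row per fold), `cv_summary.csv` (one row per
#' scenario x strategy) and `summary.csv` (accuracy-versus-null layout).
#' Every stage logs its parameters, seeds and record counts via
#' `message()`; re-running an identical configuration reproduces identical
#' outputs.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or a
#'   YAML path.
#' @param outdir output directory.
#' @param seed optional override of `config$seed`.
#' @return invisibly, a list with the result objects and output paths.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir, seed = NULL) {
  config <- if (is.character(config)) readRunConfig(config)
            else .mergeConfig(config)
  if (!is.null(seed)) config$seed <- seed
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  baseSeed <- as.integer(config$seed)
  logPath <- file.path(outdir, "run.log")
  cat("", file = logPath)
  message <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logPath, sep = "", append = TRUE)
    base::message(msg)
  }

  if (!is.null(config$input)) {
    message("pipeline: loading dataset from ", config$input$dir)
    ds <- readDataset(config$input$dir)
  } else {
    simArgs <- modifyList(config$sim, list(seed = baseSeed))
    cfg <- do.call(simConfig, simArgs)
    message("pipeline: simulating dataset (seed ", baseSeed, "): ",
            cfg@nSires, " sires, ",
            cfg@nSires * (cfg@progenyPerSireNU + cfg@progenyPerSireTE),
            " individuals, ", cfg@nSnps, " SNPs, ", cfg@nOtus, " OTUs")
    ds <- simulateDataset(cfg)
  }

  pre <- config$preprocess
  depth <- if (!is.null(pre$depth)) pre$depth
  else if (is.null(config$input) && !is.null(config$sim$seqDepth))
    # keep nearly all samples: just under the simulated sequencing depth
    round(0.85 * config$sim$seqDepth)
  else 10000
  message("pipeline: preprocessing (rarefaction depth ", depth, ")")
  data <- preprocessDataset(ds, minTotal = pre$minTotal, depth = depth,
                            pseudocount = pre$pseudocount,
                            minCallRate = pre$minCallRate,
                            minMaf = pre$minMaf, seed = baseSeed + 7L)
  message("pipeline: ", qcReport(data$genotypes)$retained,
          " SNPs retained after QC")
  if (isTRUE(config$preprocess$write)) {
    writePreprocessed(data, file.path(outdir, "preprocessed"))
    message("pipeline: wrote preprocessed inputs to ",
            file.path(outdir, "preprocessed"))
  }

  chain <- chainConfig(config$chain$nIter, config$chain$burnIn,
                       config$chain$thin, seed = baseSeed + 100L)
  results <- list()
  nulls <- list()
  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    key <- paste(sc$direction, sc$model, sc$timepoint, sc$response,
                 sep = "|")
    for (strat in sc$strategies) {
      message("pipeline: scenario ", key, " strategy ", strat)
      tp <- sc$timepoint
      if (sc$model != "G" && !tp %in% names(data$clr))
        stop("scenario ", key, " needs the ", tp,
             " OTU table, which is not available")
      plan <- if (strat == "SSt")
        planSSt(ds$pedigree, sc$direction, kExclude = config$cv$kExclude,
                nRepeats = config$cv$nRepeats,
                seed = baseSeed + 1000L + i)
      else planSOut(ds$pedigree, sc$direction)
      res <- runScenario(data, plan, model = sc$model, timepoint = tp,
                         response = sc$response, chain = chain)
      results[[paste(key, strat, sep = "|")]] <- res
      if (!is.null(config$cv$nPerm) && config$cv$nPerm > 0 &&
          strat == "SSt") {
        message("pipeline: permutation null (", config$cv$nPerm,
                " permutations)")
        nulls[[key]] <- runSNull(data, plan, model = sc$model,
                                 timepoint = tp, response = sc$response,
                                 chain = chain, nPerm = config$cv$nPerm,
                                 seed = baseSeed + 5000L + i)
      }
    }
  }

  perFold <- do.call(rbind, lapply(names(results), function(k) {
    x <- results[[k]]
    cbind(data.frame(direction = x@direction, model = x@model,
                     timepoint = x@timepoint, response = x@response,
                     strategy = x@strategy), foldResults(x))
  }))
  perScenario <- do.call(rbind, lapply(results, function(x) {
    data.frame(direction = x@direction, model = x@model,
               timepoint = x@timepoint, response = x@response,
               strategy = x@strategy, meanR = meanAccuracy(x),
               sdR = accuracySD(x), meanRMSE = meanRMSE(x),
               rmseSD = rmseSD(x), nFolds = nrow(foldResults(x)))
  }))
  rownames(perScenario) <- NULL
  paths <- c(results = file.path(outdir, "cv_results.csv"),
             summary = file.path(outdir, "cv_summary.csv"))
  data.table::fwrite(perFold, paths["results"])
  data.table::fwrite(perScenario, paths["summary"])
  if (length(nulls)) {
    tab <- assembleSummary(results, nulls)
    paths["table"] <- file.path(outdir, "summary.csv")
    data.table::fwrite(tab, paths["table"])
    paths["report"] <- file.path(outdir, "report.md")
    writeReport(results, nulls, paths["report"])
  }
  message("pipeline: wrote ", paste(basename(paths), collapse = ", "),
          " to ", outdir)
  invisible(list(results = results, nulls = nulls, paths = paths,
                 data = data, dataset = ds))
}
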