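#' @include crossval.R
NULL

#' Pearson correlation of observed and predicted measures
#'
#' @param observed,predicted numeric vectors of equal length (>= 3, finite).
#' @return the sample Pearson correlation; an error is raised for constant
#'   input (an undefined correlation must propagate as missing upstream,
#'   never as 0).
#' @export
pearsonR <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (length(observed) < 3)
    stop("need at least 3 pairs for a correlation")
  if (anyNA(observed) || anyNA(predicted) ||
      any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("non-finite values in the measure pair")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("undefined correlation: constant vector")
  cor(observed, predicted)
}

#' Root mean squared error
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (!length(observed)) stop("empty measure pair")
  sqrt(mean((predicted - observed)^2))
}

#' Empirical percentiles of a null distribution
#'
#' Linear interpolation between order statistics (`quantile type 7`); with
#' fewer than 20 values a warning is issued and the exact order statistic
#' (`type 1`) is used instead.
#'
#' @param values numeric vector (a [NullDistribution-class]'s values, or
#'   any sample).
#' @param probs probabilities (default 0.90 and 0.95).
#' @return named numeric vector of quantiles.
#' @export
empiricalPercentiles <- function(values, probs = c(0.90, 0.95)) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  type <- 7
  if (length(values) < 20) {
    warning("fewer than 20 values: using exact order statistics")
    type <- 1
  }
  quantile(values, probs = probs, type = type, names = TRUE)
}

#' Assemble the accuracy-versus-null summary table
#'
#' Joins SSt and SOut cross-validation results with their permutation null
#' per scenario key (direction, model, timepoint, response) into the
#' reporting layout: `AccSOut`, `AccSSt`, `AccSNull` (null mean),
#' `AccSNull90`, `AccSNull95`, and a significance flag that is `TRUE` iff
#' *both* the SSt and SOut accuracies exceed the 95th null percentile.
#' Scenarios lacking a null get an `NA` flag with a warning.
#'
#' @param results list of [CvResult-class] objects (SSt and SOut runs).
#' @param nulls named list of [NullDistribution-class] objects; names are
#'   scenario keys `"direction|model|timepoint|response"`.
#' @param flaggedOnly keep only significant rows (the published-table
#'   behaviour)?
#' @return data.frame, one row per scenario key.
#' @export
assembleSummary <- function(results, nulls = list(), flaggedOnly = FALSE) {
  if (!length(results)) {
    return(data.frame(direction = character(), model = character(),
                      timepoint = character(), response = character(),
                      AccSOut = numeric(), AccSSt = numeric(),
                      AccSNull = numeric(), AccSNull90 = numeric(),
                      AccSNull95 = numeric(), significant = logical()))
  }
  keyOf <- function(x) paste(x@direction, x@model, x@timepoint, x@response,
                             sep = "|")
  keys <- unique(vapply(results, keyOf, character(1)))
  rows <- lapply(keys, function(k) {
    sub <- results[vapply(results, keyOf, character(1)) == k]
    byStrat <- setNames(
      lapply(c("SSt", "SOut"), function(s) {
        hit <- Filter(function(x) x@strategy == s, sub)
        if (length(hit)) meanAccuracy(hit[[1]]) else NA_real_
      }), c("SSt", "SOut"))
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    nd <- nulls[[k]]
    if (is.null(nd)) {
      warning("no null distribution for scenario ", k)
      nullMean <- q90 <- q95 <- NA_real_
      flag <- NA
    } else {
      nullMean <- mean(nullValues(nd), na.rm = TRUE)
      q90 <- nullPercentiles(nd)[["90%"]]
      q95 <- nullPercentiles(nd)[["95%"]]
      flag <- isTRUE(byStrat$SSt > q95) && isTRUE(byStrat$SOut > q95)
    }
    data.frame(direction = parts[1], model = parts[2], timepoint = parts[3],
               response = parts[4], AccSOut = byStrat$SOut,
               AccSSt = byStrat$SSt, AccSNull = nullMean,
               AccSNull90 = q90, AccSNull95 = q95, significant = flag)
  })
  out <- do.call(rbind, rows)
  if (flaggedOnly) out <- out[!is.na(out$significant) & out$significant, ]
  rownames(out) <- NULL
  out
}
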