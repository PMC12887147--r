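#' @include brr.R
NULL

.popsOf <- function(direction) {
  if (direction == "NU-TE") c(train = "NU", validation = "TE")
  else c(train = "TE", validation = "NU")
}

# Leakage guard, run on every plan before any model is fitted: training and
# validation must never share an individual, and must come from different
# populations.
.assertNoLeakage <- function(plan, ped) {
  pops <- .popsOf(plan@direction)
  popOf <- setNames(ped$population, ped$id)
  for (f in plan@folds) {
    if (length(intersect(f$train, f$validation)))
      stop("fold leaks individuals between training and validation")
    if (!all(popOf[f$train] == pops["train"]))
      stop("training ids outside the training population")
    if (!all(popOf[f$validation] == pops["validation"]))
      stop("validation ids outside the validation population")
  }
  invisible(TRUE)
}

#' Plan sire-stratified cross-validation folds (SSt)
#'
#' Per repeat, `min(kExclude, familySize - 1)` individuals are sampled
#' uniformly (without replacement) out of every sire family of the training
#' population, so the family structure — sibs present in training — is
#' preserved while families shrink equally; the validation set is always
#' the entire opposite population. Four repeats by default.
#'
#' @param ped pedigree/phenotype data.frame with `id`, `sire`, `population`.
#' @param direction `"NU-TE"` or `"TE-NU"`.
#' @param kExclude target exclusions per family (default ~10).
#' @param nRepeats number of folds (default 4).
#' @param seed RNG seed for the exclusions.
#' @return A [FoldPlan-class] with `nRepeats` folds.
#' @export
planSSt <- function(ped, direction = c("NU-TE", "TE-NU"), kExclude = 10,
                    nRepeats = 4, seed = 1L) {
  direction <- match.arg(direction)
  pops <- .popsOf(direction)
  tr <- ped[ped$population == pops["train"], ]
  va <- ped[ped$population == pops["validation"], ]
  fams <- split(tr$id, tr$sire)
  if (any(lengths(fams) == 1L))
    warning("sire famil(ies) of size 1 in training: nothing excluded there")
  set.seed(seed)
  folds <- lapply(seq_len(nRepeats), function(r) {
    excluded <- unlist(lapply(fams, function(ids) {
      k <- min(kExclude, length(ids) - 1L)
      if (k <= 0) character() else sample(ids, k)
    }), use.names = FALSE)
    list(train = setdiff(tr$id, excluded), validation = va$id,
         meta = list(repeatIndex = r, nExcluded = length(excluded)))
  })
  plan <- new("FoldPlan", strategy = "SSt", direction = direction,
              folds = folds, seed = as.integer(seed))
  .assertNoLeakage(plan, ped)
  plan
}

#' Plan sire-family-left-out folds (SOut)
#'
#' One fold per shared founding sire: the sire's progeny are excluded from
#' the training population, and predictions are scored only on that sire's
#' progeny in the opposite population. Sires absent from the validation
#' population are skipped with a warning.
#'
#' @inheritParams planSSt
#' @return A [FoldPlan-class] with (at most) one fold per sire.
#' @export
planSOut <- function(ped, direction = c("NU-TE", "TE-NU")) {
  direction <- match.arg(direction)
  pops <- .popsOf(direction)
  tr <- ped[ped$population == pops["train"], ]
  va <- ped[ped$population == pops["validation"], ]
  folds <- list()
  for (s in sort(unique(tr$sire))) {
    vids <- va$id[va$sire == s]
    if (!length(vids)) {
      warning("sire ", s, " has no progeny in the validation population; ",
              "fold skipped")
      next
    }
    folds[[s]] <- list(train = tr$id[tr$sire != s], validation = vids,
                       meta = list(excludedSire = s))
  }
  plan <- new("FoldPlan", strategy = "SOut", direction = direction,
              folds = folds, seed = NA_integer_)
  .assertNoLeakage(plan, ped)
  plan
}

# Fit one fold and score its cross-population predictions.
.scoreFold <- function(model, response, timepoint, pops, fold, data, chain,
                       r2, foldSeed) {
  clrTrain <- if (model %in% c("M", "MG")) data$clr[[timepoint]]
  design <- buildDesign(data$phenotypes, model = model,
                        population = unname(pops["train"]),
                        response = response, clr = clrTrain,
                        geno = if (model %in% c("G", "MG")) data$genotypes,
                        timepoint = timepoint, ids = fold$train, r2 = r2)
  fit <- runGibbs(design, chainConfig(chain@nIter, chain@burnIn, chain@thin,
                                      seed = foldSeed))
  vids <- fold$validation
  pred <- predictOmic(
    fit,
    clr = if (model %in% c("M", "MG"))
      data$clr[[timepoint]][vids, , drop = FALSE],
    geno = if (model %in% c("G", "MG")) data$genotypes[, vids])
  obs <- data$phenotypes[[response]][match(vids, data$phenotypes$id)]
  r <- tryCatch(pearsonR(obs, pred), error = function(e) {
    warning("undefined correlation in a fold: ", conditionMessage(e))
    NA_real_
  })
  list(fit = fit, r = r, rmse = rmse(obs, pred),
       nTrain = length(fold$train), nValidation = length(vids))
}

#' Run one prediction scenario over a fold plan
#'
#' For every fold: fit the requested model variant on the training ids by
#' Gibbs sampling, carry the omic solutions across to the opposite
#' population with [predictOmic()], and score Pearson's r and RMSE against
#' the observed validation response. Fold chains use `chain@seed + fold
#' index`, so a run is reproducible yet folds are independent. Constant
#' (undefined-correlation) predictions score `NA` with a warning, never 0.
#'
#' @param data preprocessed bundle from [preprocessDataset()] (needs `clr`,
#'   `genotypes`, `phenotypes`).
#' @param plan a [FoldPlan-class] from [planSSt()] or [planSOut()].
#' @param model `"M"`, `"G"` or `"MG"`.
#' @param timepoint `"S1"`, `"S2"` or `"S3"` (recorded but inert for
#'   model `"G"`).
#' @param response `"Phe"` or `"PheAdg"`.
#' @param chain a [ChainConfig-class]; per-fold seeds derive from its seed.
#' @param r2 prior variance shares, as in [buildDesign()].
#' @return A [CvResult-class].
#' @export
runScenario <- function(data, plan, model = c("M", "G", "MG"),
                        timepoint = c("S3", "S1", "S2"),
                        response = c("Phe", "PheAdg"),
                        chain = chainConfig(), r2 = list(random = 0.1,
                                                         micro = 0.1,
                                                         geno = 0.3,
                                                         resid = 0.5)) {
  model <- match.arg(model)
  timepoint <- match.arg(timepoint)
  response <- match.arg(response)
  .assertNoLeakage(plan, data$phenotypes)
  pops <- .popsOf(plan@direction)
  rows <- lapply(seq_along(plan@folds), function(i) {
    sc <- .scoreFold(model, response, timepoint, pops, plan@folds[[i]],
                     data, chain, r2, foldSeed = chain@seed + i)
    data.frame(fold = i, r = sc$r, rmse = sc$rmse, nTrain = sc$nTrain,
               nValidation = sc$nValidation)
  })
  new("CvResult", direction = plan@direction, model = model,
      timepoint = timepoint, response = response, strategy = plan@strategy,
      folds = do.call(rbind, rows), seed = chain@seed)
}

#' Permutation null distribution of cross-population accuracy (SNull)
#'
#' Per permutation: shuffle the training phenotypes uniformly within the
#' training population, refit, and predict the *unshuffled* validation
#' population, recording Pearson's r. The family structure of the base
#' strategy is preserved by permuting within the folds of an SSt or SOut
#' plan (permutations cycle over its folds). The study ran 500 permutations
#' per scenario under each base strategy and pooled them; pool two runs
#' with [poolNulls()].
#'
#' @inheritParams runScenario
#' @param nPerm number of permutations (default 500; a warning is issued
#'   below 20, where empirical percentiles are unstable).
#' @param seed seed for the permutation stream; permutation `p` uses
#'   `seed + p` for both the shuffle and its chain.
#' @return A [NullDistribution-class] with 90th/95th percentiles.
#' @export
runSNull <- function(data, plan, model = c("M", "G", "MG"),
                     timepoint = c("S3", "S1", "S2"),
                     response = c("Phe", "PheAdg"),
                     chain = chainConfig(), nPerm = 500, seed = 1L,
                     r2 = list(random = 0.1, micro = 0.1, geno = 0.3,
                               resid = 0.5)) {
  model <- match.arg(model)
  timepoint <- match.arg(timepoint)
  response <- match.arg(response)
  if (nPerm < 20)
    warning("fewer than 20 permutations: empirical percentiles are unstable")
  .assertNoLeakage(plan, data$phenotypes)
  pops <- .popsOf(plan@direction)

  # Designs are identical across permutations of the same fold; build once
  # per fold and only swap the (shuffled) response.
  designs <- lapply(plan@folds, function(f) {
    clrTrain <- if (model %in% c("M", "MG")) data$clr[[timepoint]]
    buildDesign(data$phenotypes, model = model,
                population = unname(pops["train"]), response = response,
                clr = clrTrain,
                geno = if (model %in% c("G", "MG")) data$genotypes,
                timepoint = timepoint, ids = f$train, r2 = r2)
  })
  valPred <- lapply(plan@folds, function(f) {
    list(ids = f$validation,
         clr = if (model %in% c("M", "MG"))
           data$clr[[timepoint]][f$validation, , drop = FALSE],
         geno = if (model %in% c("G", "MG"))
           data$genotypes[, f$validation])
  })

  vals <- numeric(nPerm)
  nf <- length(plan@folds)
  for (p in seq_len(nPerm)) {
    k <- (p - 1L) %% nf + 1L
    d <- designs[[k]]
    set.seed(seed + p)
    d$y <- sample(d$y)
    fit <- runGibbs(d, chainConfig(chain@nIter, chain@burnIn, chain@thin,
                                   seed = seed + p))
    pred <- predictOmic(fit, clr = valPred[[k]]$clr, geno = valPred[[k]]$geno)
    obs <- data$phenotypes[[response]][match(valPred[[k]]$ids,
                                             data$phenotypes$id)]
    vals[p] <- tryCatch(pearsonR(obs, pred),
                        error = function(e) NA_real_)
  }
  pct <- empiricalPercentiles(vals[!is.na(vals)])
  new("NullDistribution", values = vals, percentiles = pct,
      strategy = plan@strategy, nPerm = as.integer(nPerm))
}

#' Pool permutation null distributions
#'
#' Concatenates the per-permutation accuracies of several
#' [NullDistribution-class] objects (e.g. the SSt-structured and
#' SOut-structured replicates of the same scenario) and recomputes the
#' percentiles.
#'
#' @param ... NullDistribution objects.
#' @return A pooled [NullDistribution-class] (strategy `"SNull"`).
#' @export
poolNulls <- function(...) {
  nd <- list(...)
  vals <- unlist(lapply(nd, nullValues))
  new("NullDistribution", values = vals,
      percentiles = empiricalPercentiles(vals[!is.na(vals)]),
      strategy = "SNull", nPerm = length(vals))
}
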