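#' @include preprocess.R
NULL

# drop-first-level dummy coding for one factor; returns NULL when the factor
# has a single level in this subset (nothing identifiable to estimate).
.dummies <- function(x, prefix) {
  f <- factor(x)
  if (nlevels(f) < 2) return(NULL)
  m <- model.matrix(~f)[, -1, drop = FALSE]
  colnames(m) <- paste0(prefix, levels(f)[-1])
  m
}

# full incidence matrix for a grouped random factor
.incidence <- function(x, prefix) {
  f <- factor(x)
  m <- model.matrix(~ f - 1)
  colnames(m) <- paste0(prefix, levels(f))
  m
}

#' Assemble the design of one model variant
#'
#' Builds the effect layout of the three model variants on a training subset
#' of one population:
#' * `M` (microbiota only): fixed sire, contemporary group and maternal line
#'   (TE) or sex (NU); random pen (TE) or litter (NU); a CLR coefficient
#'   block. The sire factor is fitted only in this variant.
#' * `G` (genomic only): as above without sire and with a centered SNP
#'   allele-count coefficient block instead of the CLR block.
#' * `MG`: both coefficient blocks, no sire factor.
#'
#' Fixed factors use a drop-first-level constraint next to an explicit
#' intercept; SNP columns are centered by training allele frequencies and
#' the centering constants are kept for leak-free validation centering;
#' the CLR matrix enters as-is.
#'
#' @param pheno phenotype data.frame carrying the response column and the
#'   factor columns (`population`, `sire`, `cg`, `sex`, `line`, `pen`,
#'   `litter`).
#' @param model `"M"`, `"G"` or `"MG"`.
#' @param population `"NU"` or `"TE"`: the training system.
#' @param response `"Phe"` or `"PheAdg"`.
#' @param clr samples x OTUs CLR matrix (required for M and MG).
#' @param geno [GenotypeMatrix-class] after QC (required for G and MG).
#' @param timepoint microbial sampling time label (bookkeeping only; the
#'   caller passes the matching `clr` matrix).
#' @param ids training individual ids; default all of `population`.
#' @param r2 named list of prior variance shares: `random` (grouped
#'   factors), `micro`, `geno`, `resid`. Defaults 0.1 / 0.1 / 0.3 / 0.5.
#' @param df prior degrees of freedom for every variance (default 5).
#' @param scaleRule see [computePriorScales()].
#' @return A design list consumed by [runGibbs()]: response `y`, effect
#'   `blocks`, and metadata (training ids, feature ids, SNP centering
#'   constants, `varY`).
#' @export
buildDesign <- function(pheno, model = c("M", "G", "MG"),
                        population = c("NU", "TE"),
                        response = c("Phe", "PheAdg"),
                        clr = NULL, geno = NULL, timepoint = NULL,
                        ids = NULL,
                        r2 = list(random = 0.1, micro = 0.1, geno = 0.3,
                                  resid = 0.5),
                        df = 5, scaleRule = c("r2", "one-minus-r2")) {
  model <- match.arg(model)
  population <- match.arg(population)
  response <- match.arg(response)
  scaleRule <- match.arg(scaleRule)
  if (model %in% c("M", "MG") && is.null(clr))
    stop("model ", model, " needs a CLR matrix")
  if (model %in% c("G", "MG") && is.null(geno))
    stop("model ", model, " needs genotypes")

  pp <- pheno[pheno$population == population, , drop = FALSE]
  if (!is.null(ids)) {
    missing <- setdiff(ids, pp$id)
    if (length(missing))
      stop("training ids not in population ", population, ": ",
           paste(head(missing, 5), collapse = ", "))
    pp <- pp[match(ids, pp$id), , drop = FALSE]
  }
  if (is.null(pp[[response]]))
    stop("phenotype table has no ", response,
         " column; run centerScale()/adjustPhenotypes()")
  y <- pp[[response]]
  n <- nrow(pp)

  blocks <- list()
  addBlock <- function(name, X, kind, r2val = NA_real_) {
    if (is.null(X) || ncol(X) == 0) return()
    blocks[[name]] <<- list(name = name, X = X, kind = kind,
                            r2 = r2val, df = df)
  }

  addBlock("intercept", matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
           "fixed_factor")
  if (model == "M")
    addBlock("sire", .dummies(pp$sire, "sire"), "fixed_factor")
  addBlock("cg", .dummies(pp$cg, "cg"), "fixed_factor")
  if (population == "NU") {
    addBlock("sex", .dummies(pp$sex, "sex"), "fixed_factor")
    addBlock("litter", .incidence(pp$litter, "litter"), "random_factor",
             r2$random)
  } else {
    addBlock("line", .dummies(pp$line, "line"), "fixed_factor")
    addBlock("pen", .incidence(pp$pen, "pen"), "random_factor", r2$random)
  }

  snpCenter <- NULL
  if (model %in% c("M", "MG")) {
    missing <- setdiff(pp$id, rownames(clr))
    if (length(missing))
      stop("individual(s) lacking a ",
           if (is.null(timepoint)) "microbiome" else timepoint,
           " sample: ", paste(head(missing, 5), collapse = ", "))
    W <- clr[pp$id, , drop = FALSE]
    addBlock("micro", W, "coefficient_matrix", r2$micro)
  }
  if (model %in% c("G", "MG")) {
    calls <- genoCalls(geno)
    missing <- setdiff(pp$id, colnames(calls))
    if (length(missing))
      stop("individual(s) lacking genotypes: ",
           paste(head(missing, 5), collapse = ", "))
    Z <- t(calls[, pp$id, drop = FALSE])
    snpCenter <- colMeans(Z)
    Z <- sweep(Z, 2, snpCenter)
    addBlock("geno", Z, "coefficient_matrix", r2$geno)
  }

  design <- list(y = y, blocks = blocks,
                 meta = list(model = model, population = population,
                             response = response, timepoint = timepoint,
                             ids = pp$id, snpCenter = snpCenter,
                             otuIds = if (!is.null(clr)) colnames(clr),
                             snpIds = if (!is.null(snpCenter))
                               names(snpCenter),
                             varY = var(y)))
  computePriorScales(design, dfResid = df, r2Resid = r2$resid,
                     scaleRule = scaleRule)
}

#' Attach scaled-inverse-chi-square prior scales to a design
#'
#' For every variance parameter the prior scale follows
#' `S_p = varY * R2_p * (df_p + 2) / MS_p`, where `MS_p = 1` for grouped
#' random factors and `MS_p` is the sum of per-column variances of the
#' design matrix for dense coefficient blocks; the residual scale is
#' `varY * R2_e * (df_e + 2)`. `R2_p` is read as the variance share the
#' effect is expected to explain a priori. `scaleRule = "one-minus-r2"`
#' substitutes `(1 - R2_p)` for `R2_p`, reproducing a literal reading of an
#' ambiguous published formula; it is provided for sensitivity analysis and
#' is not the default.
#'
#' @param design design list from [buildDesign()] (or a compatible list with
#'   `y` and `blocks`).
#' @param dfResid,r2Resid residual prior degrees of freedom and share.
#' @param scaleRule `"r2"` (default) or `"one-minus-r2"`.
#' @param varY override for the response variance used in the scales
#'   (default: the sample variance of `design$y`).
#' @return the design with `S` filled in per variance block and
#'   `residual` = list(S, df) attached.
#' @export
computePriorScales <- function(design, dfResid = 5, r2Resid = 0.5,
                               scaleRule = c("r2", "one-minus-r2"),
                               varY = NULL) {
  scaleRule <- match.arg(scaleRule)
  if (is.null(varY)) varY <- var(design$y)
  if (!is.finite(varY) || varY <= 0)
    stop("response variance must be positive")
  eff <- function(r2) if (scaleRule == "r2") r2 else 1 - r2
  for (k in seq_along(design$blocks)) {
    blk <- design$blocks[[k]]
    if (blk$kind == "fixed_factor") next
    ms <- if (blk$kind == "random_factor") 1
          else sum(apply(blk$X, 2, var))
    if (!is.finite(ms) || ms <= 0)
      stop("constant design in block '", blk$name,
           "': prior scale undefined")
    design$blocks[[k]]$S <- varY * eff(blk$r2) * (blk$df + 2) / ms
    design$blocks[[k]]$ms <- ms
  }
  design$residual <- list(S = varY * eff(r2Resid) * (dfResid + 2),
                          df = dfResid, r2 = r2Resid)
  design$meta$varY <- varY
  design
}

#' Fit a Bayesian Ridge Regression by Gibbs sampling
#'
#' Runs a single-site Gibbs chain over the design's effect blocks:
#' flat-prior Gaussian full conditionals for intercept and fixed-factor
#' dummies; Gaussian full conditionals with a common block variance for
#' grouped random factors and dense omic coefficient blocks; and
#' scaled-inverse-chi-square full conditionals for every block variance and
#' the residual variance. Posterior summaries are taken over the retained
#' draws (`floor((nIter - burnIn)/thin)` of them). The chain is
#' bit-reproducible given `chain@seed` and aborts if the residual variance
#' diverges beyond `1e6 * var(y)`.
#'
#' @param design design list from [buildDesign()].
#' @param chain a [ChainConfig-class].
#' @param fixVariances optional named list clamping variance parameters at
#'   fixed values instead of sampling them (names are block names, plus
#'   `"resid"`); used by the closed-form ridge oracle checks.
#' @return A [PosteriorSummary-class]. Its variance table reports, for each
#'   omic coefficient block, `varFrac` = posterior-mean block variance times
#'   the block's summed column variance over `var(y)` — the model's estimate
#'   of the variance share captured by that omic layer.
#' @export
runGibbs <- function(design, chain = chainConfig(), fixVariances = NULL) {
  validObject(chain)
  blocks <- design$blocks
  if (!length(blocks)) stop("design has no effect blocks")
  if (anyNA(design$y)) stop("non-finite values in the response")

  typeCode <- vapply(blocks, function(b)
    if (b$kind == "fixed_factor") 0L else 1L, integer(1))
  S <- vapply(blocks, function(b) if (is.null(b$S)) 0 else b$S, numeric(1))
  dfv <- vapply(blocks, function(b) b$df, numeric(1))
  fixv <- vapply(names(blocks), function(nm) {
    v <- fixVariances[[nm]]
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  fixE <- if (is.null(fixVariances$resid)) NA_real_ else fixVariances$resid

  set.seed(chain@seed)
  res <- gibbs_brr_cpp(design$y, lapply(blocks, `[[`, "X"), typeCode,
                       S, dfv, fixv,
                       design$residual$S, design$residual$df, fixE,
                       chain@nIter, chain@burnIn, chain@thin, 1e6)

  outBlocks <- list()
  for (k in seq_along(blocks)) {
    blk <- blocks[[k]]
    outBlocks[[blk$name]] <- list(name = blk$name, kind = blk$kind,
                                  colnames = colnames(blk$X),
                                  coefMean = as.vector(res$coefMean[[k]]),
                                  coefSD = as.vector(res$coefSD[[k]]))
  }
  vd <- res$varDraws
  colnames(vd) <- c(names(blocks), "resid")
  vd <- vd[, c(which(typeCode == 1L), ncol(vd)), drop = FALSE]

  varY <- design$meta$varY
  rows <- lapply(colnames(vd), function(nm) {
    draws <- vd[, nm]
    ms <- if (nm == "resid") NA_real_ else blocks[[nm]]$ms
    frac <- if (nm == "resid" || blocks[[nm]]$kind != "coefficient_matrix")
      NA_real_ else mean(draws) * ms / varY
    data.frame(parameter = nm, postMean = mean(draws), postSD = sd(draws),
               priorScale = if (nm == "resid") design$residual$S
                            else blocks[[nm]]$S,
               priorDf = if (nm == "resid") design$residual$df
                         else blocks[[nm]]$df,
               varFrac = frac)
  })
  variances <- do.call(rbind, rows)

  new("PosteriorSummary", blocks = outBlocks, variances = variances,
      varDraws = vd, nRetained = as.integer(res$nRetained), chain = chain,
      meta = design$meta)
}

#' Predict phenotypes from the omic solutions of a fit
#'
#' Applies only the omic coefficient blocks — `W_val %*% m_hat` for the CLR
#' block and `Z_val %*% g_hat` for the (training-centered) SNP block — to a
#' validation population. Population-specific fixed and grouped effects
#' (sire, contemporary group, sex, line, pen, litter) are never transferred:
#' their levels do not exist in the opposite system (sires do, but are
#' excluded so M, G and MG predictions stay comparable; see
#' `includeSire`).
#'
#' @param fit a [PosteriorSummary-class].
#' @param clr validation CLR matrix (samples x OTUs), columns matching the
#'   training feature space.
#' @param geno validation [GenotypeMatrix-class]; columns are centered with
#'   the training constants stored in the fit.
#' @param sire optional named sire factor for the validation individuals;
#'   only used when `includeSire = TRUE` and the fit carries sire solutions.
#' @param includeSire add the training sire solutions for shared sires
#'   (sensitivity analysis; default `FALSE`).
#' @return named numeric vector of predicted values.
#' @export
predictOmic <- function(fit, clr = NULL, geno = NULL, sire = NULL,
                        includeSire = FALSE) {
  pred <- NULL
  if ("micro" %in% names(fit@blocks)) {
    if (is.null(clr)) stop("fit carries a microbial block; supply clr")
    m <- coefMeans(fit, "micro")
    if (!identical(colnames(clr), names(m))) {
      if (!all(names(m) %in% colnames(clr)))
        stop("validation CLR matrix lacks training OTU column(s)")
      clr <- clr[, names(m), drop = FALSE]
    }
    pred <- as.vector(clr %*% m)
    names(pred) <- rownames(clr)
  }
  if ("geno" %in% names(fit@blocks)) {
    if (is.null(geno)) stop("fit carries a genomic block; supply geno")
    g <- coefMeans(fit, "geno")
    Z <- t(genoCalls(geno))
    if (!identical(colnames(Z), names(g))) {
      if (!all(names(g) %in% colnames(Z)))
        stop("validation genotypes lack training SNP column(s)")
      Z <- Z[, names(g), drop = FALSE]
    }
    Z <- sweep(Z, 2, fit@meta$snpCenter[names(g)])
    gp <- as.vector(Z %*% g)
    names(gp) <- rownames(Z)
    pred <- if (is.null(pred)) gp else {
      if (!identical(names(pred), names(gp)))
        gp <- gp[names(pred)]
      pred + gp
    }
  }
  if (is.null(pred))
    stop("fit has no omic coefficient block to predict from")
  if (includeSire && "sire" %in% names(fit@blocks)) {
    if (is.null(sire)) stop("includeSire = TRUE needs the sire factor")
    sol <- coefMeans(fit, "sire")  # drop-first dummies named sire<level>
    eff <- setNames(rep(0, length(sire)), names(sire))
    hit <- paste0("sire", sire) %in% names(sol)
    eff[hit] <- sol[paste0("sire", sire[hit])]
    pred <- pred + eff[names(pred)]
  }
  pred
}
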