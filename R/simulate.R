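#' @include methods.R
NULL

## Internal helpers ---------------------------------------------------------

# Center x within groups and rescale so its within-data variance equals
# `target`. Returns zeros (and attr dropped=TRUE) when x is constant, so the
# caller can push the unexpressible variance into the residual.
.scaleToVar <- function(x, target) {
  x <- x - mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0 || target == 0) {
    out <- rep(0, length(x))
    attr(out, "dropped") <- target > 0
    attr(out, "weight") <- 0
    return(out)
  }
  w <- sqrt(target) / s
  out <- x * w
  attr(out, "weight") <- w
  out
}

# CLR core shared by the generator and the preprocessing module:
# rows are samples; the pseudocount is added to zero cells only.
.clrCore <- function(x, pseudocount = 0.5) {
  if (any(x < 0)) stop("counts must be non-negative")
  zeroRows <- rowSums(x) == 0
  if (any(zeroRows))
    stop("cannot CLR-transform all-zero sample(s): ",
         paste(head(rownames(x)[zeroRows], 5), collapse = ", "))
  x[x == 0] <- pseudocount
  lx <- log(x)
  lx - rowMeans(lx)
}

.chunkIndices <- function(n, size) split(seq_len(n), ceiling(seq_len(n) / size))

## ---- Pedigree ------------------------------------------------------------

#' Generate a sire-linked two-population pedigree
#'
#' Builds the NU (purebred nucleus) and TE (crossbred terminal) populations:
#' every individual is the progeny of one of the shared founding sires and a
#' population-private dam; progeny are grouped into litters (one dam each),
#' single-sire single-sex pens of at most `penSize` animals, and contemporary
#' groups (assigned per litter in NU and per pen in TE, matching the grain at
#' which animals enter each facility). TE individuals additionally carry a
#' maternal-line label. Sires are the only element shared across populations.
#'
#' @param cfg a [SimConfig-class].
#' @return data.frame with columns `id`, `sire`, `dam`, `population`, `sex`,
#'   `line` (`NA` in NU), `litter`, `pen`, `cg`. Deterministic given
#'   `cfg@seed`.
#' @examples
#' ped <- generatePedigree(simConfig(nSires = 2, progenyPerSireNU = 3,
#'                                   progenyPerSireTE = 4, nCgNU = 2,
#'                                   nCgTE = 2))
#' table(ped$population)
#' @export
generatePedigree <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed + 11L)
  sireIds <- sprintf("S%02d", seq_len(cfg@nSires))

  buildPop <- function(pop, nPer, nCg, cgGrain) {
    n <- cfg@nSires * nPer
    sire <- rep(sireIds, each = nPer)
    withinFam <- rep(seq_len(nPer), times = cfg@nSires)
    id <- sprintf("%s%05d", pop, seq_len(n))
    litterIdx <- ceiling(withinFam / cfg@litterSize)
    litter <- paste(pop, "L", sire, litterIdx, sep = "_")
    dam <- paste(pop, "D", sire, litterIdx, sep = "_")
    sexes <- if (pop == "NU") c("M", "F") else c("CM", "F")
    sex <- sexes[(withinFam %% 2L) + 1L]
    # pens: single-sire, single-sex runs of at most penSize animals
    penKey <- paste(sire, sex, sep = "_")
    pen <- character(n)
    for (k in unique(penKey)) {
      idx <- which(penKey == k)
      pen[idx] <- paste(pop, "P", k, ceiling(seq_along(idx) / cfg@penSize),
                        sep = "_")
    }
    grain <- if (cgGrain == "litter") litter else pen
    units <- sample(unique(grain))
    cgOfUnit <- setNames(
      sprintf("%s_CG%02d", pop, (seq_along(units) - 1L) %% nCg + 1L), units)
    data.frame(id = id, sire = sire, dam = dam, population = pop,
               sex = sex, line = NA_character_, litter = litter, pen = pen,
               cg = unname(cgOfUnit[grain]), stringsAsFactors = FALSE)
  }

  nu <- buildPop("NU", cfg@progenyPerSireNU, cfg@nCgNU, "litter")
  te <- buildPop("TE", cfg@progenyPerSireTE, cfg@nCgTE, "pen")
  # maternal line is a property of the (crossbred) dam
  teDams <- unique(te$dam)
  lineOfDam <- setNames(
    sprintf("L%d", sample(cfg@nMaternalLines, length(teDams), replace = TRUE)),
    teDams)
  te$line <- unname(lineOfDam[te$dam])
  rbind(nu, te)
}

## ---- Genotypes -----------------------------------------------------------

#' Simulate genotypes by gene dropping through the pedigree
#'
#' Founder allele frequencies are drawn per SNP from Uniform(0.05, 0.5):
#' one frequency vector for the Duroc pool (sires and NU dams) and one per
#' commercial maternal line (TE dams). Sire and dam genotypes are drawn
#' binomially at those frequencies; each offspring receives one allele from
#' its sire and one from its dam, independently per SNP (no linkage).
#' Optional missingness is injected at `cfg@missingRate` and a fraction
#' `cfg@nonAutosomalFrac` of SNPs is flagged non-autosomal, both to give the
#' QC stage something to act on.
#'
#' @param ped pedigree from [generatePedigree()].
#' @param cfg the [SimConfig-class] that produced it.
#' @return A [GenotypeMatrix-class] (SNPs x individuals). Its metadata holds
#'   the founder truth: `sireGeno`, `damGeno` (SNPs x parents) and the
#'   founder allele frequencies — used by Mendelian-consistency tests.
#' @export
simulateGenotypes <- function(ped, cfg) {
  set.seed(cfg@seed + 22L)
  nSnps <- cfg@nSnps
  snpIds <- sprintf("SNP%05d", seq_len(nSnps))
  sireIds <- sort(unique(ped$sire))
  pDuroc <- runif(nSnps, 0.05, 0.5)
  pLine <- matrix(runif(cfg@nMaternalLines * nSnps, 0.05, 0.5),
                  nrow = nSnps,
                  dimnames = list(snpIds,
                                  sprintf("L%d", seq_len(cfg@nMaternalLines))))

  drawBinom <- function(nInd, prob) {
    matrix(rbinom(nSnps * nInd, 2L, rep(prob, times = nInd)), nrow = nSnps)
  }
  sireGeno <- drawBinom(length(sireIds), pDuroc)
  dimnames(sireGeno) <- list(snpIds, sireIds)

  dams <- unique(ped[, c("dam", "population", "line")])
  damGeno <- matrix(0L, nSnps, nrow(dams),
                    dimnames = list(snpIds, dams$dam))
  for (i in seq_len(nrow(dams))) {
    prob <- if (dams$population[i] == "NU") pDuroc else pLine[, dams$line[i]]
    damGeno[, i] <- rbinom(nSnps, 2L, prob)
  }

  n <- nrow(ped)
  calls <- matrix(NA_real_, nSnps, n, dimnames = list(snpIds, ped$id))
  for (idx in .chunkIndices(n, 250L)) {
    S <- sireGeno[, ped$sire[idx], drop = FALSE]
    D <- damGeno[, ped$dam[idx], drop = FALSE]
    calls[, idx] <-
      matrix(rbinom(length(S), 1L, as.vector(S) / 2), nrow = nSnps) +
      matrix(rbinom(length(D), 1L, as.vector(D) / 2), nrow = nSnps)
  }
  if (cfg@missingRate > 0) {
    miss <- runif(length(calls)) < cfg@missingRate
    calls[miss] <- NA_real_
  }
  autosomal <- rep(TRUE, nSnps)
  if (cfg@nonAutosomalFrac > 0) {
    autosomal[sample(nSnps, round(cfg@nonAutosomalFrac * nSnps))] <- FALSE
  }
  g <- GenotypeMatrix(calls, autosomal = autosomal)
  metadata(g)$founders <- list(sireGeno = sireGeno, damGeno = damGeno,
                               freqDuroc = pDuroc, freqLines = pLine)
  g
}

## ---- Microbiome ----------------------------------------------------------

#' Simulate OTU count tables at three sampling time points
#'
#' Per sample and time point, latent log-abundances are
#' baseline + host-genetic score + pen effect + individual noise, and counts
#' are a single multinomial draw of `cfg@seqDepth` reads over the softmax of
#' the latent vector. A fraction `heritableOtuFrac` of OTUs carries a
#' host-genetic score (a weighted sum over five causal SNPs, standardised
#' and scaled to variance `microH2`); pen effects are shared across time
#' points (a stable pen environment) while individual noise is redrawn, so
#' tables at different times are correlated only through genetics and pen.
#'
#' @param ped pedigree from [generatePedigree()].
#' @param genos [GenotypeMatrix-class] from [simulateGenotypes()].
#' @param cfg the [SimConfig-class].
#' @return list with elements `S1`, `S2`, `S3` (each an [OtuTable-class]
#'   whose samples are all individuals of both populations) and `truth`
#'   (baseline vector, heritable OTU ids, causal SNPs and weights).
#' @export
simulateMicrobiome <- function(ped, genos, cfg) {
  set.seed(cfg@seed + 33L)
  if (cfg@seqDepth < cfg@nOtus)
    warning("seqDepth < nOtus: expect a very sparse count table")
  nOtus <- cfg@nOtus
  otuIds <- sprintf("OTU%04d", seq_len(nOtus))
  n <- nrow(ped)

  baseline <- rnorm(nOtus, 0, 1.2)
  nHer <- round(cfg@heritableOtuFrac * nOtus)
  heritable <- sort(sample(nOtus, nHer))

  calls <- genoCalls(genos)[, ped$id, drop = FALSE]
  # genetic scores only need the causal rows; mean-impute missing calls there
  genScore <- matrix(0, n, nOtus)
  causal <- vector("list", nOtus)
  if (nHer > 0 && cfg@microH2 > 0) {
    for (k in heritable) {
      snps <- sample(nrow(calls), min(5L, nrow(calls)))
      w <- rnorm(length(snps))
      zz <- calls[snps, , drop = FALSE]
      if (anyNA(zz)) {
        mu <- rowMeans(zz, na.rm = TRUE)
        zz[is.na(zz)] <- mu[row(zz)[is.na(zz)]]
      }
      sc <- as.vector(crossprod(zz, w))
      s <- sd(sc)
      if (s > 0) genScore[, k] <- (sc - mean(sc)) / s * sqrt(cfg@microH2)
      causal[[k]] <- list(snps = rownames(calls)[snps], weights = w)
    }
  }

  pens <- unique(ped$pen)
  penEff <- matrix(rnorm(length(pens) * nOtus, 0, sqrt(cfg@microPenVar)),
                   length(pens), nOtus, dimnames = list(pens, NULL))
  penOfInd <- penEff[ped$pen, , drop = FALSE]

  tables <- list()
  for (tp in c("S1", "S2", "S3")) {
    latent <- matrix(baseline, n, nOtus, byrow = TRUE) + genScore + penOfInd +
      matrix(rnorm(n * nOtus, 0, sqrt(cfg@microNoiseVar)), n, nOtus)
    counts <- matrix(0L, nOtus, n, dimnames = list(otuIds, ped$id))
    for (i in seq_len(n)) {
      lp <- latent[i, ] - max(latent[i, ])
      counts[, i] <- rmultinom(1, cfg@seqDepth, exp(lp))
    }
    tables[[tp]] <- OtuTable(counts, timepoint = tp)
  }
  tables$truth <- list(baseline = setNames(baseline, otuIds),
                       heritableOtus = otuIds[heritable],
                       causal = setNames(causal, otuIds))
  tables
}

## ---- Phenotypes ----------------------------------------------------------

#' Simulate phenotypes with known variance structure
#'
#' The generative model is
#' `y = CG + sex/line + litter (NU) or pen (TE) + u + sum_t w_t (CLR(x_t) m) + e`:
#' a contemporary-group effect, a fixed sex (NU) or maternal-line (TE) shift,
#' a grouped environmental effect, an additive genomic value `u = Z g` (with
#' SNP effects mixed from shared and system-specific parts so that the
#' between-system genetic correlation equals `rgCrossSystem`), a microbial
#' contribution per sampling time built from the centered-log-ratio of the
#' simulated counts and a shared OTU effect vector `m`, and residual noise.
#' Every random component is rescaled within population so its realised
#' variance fraction equals the configured one exactly; time-point weights
#' `w_t` follow `b2` (zero at S1 under the defaults).
#'
#' @param ped,genos,micro,cfg outputs of the upstream generator stages.
#' @return list with `phenotypes` (data.frame: `id`, `y`, `population`,
#'   `sire`, `cg`, `sex`, `line`, `pen`, `litter`) and `truth` (SNP and OTU
#'   effect vectors, per-individual breeding values and component table,
#'   realised variance fractions, microbial time-point weights, seed).
#' @export
simulatePhenotypes <- function(ped, genos, micro, cfg) {
  set.seed(cfg@seed + 44L)
  need <- names(cfg@b2)[cfg@b2 > 0]
  missingTp <- setdiff(need, names(micro))
  if (length(missingTp))
    stop("microbiome table(s) missing for time point(s): ",
         paste(missingTp, collapse = ", "))

  n <- nrow(ped)
  popIdx <- split(seq_len(n), ped$population)

  calls <- genoCalls(genos)[, ped$id, drop = FALSE]
  if (anyNA(calls)) {
    mu <- rowMeans(calls, na.rm = TRUE)
    calls[is.na(calls)] <- mu[row(calls)[is.na(calls)]]
  }

  nSnps <- nrow(calls)
  gShared <- rnorm(nSnps)
  rg <- cfg@rgCrossSystem
  a <- sqrt(abs(rg))
  b <- sqrt(1 - abs(rg))
  gNU <- a * gShared + b * rnorm(nSnps)
  gTE <- sign(rg) * a * gShared + b * rnorm(nSnps)
  if (rg == 1) gTE <- gNU
  snpEff <- list(NU = setNames(gNU, rownames(calls)),
                 TE = setNames(gTE, rownames(calls)))

  presentTp <- intersect(c("S1", "S2", "S3"), names(micro))
  m <- setNames(rnorm(cfg@nOtus), rownames(otuCounts(micro[[presentTp[1]]])))

  comp <- data.frame(id = ped$id, cg = 0, sexline = 0, group = 0, u = 0,
                     mS1 = 0, mS2 = 0, mS3 = 0, e = 0)
  weights <- matrix(0, 2, 3, dimnames = list(c("NU", "TE"),
                                             c("S1", "S2", "S3")))
  clrList <- lapply(micro[presentTp], function(tb) .clrCore(t(otuCounts(tb))))

  for (pop in c("NU", "TE")) {
    idx <- popIdx[[pop]]
    pp <- ped[idx, ]
    residFrac <- 1 - cfg@h2 - sum(cfg@b2) - cfg@varCg -
      if (pop == "NU") cfg@varLitter else cfg@varPen
    if (residFrac <= 0)
      stop("variance fractions leave no residual variance in ", pop)

    uRaw <- as.vector(crossprod(calls[, idx, drop = FALSE], snpEff[[pop]]))
    u <- .scaleToVar(uRaw, cfg@h2)
    if (isTRUE(attr(u, "dropped"))) residFrac <- residFrac + cfg@h2
    comp$u[idx] <- u

    for (tp in c("S1", "S2", "S3")) {
      if (!tp %in% presentTp) next  # b2 is zero here, checked above
      cRaw <- as.vector(clrList[[tp]][pp$id, , drop = FALSE] %*% m)
      ct <- .scaleToVar(cRaw, cfg@b2[[tp]])
      weights[pop, tp] <- attr(ct, "weight")
      if (isTRUE(attr(ct, "dropped"))) residFrac <- residFrac + cfg@b2[[tp]]
      comp[[paste0("m", tp)]][idx] <- ct
    }

    cgEff <- rnorm(length(unique(pp$cg)))
    names(cgEff) <- unique(pp$cg)
    cgv <- .scaleToVar(unname(cgEff[pp$cg]), cfg@varCg)
    if (isTRUE(attr(cgv, "dropped"))) residFrac <- residFrac + cfg@varCg
    comp$cg[idx] <- cgv

    grpCol <- if (pop == "NU") pp$litter else pp$pen
    grpTarget <- if (pop == "NU") cfg@varLitter else cfg@varPen
    grpEff <- rnorm(length(unique(grpCol)))
    names(grpEff) <- unique(grpCol)
    grpv <- .scaleToVar(unname(grpEff[grpCol]), grpTarget)
    if (isTRUE(attr(grpv, "dropped"))) residFrac <- residFrac + grpTarget
    comp$group[idx] <- grpv

    shift <- if (pop == "NU") cfg@sexLineShift[1] else cfg@sexLineShift[2]
    lev <- if (pop == "NU") pp$sex else pp$line
    comp$sexline[idx] <- ifelse(lev == sort(unique(lev))[1],
                                 shift / 2, -shift / 2)
    if (length(unique(lev)) == 1L) comp$sexline[idx] <- 0

    comp$e[idx] <- .scaleToVar(rnorm(length(idx)), residFrac)
  }

  y <- comp$cg + comp$sexline + comp$group + comp$u +
    comp$mS1 + comp$mS2 + comp$mS3 + comp$e
  phen <- data.frame(id = ped$id, y = y, population = ped$population,
                     sire = ped$sire, cg = ped$cg, sex = ped$sex,
                     line = ped$line, pen = ped$pen, litter = ped$litter,
                     stringsAsFactors = FALSE)

  realized <- do.call(rbind, lapply(c("NU", "TE"), function(pop) {
    idx <- popIdx[[pop]]
    vy <- var(y[idx])
    data.frame(population = pop,
               component = c("cg", "sexline", "group", "u",
                             "mS1", "mS2", "mS3", "e"),
               fraction = vapply(c("cg", "sexline", "group", "u",
                                   "mS1", "mS2", "mS3", "e"),
                                 function(cc) var(comp[[cc]][idx]) / vy,
                                 numeric(1)))
  }))

  list(phenotypes = phen,
       truth = list(snpEffects = snpEff, otuEffects = m,
                    breedingValues = setNames(comp$u, ped$id),
                    microWeights = weights, components = comp,
                    realizedFractions = realized, seed = cfg@seed))
}

## ---- One-call generator and disk round trip ------------------------------

#' Generate a complete synthetic study
#'
#' Runs [generatePedigree()], [simulateGenotypes()], [simulateMicrobiome()]
#' and [simulatePhenotypes()] in order and bundles their outputs with the
#' truth record. Bit-reproducible given `cfg@seed`.
#'
#' @param cfg a [SimConfig-class].
#' @return list: `pedigree`, `genotypes`, `microbiome` (list S1/S2/S3),
#'   `phenotypes`, `truth` (phenotype truth plus the microbiome generative
#'   record under `$microbiome`), `config`.
#' @examples
#' ds <- simulateDataset(simConfig(nSires = 3, progenyPerSireNU = 4,
#'                                 progenyPerSireTE = 4, nSnps = 40,
#'                                 nOtus = 25, nCgNU = 2, nCgTE = 2,
#'                                 seqDepth = 500))
#' dim(otuCounts(ds$microbiome$S3))
#' @export
simulateDataset <- function(cfg) {
  ped <- generatePedigree(cfg)
  geno <- simulateGenotypes(ped, cfg)
  micro <- simulateMicrobiome(ped, geno, cfg)
  phe <- simulatePhenotypes(ped, geno, micro, cfg)
  truth <- phe$truth
  truth$microbiome <- micro$truth
  list(pedigree = ped, genotypes = geno,
       microbiome = micro[c("S1", "S2", "S3")],
       phenotypes = phe$phenotypes, truth = truth, config = cfg)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `pedigree.tsv`, `genotypes.tsv` (individuals x SNPs, entries
#' 0/1/2/NA), `otu_S1.tsv`/`otu_S2.tsv`/`otu_S3.tsv` (classic OTU-table
#' orientation with a `#OTU ID` header cell), `phenotypes.tsv` and
#' `truth.json` (effect vectors, realised variance fractions, seed).
#'
#' @param ds dataset from [simulateDataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @seealso [readDataset()] for the lossless inverse.
#' @export
writeDataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    pedigree = file.path(dir, "pedigree.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json"))
  data.table::fwrite(ds$pedigree, paths["pedigree"], sep = "\t", na = "NA",
                     quote = FALSE)
  writeGenotypes(ds$genotypes, paths["genotypes"])
  for (tp in names(ds$microbiome)) {
    p <- file.path(dir, sprintf("otu_%s.tsv", tp))
    writeOtuTable(ds$microbiome[[tp]], p)
    paths[paste0("otu_", tp)] <- p
  }
  data.table::fwrite(ds$phenotypes, paths["phenotypes"], sep = "\t",
                     na = "NA", quote = FALSE)
  tr <- ds$truth
  jsonlite::write_json(
    list(snpEffects = lapply(tr$snpEffects, as.list),
         otuEffects = as.list(tr$otuEffects),
         breedingValues = as.list(tr$breedingValues),
         microWeights = as.data.frame(tr$microWeights),
         realizedFractions = tr$realizedFractions,
         seed = tr$seed),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read back a dataset written by [writeDataset()]
#'
#' @param dir directory holding the files.
#' @return list with `pedigree`, `genotypes`, `microbiome`, `phenotypes`,
#'   `truth` (parsed JSON).
#' @export
readDataset <- function(dir) {
  ped <- as.data.frame(data.table::fread(file.path(dir, "pedigree.tsv"),
                                         na.strings = "NA"))
  geno <- loadGenotypes(file.path(dir, "genotypes.tsv"))
  micro <- list()
  for (tp in c("S1", "S2", "S3")) {
    p <- file.path(dir, sprintf("otu_%s.tsv", tp))
    if (file.exists(p)) micro[[tp]] <- loadOtuTable(p, timepoint = tp)
  }
  phen <- as.data.frame(data.table::fread(file.path(dir, "phenotypes.tsv"),
                                          na.strings = "NA"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(pedigree = ped, genotypes = geno, microbiome = micro,
       phenotypes = phen, truth = truth)
}
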