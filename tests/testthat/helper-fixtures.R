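# Shared fixture builders. Everything is generated in code at test time;
# the cache avoids re-simulating the same small dataset across test files.

tinyCfg <- function(seed = 1L, ...) {
  args <- list(nSires = 4, progenyPerSireNU = 8, progenyPerSireTE = 10,
               nSnps = 120, nOtus = 60, nCgNU = 3, nCgTE = 2,
               seqDepth = 2000, seed = seed)
  do.call(simConfig, utils::modifyList(args, list(...)))
}

.fixtureCache <- new.env(parent = emptyenv())

sharedFixture <- function() {
  if (is.null(.fixtureCache$data)) {
    ds <- simulateDataset(tinyCfg(seed = 11))
    pre <- suppressWarnings(preprocessDataset(ds, depth = 1700, seed = 5))
    .fixtureCache$data <- list(ds = ds, pre = pre)
  }
  .fixtureCache$data
}

# One genotype column (individuals for one SNP) with an exact call rate and
# minor allele frequency, for hand-built QC tables.
snpColumn <- function(n, callRate, maf) {
  nMiss <- round((1 - callRate) * n)
  m <- n - nMiss
  nAlt <- round(maf * 2 * m)
  g <- c(rep(2, nAlt %/% 2), rep(1, nAlt %% 2))
  g <- c(g, rep(0, m - length(g)), rep(NA_real_, nMiss))
  g
}

# Hand-built two-population pedigree data.frame (no simulation) for plan
# arithmetic tests.
manualPed <- function(nSires, sizeNU, sizeTE) {
  sires <- sprintf("S%02d", seq_len(nSires))
  mk <- function(pop, size) {
    data.frame(id = sprintf("%s%04d", pop, seq_len(nSires * size)),
               sire = rep(sires, each = size),
               population = pop, stringsAsFactors = FALSE)
  }
  rbind(mk("NU", sizeNU), mk("TE", sizeTE))
}
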