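# Shared fixtures and independent oracles used across test files.

# One-row pileup site with explicit orientation counts.
makeSite <- function(fwd_ref, fwd_alt, rev_ref, rev_alt, mean_bq = 33,
                     chrom = "chr", pos = 1L, ref = "C", alt = "A",
                     subculture = 0L, replicate = 1L) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             fwd_ref = fwd_ref, fwd_alt = fwd_alt, rev_ref = rev_ref,
             rev_alt = rev_alt, mean_bq = mean_bq, subculture = subculture,
             replicate = replicate, stringsAsFactors = FALSE)
}

# Brute-force filtering oracle: evaluates every rule independently from the
# raw pileup, then takes the conjunction. Kept deliberately naive (per-row
# loops, direct formulas) and separate from the package's cascade.
oracleKeepSet <- function(pileups, qualMin = 100, afMin = 0.04,
                          minReads = 4, minBq = 20, consensusAfMin = 0.005,
                          strandBiasP = 0.001, recurrenceAf = 0.08,
                          recurrenceCount = 3, starterAfMax = 0.5,
                          depthCorrThreshold = 0.8, depthCorrMinPoints = 6,
                          errorRate = 0.001, exclusions = NULL) {
  key <- paste(pileups$replicate, pileups$chrom, pileups$pos, pileups$ref,
               pileups$alt, sep = "/")
  kept <- character(0)
  for (k in unique(key)) {
    rows <- pileups[key == k, ]
    rows <- rows[order(rows$subculture), ]
    dFwd <- rows$fwd_ref + rows$fwd_alt
    dRev <- rows$rev_ref + rows$rev_alt
    depth <- dFwd + dRev
    altTot <- rows$fwd_alt + rows$rev_alt
    af <- ifelse(depth > 0, altTot / depth, 0)
    sitePass <- logical(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      qual <- if (altTot[i] == 0) 0 else
        min(-10 * pbinom(altTot[i] - 1, depth[i], errorRate / 3,
                         lower.tail = FALSE, log.p = TRUE) / log(10), 1000)
      ruleA <- qual >= qualMin
      sb <- if (altTot[i] == 0) 1 else
        fisher.test(matrix(c(rows$fwd_ref[i], rows$fwd_alt[i],
                             rows$rev_ref[i], rows$rev_alt[i]), 2))$p.value
      ruleB <- af[i] >= consensusAfMin && sb >= strandBiasP
      afF <- if (dFwd[i] > 0) rows$fwd_alt[i] / dFwd[i] else NA
      afR <- if (dRev[i] > 0) rows$rev_alt[i] / dRev[i] else NA
      ruleOrient <- !is.na(afF) && !is.na(afR) && afF > afMin && afR > afMin
      ruleReads <- dFwd[i] >= minReads && dRev[i] >= minReads &&
        rows$mean_bq[i] >= minBq
      sitePass[i] <- ruleA && ruleB && ruleOrient && ruleReads
    }
    if (!any(sitePass)) next
    ruleRecur <- sum(af > recurrenceAf) >= recurrenceCount
    af0 <- af[rows$subculture == 0]
    ruleStarter <- !length(af0) || af0[1] <= starterAfMax
    ruleRrna <- TRUE
    if (!is.null(exclusions)) {
      hit <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(rows$chrom[1],
                               IRanges::IRanges(rows$pos[1], rows$pos[1])),
        exclusions)
      ruleRrna <- length(hit) == 0
    }
    ruleDepth <- TRUE
    if (nrow(rows) >= depthCorrMinPoints) {
      rho <- suppressWarnings(cor(af, depth, method = "spearman"))
      ruleDepth <- is.na(rho) || abs(rho) < depthCorrThreshold
    }
    if (ruleRecur && ruleStarter && ruleRrna && ruleDepth)
      kept <- c(kept, k)
  }
  sort(kept)
}

cascadeKeepKeys <- function(cascade) {
  ks <- cascade$keepSet
  sort(paste(ks$replicate, ks$chrom, ks$pos, ks$ref, ks$alt, sep = "/"))
}

# Random pileup panel mixing true signals, starter background, artifacts
# and error-only sites; used for oracle-equivalence checks.
randomPileupPanel <- function(nVariants, nSubcultures = 5, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (v in seq_len(nVariants)) {
    kind <- sample(c("signal", "noise", "starter", "low"), 1)
    af <- switch(kind,
      signal = pmin(pmax(cumsum(runif(nSubcultures, -0.05, 0.25)), 0), 0.95),
      noise = rep(0, nSubcultures),
      starter = c(runif(1, 0.55, 0.95), runif(nSubcultures - 1, 0, 0.9)),
      low = runif(nSubcultures, 0, 0.06))
    rows[[v]] <- simulatePileup(af, seqParams(),
                                pos = v * 50L, subculture = seq_len(nSubcultures) - 1L)
  }
  do.call(rbind, rows)
}

# Deterministic logistic selection recursion (one-locus haploid).
logisticRecursion <- function(x0, s, generations) {
  x <- x0
  for (i in seq_len(generations)) x <- (1 + s) * x / ((1 + s) * x + (1 - x))
  x
}

# Synthetic gene set: nGenes back-to-back genes of equal length covering
# the genome exactly.
tilingGenes <- function(nGenes = 5000, geneLength = 1200) {
  data.frame(gene_id = sprintf("g%04d", seq_len(nGenes)), chrom = "chr",
             start = (seq_len(nGenes) - 1L) * geneLength + 1L,
             end = seq_len(nGenes) * geneLength,
             strand = "+", stringsAsFactors = FALSE)
}

# Catalogue with nEnriched heavily hit genes and the remaining records
# spread one-per-gene so no background gene is ever multiply hit.
enrichedCatalogue <- function(genes, enrichedIdx, nEnrichedHits,
                              nBackground, seed = 1) {
  set.seed(seed)
  perGene <- rep(floor(nEnrichedHits / length(enrichedIdx)),
                 length(enrichedIdx))
  perGene[1] <- perGene[1] + nEnrichedHits - sum(perGene)
  rows <- list()
  for (i in seq_along(enrichedIdx)) {
    g <- genes[enrichedIdx[i], ]
    rows[[i]] <- data.frame(chrom = g$chrom,
                            pos = sample(g$start:g$end, perGene[i],
                                         replace = TRUE))
  }
  bgGenes <- sample(setdiff(seq_len(nrow(genes)), enrichedIdx), nBackground)
  bg <- genes[bgGenes, ]
  rows[[length(rows) + 1L]] <- data.frame(
    chrom = bg$chrom,
    pos = bg$start + sample.int(bg$end[1] - bg$start[1] + 1L, nBackground,
                                replace = TRUE) - 1L)
  cat <- do.call(rbind, rows)
  cat$ref <- "G"; cat$alt <- "T"; cat$kind <- "SNP"
  cat
}
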