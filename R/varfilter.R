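## Variant-filtering cascade.
##
## The two external joint callers of the original workflow are not invoked;
## their consensus logic is re-specified as two internal criteria on the
## same pileup: criterion A, a Phred-scaled binomial site score >= qualMin
## (the QUAL >= 100 analogue), and criterion B, a strand-exactness screen
## plus a minimum combined AF (the FILTER = PASS analogue). Thresholds use
## strict inequality for "above 0.04" and "AF > 0.08" and non-strict for
## "QUAL >= 100".

appendFilters <- function(filters, label, hit) {
  ifelse(hit, ifelse(nzchar(filters), paste(filters, label, sep = ";"),
                     label), filters)
}

#' Phred-scaled site score under the error-only model
#'
#' The score is `-10 * log10` of the binomial upper-tail probability of
#' observing at least the seen number of alternate reads if the site were
#' homozygous reference and every alternate read were a miscall landing on
#' this base (success probability `errorRate / 3`). Capped at `qualMax`.
#' Zero alternate reads give a score of exactly 0, and the score is
#' monotone non-decreasing in the alternate count at fixed depth.
#'
#' @param pileup data.frame of pileup sites ([simulatePileup()] layout).
#' @param errorRate per-base miscall probability.
#' @param qualMax cap on the Phred score (default 1000).
#' @return Numeric vector of Phred scores, one per row.
#' @examples
#' p <- data.frame(chrom = "chr", pos = 1L, ref = "C", alt = "A",
#'                 fwd_ref = 180, fwd_alt = 20, rev_ref = 180, rev_alt = 20,
#'                 mean_bq = 33, subculture = 0L, replicate = 1L)
#' scoreSite(p, errorRate = 0.003)
#' @export
scoreSite <- function(pileup, errorRate, qualMax = 1000) {
  depth <- pileup$fwd_ref + pileup$fwd_alt + pileup$rev_ref + pileup$rev_alt
  if (any(depth <= 0))
    stop("undefined score: pileup site with zero depth")
  alt <- pileup$fwd_alt + pileup$rev_alt
  p <- errorRate / 3
  logTail <- pbinom(alt - 1, depth, p, lower.tail = FALSE, log.p = TRUE)
  qual <- -10 * logTail / log(10)
  qual[alt == 0] <- 0
  pmin(qual, qualMax)
}

#' Dual-criterion consensus call at a pileup site
#'
#' Applies criterion A (Phred site score >= `qualMin`, label `low_qual` on
#' failure) and criterion B (combined AF >= `consensusAfMin` and a Fisher
#' exact strand-exactness screen with p >= `strandBiasP`, label
#' `no_consensus` on failure). A site failing either criterion is returned
#' with the corresponding label, never dropped.
#'
#' @param pileup data.frame of pileup sites.
#' @param params a [FilterParams-class].
#' @param errorRate per-base miscall probability used for the site score.
#' @return data.frame of calls: site key columns plus `qual, depth_fwd,
#'   depth_rev, af, af_fwd, af_rev, mean_bq, subculture, replicate` and a
#'   `filters` column (`""` while no rule has failed).
#' @examples
#' set.seed(1)
#' consensusCall(simulatePileup(0.5, seqParams()), filterParams(), 0.001)
#' @export
consensusCall <- function(pileup, params = filterParams(),
                          errorRate = 0.001) {
  pu <- pileupAlleleFrequencies(pileup)
  qual <- scoreSite(pileup, errorRate, params@qualMax)
  filters <- character(nrow(pu))
  filters <- appendFilters(filters, "low_qual", qual < params@qualMin)
  strandP <- vapply(seq_len(nrow(pu)), function(i) {
    m <- matrix(c(pu$fwd_ref[i], pu$fwd_alt[i],
                  pu$rev_ref[i], pu$rev_alt[i]), nrow = 2)
    if (pu$fwd_alt[i] + pu$rev_alt[i] == 0) return(1)
    fisher.test(m)$p.value
  }, numeric(1))
  failB <- (is.na(pu$af) | pu$af < params@consensusAfMin) |
    strandP < params@strandBiasP
  filters <- appendFilters(filters, "no_consensus", failB)
  data.frame(chrom = pu$chrom, pos = pu$pos, ref = pu$ref, alt = pu$alt,
             qual = qual, depth_fwd = pu$depth_fwd,
             depth_rev = pu$depth_rev, af = pu$af, af_fwd = pu$af_fwd,
             af_rev = pu$af_rev, mean_bq = pu$mean_bq,
             subculture = pu$subculture, replicate = pu$replicate,
             filters = filters, stringsAsFactors = FALSE)
}

#' Per-orientation allele-frequency and read-support filter
#'
#' Adds `low_orientation_af` unless the allele frequency is strictly above
#' `afOrientationMin` in both the first-forward and first-reverse strata,
#' and `low_reads` if read support is below `minReads` (per orientation
#' stratum under the default conservative reading, or in total with
#' `minReadsMode = "total"`) or the mean base quality is below `minBq`.
#'
#' @param calls data.frame of calls from [consensusCall()].
#' @param params a [FilterParams-class].
#' @return `calls` with labels appended to `filters`.
#' @export
orientationFilter <- function(calls, params = filterParams()) {
  lowAF <- is.na(calls$af_fwd) | is.na(calls$af_rev) |
    calls$af_fwd <= params@afOrientationMin |
    calls$af_rev <= params@afOrientationMin
  calls$filters <- appendFilters(calls$filters, "low_orientation_af", lowAF)
  lowReads <- if (params@minReadsMode == "per_orientation")
    calls$depth_fwd < params@minReads | calls$depth_rev < params@minReads
  else
    calls$depth_fwd + calls$depth_rev < params@minReads
  lowReads <- lowReads | calls$mean_bq < params@minBq
  calls$filters <- appendFilters(calls$filters, "low_reads", lowReads)
  calls
}

#' Split multiallelic records into biallelic ones
#'
#' Rows whose `alt` is a comma-separated list are expanded to one row per
#' alternate allele; per-alt columns (`fwd_alt`, `rev_alt` and, when
#' present, `af`, `af_fwd`, `af_rev`) holding comma-separated values are
#' distributed across the expanded rows. Positions and reference counts
#' are unchanged, so the per-site alternate AF sum is preserved.
#'
#' @param records data.frame with at least an `alt` column.
#' @return data.frame with one alternate allele per row.
#' @examples
#' rec <- data.frame(chrom = "chr", pos = 10L, ref = "C", alt = "A,T",
#'                   fwd_ref = 90, fwd_alt = "5,10", rev_ref = 85,
#'                   rev_alt = "6,9", mean_bq = 33, subculture = 0L,
#'                   replicate = 1L)
#' splitMultiallelic(rec)
#' @export
splitMultiallelic <- function(records) {
  if (!nrow(records)) return(records)
  alts <- strsplit(as.character(records$alt), ",", fixed = TRUE)
  nAlt <- lengths(alts)
  perAlt <- intersect(c("fwd_alt", "rev_alt", "af", "af_fwd", "af_rev"),
                      names(records))
  idx <- rep(seq_len(nrow(records)), nAlt)
  out <- records[idx, , drop = FALSE]
  out$alt <- unlist(alts)
  which_alt <- unlist(lapply(nAlt, seq_len))
  for (col in perAlt) {
    vals <- strsplit(as.character(records[[col]]), ",", fixed = TRUE)
    bad <- lengths(vals) != nAlt
    vals[bad] <- lapply(which(bad), function(i)
      rep(vals[[i]][1], nAlt[i]))
    out[[col]] <- as.numeric(unlist(vals)[cumsum(nAlt)[idx] - nAlt[idx] +
                                            which_alt])
  }
  rownames(out) <- NULL
  out
}

runLengthAtLeast <- function(hits, k) {
  if (!any(hits)) return(FALSE)
  r <- rle(hits)
  any(r$values & r$lengths >= k)
}

#' Trajectory-level (heatmap) inclusion filter
#'
#' A variant trajectory is kept iff all of: (i) its AF is strictly above
#' `recurrenceAf` in at least `recurrenceCount` subcultures of the
#' replicate (missing AFs, below detection, count as 0); (ii) its position
#' is outside every exclusion interval (rRNA regions); (iii) its
#' subculture-0 AF does not exceed `starterAfMax` (pre-existing starter
#' background); (iv) under the depth-artifact screen, |Spearman rho|
#' between AF and depth across subcultures stays below
#' `depthCorrThreshold` (applied when at least `depthCorrMinPoints`
#' subcultures are available). This last rule generalizes the original
#' workflow's manual removal of one depth-correlated call rather than
#' hard-coding its position.
#'
#' @param traj data.frame for one variant in one replicate with columns
#'   `subculture, af` and optionally `depth, chrom, pos`.
#' @param params a [FilterParams-class].
#' @param exclusions `GRanges` of excluded regions, or `NULL`.
#' @return List with `keep` (logical) and `labels` (character vector of
#'   failed rules).
#' @examples
#' traj <- data.frame(subculture = 0:3, af = c(0.01, 0.09, 0.12, 0.30))
#' trajectoryFilter(traj, filterParams())$keep
#' @export
trajectoryFilter <- function(traj, params = filterParams(),
                             exclusions = NULL) {
  if (!nrow(traj)) stop("trajectory is empty")
  labels <- character()
  af <- traj$af
  af[is.na(af)] <- 0
  hits <- af > params@recurrenceAf
  recurrent <- if (params@consecutiveRecurrence)
    runLengthAtLeast(hits[order(traj$subculture)], params@recurrenceCount)
  else sum(hits) >= params@recurrenceCount
  if (!recurrent) labels <- c(labels, "insufficient_recurrence")

  if (!is.null(exclusions) && length(exclusions) &&
      !is.null(traj$chrom) && !is.null(traj$pos)) {
    gr <- GenomicRanges::GRanges(traj$chrom[1],
                                 IRanges::IRanges(traj$pos[1], traj$pos[1]))
    if (length(GenomicRanges::findOverlaps(gr, exclusions)) > 0)
      labels <- c(labels, "rrna")
  }

  starter <- af[traj$subculture == 0]
  if (length(starter) && starter[1] > params@starterAfMax)
    labels <- c(labels, "starter_background")

  if (params@depthScreen && !is.null(traj$depth) &&
      sum(!is.na(traj$depth)) >= params@depthCorrMinPoints) {
    ok <- !is.na(traj$depth)
    suppressWarnings(
      rho <- stats::cor(af[ok], traj$depth[ok], method = "spearman"))
    if (!is.na(rho) && abs(rho) >= params@depthCorrThreshold)
      labels <- c(labels, "depth_artifact")
  }
  list(keep = length(labels) == 0L, labels = labels)
}

variantKey <- function(df) {
  paste(df$replicate, df$chrom, df$pos, df$ref, df$alt, sep = "\r")
}

#' Run the full variant-filtering cascade
#'
#' Composes the cascade in workflow order: multiallelic splitting, site
#' scoring, dual-criterion consensus, the per-orientation AF/read-support
#' filter, trajectory assembly per (replicate, variant), and the
#' trajectory-level rules. Every rule appends a label and no call is ever
#' silently dropped, so the keep-set is exactly the conjunction of the
#' individual rules. Variants passing the site-level rules in at least one
#' subculture enter the trajectory stage (the joint-called set); their
#' trajectory labels are appended to all of the variant's calls in that
#' replicate.
#'
#' @param pileups data.frame of pileup sites across subcultures and
#'   replicates ([simulatePileup()] layout; `alt` may be multiallelic).
#' @param params a [FilterParams-class].
#' @param errorRate per-base miscall probability for the site score.
#' @param exclusions `GRanges` of excluded (rRNA) regions, or `NULL`.
#' @return List with components `calls` (every call with its accumulated
#'   filter labels), `trajectories` (one row per site-passing variant per
#'   replicate: key columns, recurrence count, starter AF, depth
#'   correlation, `keep` and `labels`), and `keepSet` (the kept variant
#'   keys as a data.frame).
#' @examples
#' truth <- data.frame(chrom = "chr", pos = 500L, ref = "G", alt = "T",
#'                     subculture = 0:4, af = c(0, 0.1, 0.3, 0.5, 0.9))
#' pile <- simulateSeriesPileups(truth, seqParams(), seed = 3)
#' res <- runFilterCascade(pile, filterParams(), errorRate = 0.001)
#' res$keepSet
#' @export
runFilterCascade <- function(pileups, params = filterParams(),
                             errorRate = 0.001, exclusions = NULL) {
  emptyTraj <- data.frame(replicate = integer(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), n_recurrent = integer(),
                          starter_af = numeric(), depth_rho = numeric(),
                          keep = logical(), labels = character(),
                          stringsAsFactors = FALSE)
  if (is.null(pileups) || !nrow(pileups)) {
    calls <- data.frame()
    return(list(calls = calls, trajectories = emptyTraj,
                keepSet = emptyTraj[, 1:5]))
  }
  need <- setdiff(PILEUP_COLUMNS, names(pileups))
  if (length(need))
    stop("pileups are missing required columns: ",
         paste(need, collapse = ", "))

  pileups <- splitMultiallelic(pileups)
  calls <- consensusCall(pileups, params, errorRate)
  calls <- orientationFilter(calls, params)

  sitePass <- !nzchar(calls$filters)
  key <- variantKey(calls)
  joint <- unique(key[sitePass])

  trajRows <- list()
  for (k in joint) {
    member <- which(key == k)
    traj <- calls[member, c("subculture", "af", "chrom", "pos")]
    traj$depth <- calls$depth_fwd[member] + calls$depth_rev[member]
    traj <- traj[order(traj$subculture), ]
    tf <- trajectoryFilter(traj, params, exclusions)
    if (length(tf$labels))
      for (lab in tf$labels)
        calls$filters[member] <- appendFilters(calls$filters[member], lab,
                                               TRUE)
    af0 <- traj$af[traj$subculture == 0]
    ok <- !is.na(traj$depth)
    rho <- if (sum(ok) >= 2)
      suppressWarnings(stats::cor(ifelse(is.na(traj$af), 0, traj$af)[ok],
                                  traj$depth[ok], method = "spearman"))
    else NA_real_
    trajRows[[length(trajRows) + 1L]] <- data.frame(
      replicate = calls$replicate[member][1], chrom = traj$chrom[1],
      pos = traj$pos[1], ref = calls$ref[member][1],
      alt = calls$alt[member][1],
      n_recurrent = sum(traj$af > params@recurrenceAf, na.rm = TRUE),
      starter_af = if (length(af0)) af0[1] else NA_real_,
      depth_rho = rho, keep = tf$keep,
      labels = paste(tf$labels, collapse = ";"), stringsAsFactors = FALSE)
  }
  trajectories <- if (length(trajRows)) do.call(rbind, trajRows) else
    emptyTraj
  keepSet <- trajectories[trajectories$keep,
                          c("replicate", "chrom", "pos", "ref", "alt")]
  rownames(keepSet) <- NULL
  list(calls = calls, trajectories = trajectories, keepSet = keepSet)
}

#' Allele-frequency trajectory matrix for heatmap plotting
#'
#' Pivots cascade output into a variant-by-subculture AF matrix per
#' replicate, the layout used for mutation-frequency heatmaps.
#'
#' @param cascade result of [runFilterCascade()].
#' @param keptOnly restrict to the kept (post-heatmap-filter) set.
#' @return data.frame with key columns and one `sc<k>` column per
#'   subculture.
#' @export
trajectoryMatrix <- function(cascade, keptOnly = TRUE) {
  calls <- cascade$calls
  traj <- cascade$trajectories
  if (keptOnly) traj <- traj[traj$keep, , drop = FALSE]
  if (!nrow(traj)) return(traj)
  subcultures <- sort(unique(calls$subculture))
  key <- variantKey(calls)
  out <- traj[, c("replicate", "chrom", "pos", "ref", "alt")]
  for (sc in subcultures) out[[paste0("sc", sc)]] <- NA_real_
  for (i in seq_len(nrow(traj))) {
    member <- which(key == variantKey(traj[i, ]))
    m <- calls[member, ]
    for (j in seq_len(nrow(m)))
      out[i, paste0("sc", m$subculture[j])] <- m$af[j]
  }
  rownames(out) <- NULL
  out
}
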