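## Synthetic ultra-deep pooled-sequencing pileups.
##
## "First-forward / first-reverse orientation" is modelled abstractly as two
## read strata: the orientation filter only needs two independent sources of
## support, not real read-pair semantics.

PILEUP_COLUMNS <- c("chrom", "pos", "ref", "alt", "fwd_ref", "fwd_alt",
                    "rev_ref", "rev_alt", "mean_bq", "subculture",
                    "replicate")

#' Simulate pileup sites at given true allele frequencies
#'
#' For each true allele frequency, total depth is drawn from a negative
#' binomial (mean `meanDepth`, size `depthDispersion`), split between the
#' forward and reverse orientation strata binomially at
#' `orientationBalance`; alternate reads per stratum are binomial with
#' success probability `af * (1 - eps) + (1 - af) * eps / 3`, the chance
#' that a read reports the alternate base given miscall rate eps. Mean base
#' qualities are Gaussian around `bqMean`, floored at `bqFloor`.
#'
#' @param trueAF numeric vector of true allele frequencies in `[0, 1]`.
#' @param params a [SeqParams-class].
#' @param chrom,pos,ref,alt,subculture,replicate site annotations, recycled
#'   to `length(trueAF)`.
#' @return data.frame with one row per site and columns
#'   `chrom, pos, ref, alt, fwd_ref, fwd_alt, rev_ref, rev_alt, mean_bq,
#'   subculture, replicate`.
#' @examples
#' set.seed(1)
#' simulatePileup(c(0, 0.05, 0.5), seqParams())
#' @export
simulatePileup <- function(trueAF, params = seqParams(), chrom = "chr",
                           pos = seq_along(trueAF), ref = "C", alt = "A",
                           subculture = 0L, replicate = 1L) {
  stopifnot(all(trueAF >= 0 & trueAF <= 1))
  n <- length(trueAF)
  eps <- params@errorRate
  depth <- rnbinom(n, size = params@depthDispersion, mu = params@meanDepth)
  depth <- pmax(depth, 1L)
  fwd <- rbinom(n, depth, params@orientationBalance)
  rev <- depth - fwd
  pAlt <- trueAF * (1 - eps) + (1 - trueAF) * eps / 3
  fwdAlt <- rbinom(n, fwd, pAlt)
  revAlt <- rbinom(n, rev, pAlt)
  bq <- pmax(round(rnorm(n, params@bqMean, 2)), params@bqFloor)
  data.frame(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             fwd_ref = fwd - fwdAlt, fwd_alt = fwdAlt,
             rev_ref = rev - revAlt, rev_alt = revAlt,
             mean_bq = bq,
             subculture = rep_len(as.integer(subculture), n),
             replicate = rep_len(as.integer(replicate), n),
             stringsAsFactors = FALSE)
}

#' Combined and per-orientation allele frequencies of a pileup
#'
#' @param pileup data.frame in the [simulatePileup()] column layout.
#' @return The input with `depth`, `af`, `af_fwd`, `af_rev`, `depth_fwd`
#'   and `depth_rev` columns appended (per-orientation AFs are `NA` where
#'   the stratum has zero depth).
#' @export
pileupAlleleFrequencies <- function(pileup) {
  dFwd <- pileup$fwd_ref + pileup$fwd_alt
  dRev <- pileup$rev_ref + pileup$rev_alt
  depth <- dFwd + dRev
  pileup$depth <- depth
  pileup$depth_fwd <- dFwd
  pileup$depth_rev <- dRev
  pileup$af <- ifelse(depth > 0, (pileup$fwd_alt + pileup$rev_alt) / depth,
                      NA_real_)
  pileup$af_fwd <- ifelse(dFwd > 0, pileup$fwd_alt / dFwd, NA_real_)
  pileup$af_rev <- ifelse(dRev > 0, pileup$rev_alt / dRev, NA_real_)
  pileup
}

#' Sequence a simulated subculture series
#'
#' Generates one pileup per (variant, subculture) from a series' true
#' allele-frequency table, plus a configurable number of allele-free
#' background sites per subculture to exercise false-positive behaviour.
#' Deterministic given `seed`.
#'
#' @param series a [SeriesResult-class], or a data.frame in the layout of
#'   [trueAlleleFrequencies()] (columns `chrom, pos, ref, alt, subculture,
#'   af`).
#' @param params a [SeqParams-class].
#' @param nBackground background (true AF = 0) sites per subculture.
#' @param replicate replicate id stamped on the output.
#' @param seed integer RNG seed.
#' @return data.frame of pileup sites ([simulatePileup()] layout).
#' @examples
#' truth <- data.frame(chrom = "chr", pos = 100L, ref = "G", alt = "T",
#'                     subculture = 0:3, af = c(0, 0.1, 0.4, 0.8))
#' pile <- simulateSeriesPileups(truth, seqParams(), nBackground = 2,
#'                               seed = 7)
#' @export
simulateSeriesPileups <- function(series, params = seqParams(),
                                  nBackground = 0L, replicate = 1L,
                                  seed = 1L) {
  truth <- if (is(series, "SeriesResult")) trueAlleleFrequencies(series)
           else series
  set.seed(as.integer(seed))
  stopifnot(all(truth$af >= 0 & truth$af <= 1))
  subcultures <- sort(unique(truth$subculture))
  out <- list()
  if (nrow(truth)) {
    out[[1L]] <- simulatePileup(truth$af, params, chrom = truth$chrom,
                                pos = truth$pos, ref = truth$ref,
                                alt = truth$alt,
                                subculture = truth$subculture,
                                replicate = replicate)
  }
  if (nBackground > 0L && length(subcultures)) {
    maxPos <- if (nrow(truth)) max(truth$pos) else 0L
    bgPos <- maxPos + seq_len(nBackground) * 1000L
    for (sc in subcultures) {
      out[[length(out) + 1L]] <-
        simulatePileup(rep(0, nBackground), params, pos = bgPos,
                       subculture = sc, replicate = replicate)
    }
  }
  if (!length(out)) {
    empty <- simulatePileup(numeric(0), params)
    return(empty)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicate, res$subculture, res$chrom, res$pos), ]
  rownames(res) <- NULL
  res
}
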