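## Per-isolate mutation accounting, substitution spectrum and hotspot
## enrichment over a mutation catalogue (one row per mutation record per
## isolate; multi-hit positions count once per record, no per-site
## deduplication).

SPECTRUM_CLASSES <- c("G:C>T:A", "G:C>A:T", "G:C>C:G",
                      "A:T>T:A", "A:T>G:C", "A:T>C:G")

#' Mean number of mutations per isolate
#'
#' Total catalogue records divided by the number of isolates sequenced;
#' isolates with zero mutations count in the denominator.
#'
#' @param catalogue data.frame of mutation records (one row each), or an
#'   integer total.
#' @param nIsolates number of isolates (> 0).
#' @return The mean as a single numeric.
#' @examples
#' meanMutationsPerIsolate(211 + 12 + 2, 71)  # 3.169
#' @export
meanMutationsPerIsolate <- function(catalogue, nIsolates) {
  if (nIsolates <= 0) stop("nIsolates must be > 0")
  total <- if (is.data.frame(catalogue)) nrow(catalogue) else
    as.numeric(catalogue)
  total / nIsolates
}

#' Classify a single-nucleotide substitution
#'
#' Maps a ref/alt base pair to one of the six strand-collapsed
#' substitution classes (a G>T on one strand and a C>A on the other are
#' the same event, reported as the `G:C>T:A` class) and labels it as a
#' transition or transversion by the purine/pyrimidine rule. Vectorized.
#'
#' @param ref,alt single `A/C/G/T` bases, `ref != alt`.
#' @return data.frame with columns `class` and `ti_tv`.
#' @examples
#' classifySubstitution("G", "T")  # G:C>T:A, transversion
#' classifySubstitution("A", "G")  # A:T>G:C, transition
#' @export
classifySubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  bases <- c("A", "C", "G", "T")
  if (any(!ref %in% bases) || any(!alt %in% bases) || any(ref == alt))
    stop("classification error: ref and alt must be distinct single bases")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # collapse to the pyrimidine-reference strand
  cref <- ifelse(ref %in% c("C", "T"), ref, comp[ref])
  calt <- ifelse(ref %in% c("C", "T"), alt, comp[alt])
  cls <- ifelse(cref == "C",
                paste0("G:C>", comp[calt], ":", calt),
                paste0("A:T>", comp[calt], ":", calt))
  purine <- c("A", "G")
  ti <- (ref %in% purine) == (alt %in% purine)
  data.frame(class = unname(cls),
             ti_tv = ifelse(ti, "transition", "transversion"),
             stringsAsFactors = FALSE)
}

#' Substitution-spectrum summary of a catalogue
#'
#' Counts and fractions per strand-collapsed substitution class, computed
#' over SNP records only (indels are excluded from the denominator).
#' Fractions sum to 1 over the six classes whenever SNPs exist; with no
#' SNPs the fractions are returned as `NA` and flagged.
#'
#' @param catalogue data.frame with columns `ref`, `alt` and `kind`
#'   (`"SNP"`, `"insertion"`, `"deletion"`).
#' @return List with `counts` (named integer over the six classes plus
#'   indels), `fractions` (named numeric over the six classes), `nSNP`,
#'   and `defined` (FALSE when the SNP denominator is zero).
#' @examples
#' cat <- data.frame(ref = c("G", "C", "A"), alt = c("T", "A", "G"),
#'                   kind = "SNP")
#' spectrumSummary(cat)$fractions
#' @export
spectrumSummary <- function(catalogue) {
  counts <- setNames(integer(length(SPECTRUM_CLASSES)), SPECTRUM_CLASSES)
  nIns <- sum(catalogue$kind == "insertion")
  nDel <- sum(catalogue$kind == "deletion")
  snp <- catalogue[catalogue$kind == "SNP", , drop = FALSE]
  if (nrow(snp)) {
    cls <- classifySubstitution(snp$ref, snp$alt)$class
    tab <- table(factor(cls, levels = SPECTRUM_CLASSES))
    counts[] <- as.integer(tab)
  }
  nSNP <- sum(counts)
  fractions <- if (nSNP > 0) counts / nSNP else
    setNames(rep(NA_real_, length(SPECTRUM_CLASSES)), SPECTRUM_CLASSES)
  list(counts = c(counts, insertion = nIns, deletion = nDel),
       fractions = fractions, nSNP = nSNP, defined = nSNP > 0)
}

geneModelsToGRanges <- function(genes) {
  if (is(genes, "GRanges")) return(genes)
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start, genes$end),
    strand = if (!is.null(genes$strand)) genes$strand else "*")
  names(gr) <- genes$gene_id
  gr
}

#' Assign catalogue mutations to genomic regions
#'
#' Every mutation is assigned to exactly one region: the gene body whose
#' 1-based inclusive bounds contain its position (a mutation at a gene's
#' start or end coordinate belongs to that gene), or a named intergenic
#' region keyed by the flanking gene ids
#' (`intergenic:<left>|<right>`, with `<start>`/`<end>` markers at the
#' chromosome ends). Counts therefore always sum to the catalogue size.
#'
#' @param catalogue data.frame with `chrom` and `pos` columns.
#' @param genes data.frame of gene models (`gene_id, chrom, start, end`,
#'   optional `strand`), assumed non-overlapping, or a `GRanges` with
#'   names.
#' @param chromLengths optional named vector of chromosome lengths, used to
#'   validate positions.
#' @return Named integer vector of counts, one element per hit region.
#' @examples
#' genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr",
#'                     start = c(100L, 500L), end = c(200L, 700L))
#' cat <- data.frame(chrom = "chr", pos = c(100L, 150L, 300L, 600L))
#' regionCounts(cat, genes)
#' @export
regionCounts <- function(catalogue, genes, chromLengths = NULL) {
  gr <- geneModelsToGRanges(genes)
  assignments <- assignRegions(catalogue, gr, chromLengths)
  tab <- table(assignments)
  setNames(as.integer(tab), names(tab))
}

assignRegions <- function(catalogue, gr, chromLengths = NULL) {
  if (!nrow(catalogue)) return(character(0))
  if (!is.null(chromLengths)) {
    len <- chromLengths[as.character(catalogue$chrom)]
    if (any(is.na(len)) || any(catalogue$pos < 1 | catalogue$pos > len))
      stop("mutation position outside chromosome bounds")
  }
  mutGR <- GenomicRanges::GRanges(
    catalogue$chrom, IRanges::IRanges(catalogue$pos, catalogue$pos))
  hit <- GenomicRanges::findOverlaps(mutGR, gr, select = "first")
  out <- character(nrow(catalogue))
  inGene <- !is.na(hit)
  out[inGene] <- names(gr)[hit[inGene]]
  if (any(!inGene)) {
    pre <- GenomicRanges::precede(mutGR[!inGene], gr, select = "first")
    fol <- GenomicRanges::follow(mutGR[!inGene], gr, select = "last")
    left <- ifelse(is.na(fol), "<start>", names(gr)[fol])
    right <- ifelse(is.na(pre), "<end>", names(gr)[pre])
    out[!inGene] <- paste0("intergenic:", left, "|", right)
  }
  out
}

#' Length-aware hotspot enrichment test
#'
#' For each region, the p-value is the upper-tail probability of observing
#' at least the seen number of mutations under a length-proportional
#' uniform placement null: `P(X >= observed)` with
#' `X ~ Binomial(totalMutations, regionLength / genomeLength)` (or a
#' Poisson null with the same mean under `method = "poisson"`). P-values
#' are Benjamini-Hochberg adjusted across regions and a region is declared
#' enriched when its q-value is at or below `fdr`.
#'
#' @param observed named integer vector of per-region mutation counts.
#' @param regionLengths named numeric vector of region lengths (bp),
#'   covering at least the names in `observed`.
#' @param genomeLength total genome length (bp).
#' @param totalMutations total mutations placed (defaults to
#'   `sum(observed)`; pass the catalogue size when `observed` covers only
#'   a subset of regions).
#' @param fdr false-discovery-rate level for the `enriched` flag.
#' @param method `"binomial"` (exact, default) or `"poisson"`.
#' @return data.frame with columns `region, length, observed, expected,
#'   p, q, enriched`, ordered by `p`.
#' @examples
#' hotspotTest(c(hs = 10, bg = 90), c(hs = 1000, bg = 999000),
#'             genomeLength = 1e6)
#' @export
hotspotTest <- function(observed, regionLengths, genomeLength,
                        totalMutations = sum(observed), fdr = 0.05,
                        method = c("binomial", "poisson")) {
  method <- match.arg(method)
  if (genomeLength <= 0) stop("genomeLength must be > 0")
  if (sum(regionLengths[names(observed)]) > genomeLength)
    stop("region lengths exceed genome length")
  lens <- regionLengths[names(observed)]
  if (any(is.na(lens))) stop("regionLengths missing for some regions")
  p0 <- lens / genomeLength
  expected <- totalMutations * p0
  p <- if (method == "binomial")
    pbinom(observed - 1, totalMutations, p0, lower.tail = FALSE)
  else
    ppois(observed - 1, expected, lower.tail = FALSE)
  p[observed == 0] <- 1
  q <- p.adjust(p, method = "BH")
  out <- data.frame(region = names(observed), length = unname(lens),
                    observed = unname(observed),
                    expected = unname(expected), p = unname(p),
                    q = unname(q), enriched = unname(q <= fdr),
                    stringsAsFactors = FALSE)
  out[order(out$p, -out$observed), , drop = FALSE]
}

#' Hotspot scan over gene models
#'
#' Convenience wrapper: assigns a catalogue to regions with
#' [regionCounts()] over the given gene models (regions with zero hits are
#' retained with observed = 0 for genes; intergenic regions appear only
#' when hit) and runs [hotspotTest()].
#'
#' @inheritParams regionCounts
#' @inheritParams hotspotTest
#' @return See [hotspotTest()].
#' @export
hotspotScan <- function(catalogue, genes, genomeLength, fdr = 0.05,
                        method = "binomial") {
  gr <- geneModelsToGRanges(genes)
  counts <- regionCounts(catalogue, gr)
  geneLens <- setNames(GenomicRanges::width(gr), names(gr))
  allCounts <- setNames(integer(length(gr)), names(gr))
  allCounts[intersect(names(counts), names(allCounts))] <-
    counts[intersect(names(counts), names(allCounts))]
  inter <- setdiff(names(counts), names(allCounts))
  interLens <- numeric(0)
  if (length(inter)) {
    gaps <- GenomicRanges::gaps(GenomicRanges::reduce(gr))
    gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
    interLens <- setNames(rep(NA_real_, length(inter)), inter)
    # length of the named intergenic gap: locate by flanking ids
    for (nm in inter) {
      ids <- strsplit(sub("^intergenic:", "", nm), "|", fixed = TRUE)[[1]]
      bounds <- c(
        if (ids[1] != "<start>") GenomicRanges::end(gr[ids[1]]) + 1 else 1,
        if (ids[2] != "<end>") GenomicRanges::start(gr[ids[2]]) - 1 else
          genomeLength)
      interLens[nm] <- max(bounds[2] - bounds[1] + 1, 1)
    }
    allCounts <- c(allCounts, counts[inter])
  }
  hotspotTest(allCounts, c(geneLens, interLens), genomeLength,
              totalMutations = nrow(catalogue), fdr = fdr, method = method)
}
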