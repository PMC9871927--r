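test_that("mean mutations per isolate is total records over isolates", {
  expect_equal(round(meanMutationsPerIsolate(211 + 12 + 2, 71), 2), 3.17)
  expect_identical(meanMutationsPerIsolate(data.frame()[0, ], 10), 0)
  cat <- data.frame(isolate_id = c("a", "b", "b", "c", "c", "c"))
  expect_identical(meanMutationsPerIsolate(cat, 3), 2)
  expect_error(meanMutationsPerIsolate(10, 0), "nIsolates")
})

test_that("substitution classification collapses strands correctly", {
  gt <- classifySubstitution("G", "T")
  expect_identical(gt$class, "G:C>T:A")
  expect_identical(gt$ti_tv, "transversion")
  expect_identical(classifySubstitution("A", "G")$ti_tv, "transition")
  expect_identical(classifySubstitution("C", "A")$class,
                   classifySubstitution("G", "T")$class)

  # complementing ref and alt never changes the collapsed class
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  for (r in bases) for (a in setdiff(bases, r)) {
    expect_identical(classifySubstitution(r, a)$class,
                     classifySubstitution(comp[[r]], comp[[a]])$class)
  }

  expect_error(classifySubstitution("A", "A"), "classification")
  expect_error(classifySubstitution("N", "A"), "classification")
})

test_that("spectrum summary counts SNPs only and normalizes", {
  cat <- data.frame(
    ref = c(rep("G", 50), rep("C", 37), rep("A", 8), rep("C", 5)),
    alt = c(rep("T", 50), rep("A", 37), rep("G", 8), rep("T", 5)),
    kind = "SNP")
  spec <- spectrumSummary(cat)
  expect_identical(unname(spec$counts[["G:C>T:A"]]), 87L)
  expect_equal(unname(spec$fractions[["G:C>T:A"]]), 0.87)
  expect_equal(sum(spec$fractions), 1)

  indels <- data.frame(ref = c("AT", "C"), alt = c("A", "CG"),
                       kind = c("deletion", "insertion"))
  mixed <- spectrumSummary(rbind(cat, indels))
  expect_identical(mixed$nSNP, 100L)
  expect_identical(unname(mixed$counts[["deletion"]]), 1L)

  none <- spectrumSummary(indels)
  expect_false(none$defined)
  expect_true(all(is.na(none$fractions)))
})

test_that("region assignment is exhaustive with inclusive gene bounds", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr",
                      start = c(100L, 500L), end = c(200L, 700L),
                      strand = "+")
  cat <- data.frame(chrom = "chr",
                    pos = c(100L, 200L, 150L, 300L, 600L, 50L, 900L))
  counts <- regionCounts(cat, genes)
  expect_identical(unname(counts[["g1"]]), 3L)       # inclusive both ends
  expect_identical(unname(counts[["g2"]]), 1L)
  expect_identical(unname(counts[["intergenic:g1|g2"]]), 1L)
  expect_identical(unname(counts[["intergenic:<start>|g1"]]), 1L)
  expect_identical(unname(counts[["intergenic:g2|<end>"]]), 1L)
  expect_identical(sum(counts), nrow(cat))

  expect_identical(length(regionCounts(cat[0, ], genes)), 0L)
  expect_error(
    regionCounts(data.frame(chrom = "chr", pos = 5000L), genes,
                 chromLengths = c(chr = 1000)),
    "outside chromosome bounds")

  # conservation on a random catalogue
  set.seed(9)
  rand <- data.frame(chrom = "chr", pos = sample.int(1000, 200,
                                                     replace = TRUE))
  expect_identical(sum(regionCounts(rand, genes)), 200L)
})

test_that("hotspot test matches the exact binomial tail oracle", {
  # oracle computed by explicit density summation
  oracleP <- sum(dbinom(10:100, 100, 1000 / 1e6))
  res <- hotspotTest(c(hs = 10L, rest = 90L),
                     c(hs = 1000, rest = 999000), genomeLength = 1e6)
  expect_equal(res$p[res$region == "hs"], oracleP, tolerance = 1e-12)
  expect_true(res$enriched[res$region == "hs"])

  zero <- hotspotTest(c(a = 0L, b = 5L), c(a = 1000, b = 2000),
                      genomeLength = 1e6, totalMutations = 5)
  expect_identical(zero$p[zero$region == "a"], 1)

  # BH keeps q >= p and preserves ordering
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(hotspotTest(c(a = 1L), c(a = 10), genomeLength = 0),
               "genomeLength")
})

test_that("hotspot p-values are super-uniform under uniform placement", {
  genes <- tilingGenes(nGenes = 200, geneLength = 1000)
  genomeLength <- 200 * 1000
  p0 <- 1000 / genomeLength
  set.seed(10)
  pvals <- replicate(400, {
    hits <- tabulate(sample.int(200, 50, replace = TRUE), nbins = 200)
    p <- pbinom(hits - 1, 50, p0, lower.tail = FALSE)
    p[sample.int(200, 1)]
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    se <- sqrt(alpha * (1 - alpha) / length(pvals))
    expect_lte(mean(pvals <= alpha), alpha + 3 * se)
  }
})

test_that("hotspot scan recovers constructed enrichment exactly", {
  genes <- tilingGenes(nGenes = 500, geneLength = 1200)
  genomeLength <- 500 * 1200
  cat <- enrichedCatalogue(genes, enrichedIdx = c(10, 120, 300, 450),
                           nEnrichedHits = 60, nBackground = 60, seed = 11)
  res <- hotspotScan(cat, genes, genomeLength, fdr = 0.05)
  expect_identical(sort(res$region[res$enriched]),
                   sort(genes$gene_id[c(10, 120, 300, 450)]))
})
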