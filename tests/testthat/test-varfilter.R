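test_that("site score matches the exact binomial tail and is monotone", {
  expect_identical(scoreSite(makeSite(200, 0, 200, 0), 0.003), 0)

  # independent oracle: explicit density sum for P(X >= 40 | 400, 0.001)
  tail40 <- sum(dbinom(40:400, 400, 0.003 / 3))
  site <- makeSite(180, 20, 180, 20)
  q <- scoreSite(site, 0.003)
  expect_gt(q, 100)
  expect_equal(q, -10 * log10(tail40), tolerance = 1e-6)

  quals <- vapply(0:30, function(a)
    scoreSite(makeSite(200 - a, a, 200, 0), 0.003), numeric(1))
  expect_true(all(diff(quals) >= 0))

  expect_error(scoreSite(makeSite(0, 0, 0, 0), 0.003), "zero depth")
  # zero error rate: any alt support hits the score cap
  expect_identical(scoreSite(makeSite(199, 1, 200, 0), 0), 1000)
})

test_that("consensus calling applies both criteria and never drops a site", {
  params <- filterParams()
  noAlt <- consensusCall(makeSite(92, 0, 92, 0), params, 0.001)
  expect_match(noAlt$filters, "low_qual")

  clean <- consensusCall(makeSite(92, 92, 92, 92), params, 0.001)
  expect_identical(clean$filters, "")
  expect_equal(clean$af, 0.5)

  # passes criterion A (huge score) but fails strand exactness
  biased <- consensusCall(makeSite(160, 40, 200, 0), params, 0.001)
  expect_gt(biased$qual, 100)
  expect_match(biased$filters, "no_consensus")
  expect_identical(nrow(biased), 1L)
})

test_that("orientation filter applies the per-stratum AF and read rules", {
  params <- filterParams()
  asCall <- function(site) consensusCall(site, params, 0.001)

  pass <- orientationFilter(asCall(makeSite(45, 5, 54, 6)), params)
  expect_false(grepl("low_orientation_af|low_reads", pass$filters))

  oneLow <- orientationFilter(asCall(makeSite(95, 5, 97, 3)), params)
  expect_match(oneLow$filters, "low_orientation_af")

  # AF exactly 0.04 fails the strict inequality
  border <- orientationFilter(asCall(makeSite(48, 2, 48, 2)), params)
  expect_match(border$filters, "low_orientation_af")

  thin <- orientationFilter(asCall(makeSite(1, 2, 50, 10)), params)
  expect_match(thin$filters, "low_reads")

  lowBq <- orientationFilter(asCall(makeSite(45, 5, 45, 5, mean_bq = 15)),
                             params)
  expect_match(lowBq$filters, "low_reads")

  # alternative reading: total reads only
  totalMode <- orientationFilter(asCall(makeSite(1, 2, 50, 10)),
                                 filterParams(minReadsMode = "total"))
  expect_false(grepl("low_reads", totalMode$filters))
})

test_that("multiallelic splitting preserves per-alt counts and round-trips", {
  single <- makeSite(90, 10, 85, 9)
  expect_identical(splitMultiallelic(single), single)

  multi <- makeSite(90, "5,10", 85, "6,9", alt = "A,T")
  out <- splitMultiallelic(multi)
  expect_identical(nrow(out), 2L)
  expect_identical(out$alt, c("A", "T"))
  expect_identical(out$fwd_alt, c(5, 10))
  expect_identical(out$rev_alt, c(6, 9))
  expect_identical(sum(out$fwd_alt), 15)
  # re-merging by site recovers the original alt set
  merged <- tapply(out$alt, paste(out$chrom, out$pos), paste,
                   collapse = ",")
  expect_identical(as.vector(merged), "A,T")
})

test_that("trajectory rules follow the recurrence/starter/exclusion logic", {
  params <- filterParams()
  keep <- trajectoryFilter(
    data.frame(subculture = 0:3, af = c(0.01, 0.09, 0.12, 0.30)), params)
  expect_true(keep$keep)

  few <- trajectoryFilter(
    data.frame(subculture = 0:3, af = c(0.09, 0.09, 0.05, 0.02)), params)
  expect_false(few$keep)
  expect_identical(few$labels, "insufficient_recurrence")

  starter <- trajectoryFilter(
    data.frame(subculture = 0:3, af = c(0.6, 0.3, 0.3, 0.3)), params)
  expect_true("starter_background" %in% starter$labels)

  rrna <- trajectoryFilter(
    data.frame(subculture = 0:3, af = c(0.01, 0.09, 0.12, 0.30),
               chrom = "chr", pos = 15L),
    params,
    exclusions = GenomicRanges::GRanges("chr",
                                        IRanges::IRanges(10, 20)))
  expect_identical(rrna$labels, "rrna")

  # AF tracking depth across >= 6 subcultures is a depth artifact
  depthArt <- trajectoryFilter(
    data.frame(subculture = 0:7, af = seq(0.1, 0.45, length.out = 8),
               depth = seq(200, 480, length.out = 8)), params)
  expect_identical(depthArt$labels, "depth_artifact")

  # consecutive-recurrence variant of the rule
  gappy <- data.frame(subculture = 0:6,
                      af = c(0.09, 0.01, 0.09, 0.01, 0.09, 0.01, 0.09))
  expect_true(trajectoryFilter(gappy, filterParams(depthScreen = FALSE))$keep)
  expect_false(trajectoryFilter(
    gappy, filterParams(consecutiveRecurrence = TRUE,
                        depthScreen = FALSE))$keep)

  # missing AFs count as zero for recurrence
  nas <- trajectoryFilter(
    data.frame(subculture = 0:3, af = c(NA, 0.09, NA, 0.09)), params)
  expect_false(nas$keep)
})

test_that("cascade equals the independent-rule oracle and is deterministic", {
  pile <- randomPileupPanel(60, nSubcultures = 5, seed = 21)
  res <- runFilterCascade(pile, filterParams(), errorRate = 0.001)
  expect_identical(cascadeKeepKeys(res), oracleKeepSet(pile))

  res2 <- runFilterCascade(pile, filterParams(), errorRate = 0.001)
  expect_identical(res$calls, res2$calls)
  expect_identical(res$trajectories, res2$trajectories)

  # with exclusion regions covering some variants
  excl <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 500))
  resEx <- runFilterCascade(pile, filterParams(), errorRate = 0.001,
                            exclusions = excl)
  expect_identical(cascadeKeepKeys(resEx),
                   oracleKeepSet(pile, exclusions = excl))
})

test_that("cascade output is label-complete and never drops calls", {
  pile <- randomPileupPanel(40, nSubcultures = 5, seed = 31)
  res <- runFilterCascade(pile, filterParams(), errorRate = 0.001)
  expect_identical(nrow(res$calls), nrow(pile))

  keys <- with(res$keepSet, paste(replicate, chrom, pos, ref, alt))
  callKeys <- with(res$calls, paste(replicate, chrom, pos, ref, alt))
  # every kept variant has at least one fully clean call ...
  for (k in keys)
    expect_true(any(!nzchar(res$calls$filters[callKeys == k])))
  # ... and every fully clean call belongs to a kept variant
  expect_true(all(callKeys[!nzchar(res$calls$filters)] %in% keys))

  labels <- unlist(strsplit(res$calls$filters[nzchar(res$calls$filters)],
                            ";"))
  expect_true(all(labels %in% degeneR:::FILTER_LABELS))

  empty <- runFilterCascade(pile[0, ], filterParams())
  expect_identical(nrow(empty$trajectories), 0L)
  expect_identical(nrow(empty$keepSet), 0L)
})

test_that("a strong persistent variant survives the full cascade", {
  truth <- data.frame(chrom = "chr", pos = 777L, ref = "G", alt = "T",
                      subculture = 1:5, af = 0.5)
  hits <- vapply(1:200, function(seed) {
    pile <- simulateSeriesPileups(truth, seqParams(), seed = seed)
    nrow(runFilterCascade(pile, filterParams(),
                          errorRate = 0.001)$keepSet) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
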