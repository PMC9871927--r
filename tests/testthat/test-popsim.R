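test_that("dilution is binomial thinning with unbiased composition", {
  # enumeration oracle at small N: E[transferred] = N * d exactly
  enumMean <- function(N, d) sum(0:N * dbinom(0:N, N, d))
  expect_equal(enumMean(5, 0.1), 0.5)

  set.seed(11)
  regime <- regimeConfig(dilutionFactor = 0.1)
  st <- populationState(c(a = 5, b = 5))
  draws <- replicate(2000, {
    out <- applyDilution(st, regime)
    vegetativeCounts(out)
  })
  se <- sqrt(5 * 0.1 * 0.9 / 2000)
  expect_lt(abs(mean(draws["a", ]) - enumMean(5, 0.1)), 3 * se)
  expect_lt(abs(mean(draws["b", ]) - enumMean(5, 0.1)), 3 * se)

  # large-N expectation: N = 1e9 at 1:10 transfers ~1e8
  set.seed(12)
  big <- applyDilution(populationState(c(WT = 1e9)), regime)
  expect_lt(abs(vegetativeCounts(big)[["WT"]] - 1e8), 5 * sqrt(1e9 * 0.09))

  expect_error(applyDilution(st, regimeConfig(dilutionFactor = 1)),
               "nSubcultures|dilutionFactor")
})

test_that("heat shock kills vegetative cells and germinates spores", {
  set.seed(1)
  st <- populationState(c(WT = 1e8, FW = 1e7), spores = c(WT = 1e6, FW = 0))
  out <- applyHeatShock(st, germinationEfficiency = 1.0)
  expect_identical(unname(vegetativeCounts(out)[c("WT", "FW")]), c(1e6, 0))
  expect_true(all(sporeCounts(out) == 0))

  # binomial germination expectation at efficiency 0.5
  set.seed(2)
  survivors <- replicate(1000, {
    s <- applyHeatShock(populationState(c(WT = 0), spores = c(WT = 1e6)),
                        0.5)
    vegetativeCounts(s)[["WT"]]
  })
  expect_lt(abs(mean(survivors) - 5e5), 3 * sqrt(1e6 * 0.25 / 1000))

  expect_error(
    applyHeatShock(populationState(c(WT = 100)), 0.5),
    class = "degeneR_extinction")
})

test_that("growth reproduces the one-log sporulation drop", {
  set.seed(3)
  regime <- regimeConfig(carryingCapacity = 1e9)
  st <- populationState(c(WT = 1e8))
  out <- growTransfer(st, list(genotypeClass("WT", sporulationFraction = 0.9)),
                      regime)
  veg <- vegetativeCounts(out)[["WT"]]
  # 1e9 pre-sporulation, 90% sporulate: vegetative ~1e8 (one-log drop)
  expect_lt(abs(veg - 1e8), 5 * sqrt(1e9 * 0.09))
  expect_lt(abs(sporeCounts(out)[["WT"]] - 9e8), 5 * sqrt(1e9 * 0.09))
  expect_equal(out@solventsGL, 7.2, tolerance = 1e-6)
})

test_that("equal-fitness growth leaves expected frequencies unchanged", {
  set.seed(4)
  classes <- list(genotypeClass("a", sporulationFraction = 0),
                  genotypeClass("b", sporulationFraction = 0))
  regime <- regimeConfig(carryingCapacity = 1e5, mutationRate = 0)
  finals <- replicate(400, {
    out <- growTransfer(populationState(c(a = 5000, b = 5000)), classes,
                        regime)
    v <- vegetativeCounts(out)
    v[["a"]] / sum(v)
  })
  # neutral drift only: mean frequency stays 0.5
  expect_lt(abs(mean(finals) - 0.5), 3 * sd(finals) / sqrt(length(finals)))
})

test_that("selection matches the deterministic logistic recursion", {
  classes <- list(genotypeClass("mut", baselineFitness = 1.2,
                                sporulationFraction = 0),
                  genotypeClass("wt", sporulationFraction = 0))
  # g = log2(K/N0) = 10 exact generations
  regime <- regimeConfig(carryingCapacity = 1024 * 1000,
                         mutationRate = 0)
  expected <- logisticRecursion(0.5, 0.2, 10)
  set.seed(5)
  finals <- replicate(1000, {
    out <- growTransfer(populationState(c(mut = 500, wt = 500)), classes,
                        regime)
    v <- vegetativeCounts(out)
    v[["mut"]] / sum(v)
  })
  expect_lt(abs(mean(finals) - expected),
            3 * sd(finals) / sqrt(length(finals)))
})

test_that("spawned mutations follow the configured spectrum and templates", {
  st <- populationState(c(WT = 1e6))
  regime0 <- regimeConfig(mutationRate = 0)
  out <- spawnMutations(st, regime0, classes = list(genotypeClass("WT")),
                        births = 1e6)
  expect_identical(nrow(out$ledger), 0L)
  expect_identical(length(out$classes), 1L)

  # realized SNP-class fraction matches the 87% G:C>T:A weight
  set.seed(6)
  region <- defaultTargetWeights()[5, ]
  recs <- do.call(rbind, replicate(
    12000, degeneR:::drawMutationRecord(region, defaultSpectrum()),
    simplify = FALSE))
  snps <- recs[recs$kind == "SNP", ]
  frac <- mean(classifySubstitution(snps$ref, snps$alt)$class == "G:C>T:A")
  expect_lt(abs(frac - 0.87), 0.01)
  # indel records have length-consistent ref/alt
  dels <- recs[recs$kind == "deletion", ]
  expect_true(all(nchar(dels$ref) > nchar(dels$alt)))

  # a spo0A-region hit founds a Spo0A-null class
  set.seed(7)
  spo0aOnly <- defaultTargetWeights()
  spo0aOnly$weight <- c(0, 1, 0, 0, 0)
  sp <- spawnMutations(st, regimeConfig(mutationRate = 5e-6),
                       targetWeights = spo0aOnly,
                       classes = list(genotypeClass("WT")), births = 1e6)
  expect_gt(nrow(sp$ledger), 0)
  newCl <- sp$classes[[2]]
  expect_identical(newCl@sporulationFraction, 0)
  expect_identical(newCl@solventYield, 0)
  expect_identical(newCl@morphotype, "FW")
  expect_true(all(sp$ledger$region == "hotspot2_spo0A"))

  expect_error(
    spawnMutations(st, regimeConfig(mutationRate = 1e-6),
                   targetWeights = transform(defaultTargetWeights(),
                                             weight = 0),
                   classes = list(genotypeClass("WT")), births = 1e6),
    "weights")
})

test_that("simulateSeries is deterministic and keeps counts sane", {
  regime <- regimeConfig(nSubcultures = 4L, carryingCapacity = 1e6,
                         mutationRate = 1e-6)
  a <- simulateSeries(defaultClasses(), regime, seed = 99)
  b <- simulateSeries(defaultClasses(), regime, seed = 99)
  expect_identical(seriesStates(a), seriesStates(b))
  expect_identical(mutationLedger(a), mutationLedger(b))
  expect_identical(trueAlleleFrequencies(a), trueAlleleFrequencies(b))
  expect_identical(seriesPhenotypes(a), seriesPhenotypes(b))

  st <- seriesStates(a)
  expect_true(all(st$vegetative >= 0 & st$spores >= 0))
  expect_true(all(st$vegetative == round(st$vegetative)))
  af <- trueAlleleFrequencies(a)
  expect_true(all(af$af >= 0 & af$af <= 1))
})

test_that("heat shock regime zeroes non-sporulating lineages in every run", {
  regime <- regimeConfig(nSubcultures = 3L, carryingCapacity = 1e6,
                         mutationRate = 0, heatShock = TRUE)
  for (seed in 1:10) {
    res <- simulateSeries(defaultClasses(withNull = TRUE), regime,
                          seed = seed,
                          initialFractions = c(WT = 0.9, spo0A_null = 0.1))
    st <- seriesStates(res)
    late <- st[st$subculture >= 1 & st$genotype == "spo0A_null", ]
    expect_true(all(late$vegetative == 0))
  }
})

test_that("growth signals extinction and invalid regimes", {
  expect_error(
    growTransfer(populationState(c(WT = 0)), list(genotypeClass("WT")),
                 regimeConfig()),
    class = "degeneR_extinction")
  expect_error(
    growTransfer(populationState(c(WT = 1e8)), list(genotypeClass("WT")),
                 regimeConfig(carryingCapacity = 1e7)),
    "carrying capacity")
})
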