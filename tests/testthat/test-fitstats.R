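test_that("relative fitness follows the odds-ratio formula", {
  expect_equal(relativeFitness(0.5, 0.5), 1.0)
  expect_equal(relativeFitness(0.1, 0.5), 9.0)
  expect_equal(relativeFitness(0.9, 0.5), 1 / 9)

  # antisymmetry and monotonicity on a random grid
  set.seed(13)
  x1 <- runif(200, 0.01, 0.99)
  x2 <- runif(200, 0.01, 0.99)
  expect_equal(relativeFitness(x1, x2) * relativeFitness(x2, x1),
               rep(1, 200))
  xs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(relativeFitness(0.3, xs)) > 0))
  expect_true(all((relativeFitness(x1, x2) == 1) == (x1 == x2)))
})

test_that("boundary proportions are flagged, never silent infinities", {
  w <- relativeFitness(c(0.5, 0), c(0.2, 0.5))
  expect_true(is.na(w[2]) && !is.na(w[1]))
  expect_identical(attr(w, "boundary"), 2L)
  expect_error(relativeFitness(1, 0.5, boundary = "error"), "boundary")
  expect_error(relativeFitness(-0.1, 0.5), "proportions")
})

test_that("generations accounting matches the dilution arithmetic", {
  expect_equal(generationsElapsed(5, 0.1), 5 * log2(10))
  expect_equal(round(generationsElapsed(5, 0.1), 1), 16.6)
  expect_identical(generationsElapsed(0, 0.1), 0)
  expect_equal(generationsElapsed(1, 0.5), 1.0)
  # additivity
  expect_equal(generationsElapsed(7, 0.1),
               generationsElapsed(3, 0.1) + generationsElapsed(4, 0.1))
  expect_error(generationsElapsed(5, 1.2), "dilutionFactor")
})

test_that("percent change is signed and matches the solvent/acid figures", {
  expect_equal(percentChange(7.23, 1.44), -80.08, tolerance = 1e-3)
  expect_equal(percentChange(1.95, 5.76), 195.38, tolerance = 1e-2)
  expect_identical(percentChange(5, 5), 0)
  expect_error(percentChange(0, 5), "initial")
})

test_that("frequency dependence is detected and crossover interpolated", {
  # constructed data: w > 1 below x1 = 0.6, w < 1 above 0.8
  xs <- c(0.2, 0.4, 0.6, 0.7, 0.8, 0.9)
  obs <- data.frame(x1 = rep(xs, each = 4),
                    w = rep(c(3, 2, 1.5, 1.2, 0.8, 0.5), each = 4) +
                      rep(c(-0.02, -0.01, 0.01, 0.02), times = 6))
  fd <- frequencyDependence(obs)
  expect_true(fd$negative_freq_dependence)
  expect_lt(fd$rho, 0)
  expect_gt(fd$crossover, 0.6)
  expect_lt(fd$crossover, 0.8)

  # constant fitness: no dependence declared
  flat <- data.frame(x1 = rep(xs, each = 4),
                     w = 1.2 + rep(c(-0.02, -0.01, 0.01, 0.02), times = 6))
  expect_false(frequencyDependence(flat)$negative_freq_dependence)

  expect_error(
    frequencyDependence(data.frame(x1 = c(0.1, 0.1, 0.2), w = 1:3)),
    "at least 5")
})

test_that("simulated competitions recover the programmed dependence sign", {
  fw <- defaultClasses(withNull = TRUE)[[2]]
  wt <- genotypeClass("WT")
  set.seed(14)
  hits <- vapply(1:20, function(i) {
    x1s <- rep(seq(0.05, 0.95, length.out = 10), 3)
    obs <- do.call(rbind, lapply(x1s, function(x1) {
      cc <- simulateCompetition(fw, wt, x1, inoculumSize = 1e6)
      data.frame(x1 = cc$x1, w = cc$w)
    }))
    frequencyDependence(obs)$negative_freq_dependence
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # the crossover sits near the parameterized 1 - 1/b over c
  set.seed(15)
  x1s <- rep(seq(0.05, 0.95, length.out = 12), 5)
  obs <- do.call(rbind, lapply(x1s, function(x1) {
    cc <- simulateCompetition(fw, wt, x1, inoculumSize = 1e6)
    data.frame(x1 = cc$x1, w = cc$w)
  }))
  fd <- frequencyDependence(obs)
  expect_gt(fd$crossover, 0.6)
  expect_lt(fd$crossover, 0.95)
})

test_that("series summaries report extremes, changes and dominance", {
  flat <- data.frame(subculture = 0:2, solvents_gl = 5, acids_gl = 2,
                     spores_cfu = 1e8, frac_RD = 0.6, frac_DCOG = 0.4,
                     frac_CIC = 0, frac_FW = 0)
  rep1 <- summarizeSeries(flat)
  expect_identical(rep1$solvent_change_pct, 0)
  expect_identical(unname(rep1$dominant_morphotype), rep("RD", 3))

  two <- data.frame(subculture = 0:1, solvents_gl = c(10, 2),
                    acids_gl = c(1, 2), spores_cfu = c(1e8, 1e6),
                    frac_RD = c(0.9, 0.1), frac_DCOG = 0,
                    frac_CIC = 0, frac_FW = c(0.1, 0.9))
  rep2 <- summarizeSeries(two)
  expect_equal(rep2$solvent_change_pct, -80)
  expect_identical(unname(rep2$dominant_morphotype), c("RD", "FW"))
  expect_equal(rep2$spore_log10, c(8, 6))
  expect_identical(rep2$solvent_max$subculture, 0L)

  # dominance ties break on the fixed morphotype order
  tie <- data.frame(subculture = 0:1, solvents_gl = 1, acids_gl = 1,
                    spores_cfu = 1, frac_RD = 0.5, frac_DCOG = 0.5,
                    frac_CIC = 0, frac_FW = 0)
  expect_identical(unname(summarizeSeries(tie)$dominant_morphotype),
                   rep("RD", 2))

  expect_error(summarizeSeries(flat[1, ]), "at least 2")
})
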