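## Relative-fitness and phenotype-trajectory statistics.

#' Relative fitness from before/after proportions
#'
#' Computes the odds-ratio relative fitness
#' `w = [x2 (1 - x1)] / [x1 (1 - x2)]`, comparing a mutant's proportion
#' before (`x1`) and after (`x2`) competition. `w > 1` means the mutant
#' outcompetes the reference; `w = 1` iff `x1 = x2`. Satisfies the
#' antisymmetry `w(x1, x2) * w(x2, x1) = 1` and is strictly increasing in
#' `x2` at fixed `x1`. Vectorized.
#'
#' Proportions on the boundary (0 or 1), which arise when one competitor
#' drops below plating detection, leave `w` undefined: such elements are
#' returned as `NA` with a `"boundary"` attribute marking them (never a
#' silent infinity); with `boundary = "error"` they raise an error.
#'
#' @param x1 initial mutant proportion(s) in `(0, 1)`.
#' @param x2 mutant proportion(s) at the timepoint, in `(0, 1)`.
#' @param boundary `"flag"` (default) or `"error"`.
#' @return Numeric vector of fitness values; flagged elements are `NA` and
#'   indexed in `attr(, "boundary")`.
#' @examples
#' relativeFitness(0.5, 0.5)  # 1
#' relativeFitness(0.1, 0.5)  # 9
#' relativeFitness(0.9, 0.5)  # 1/9
#' @export
relativeFitness <- function(x1, x2, boundary = c("flag", "error")) {
  boundary <- match.arg(boundary)
  if (any(x1 < 0 | x1 > 1 | x2 < 0 | x2 > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  bad <- x1 <= 0 | x1 >= 1 | x2 <= 0 | x2 >= 1
  if (any(bad, na.rm = TRUE) && boundary == "error")
    stop("undefined fitness: proportion at boundary 0 or 1")
  w <- (x2 * (1 - x1)) / (x1 * (1 - x2))
  w[bad] <- NA_real_
  if (any(bad, na.rm = TRUE)) attr(w, "boundary") <- which(bad)
  w
}

#' Generations elapsed over serial transfers
#'
#' Each 1:d transfer requires `log2(1/d)` doublings to restore the
#' population, so `g = nTransfers * log2(1 / dilutionFactor)`; five 1:10
#' transfers give 16.6 generations.
#'
#' @param nTransfers number of transfers (>= 0).
#' @param dilutionFactor transferred fraction in `(0, 1)`.
#' @return Generations as a single numeric.
#' @examples
#' generationsElapsed(5, 0.1)  # 16.61
#' @export
generationsElapsed <- function(nTransfers, dilutionFactor) {
  if (nTransfers < 0) stop("nTransfers must be >= 0")
  if (dilutionFactor <= 0 || dilutionFactor >= 1)
    stop("dilutionFactor must be strictly inside (0, 1)")
  nTransfers * log2(1 / dilutionFactor)
}

#' Signed percent change
#'
#' `100 * (final - initial) / initial`; negative values are decreases
#' (reported in text as "<magnitude>% decrease").
#'
#' @param initial baseline value (> 0).
#' @param final value at the endpoint.
#' @return Signed percent change.
#' @examples
#' percentChange(7.23, 1.44)  # -80.1, an 80% decrease
#' percentChange(1.95, 5.76)  # +195.4
#' @export
percentChange <- function(initial, final) {
  if (any(initial <= 0)) stop("initial must be > 0")
  100 * (final - initial) / initial
}

#' Frequency-dependence analysis of fitness observations
#'
#' Tests whether relative fitness declines with the mutant's initial
#' frequency: Spearman rank correlation of `w` against `x1` (negative
#' frequency dependence is declared iff the correlation is negative with
#' p < `alpha`), a sign summary, and the crossover frequency where the
#' fitted fitness equals 1, estimated by monotone (antitonic)
#' interpolation of the median `w` per distinct `x1`.
#'
#' @param observations data.frame with columns `x1` and either `w` or
#'   `x2` (in which case `w` is computed via [relativeFitness()]).
#' @param alpha significance level for the declaration (default 0.05).
#' @return List with `rho`, `p_value`, `negative_freq_dependence`,
#'   `n_w_above_1`, `n_w_below_1`, and `crossover` (`NA` when the fitted
#'   fitness never crosses 1 inside the observed `x1` range).
#' @examples
#' obs <- data.frame(x1 = rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 3))
#' obs$w <- 2 - 1.8 * obs$x1 + rnorm(nrow(obs), 0, 0.05)
#' frequencyDependence(obs)
#' @export
frequencyDependence <- function(observations, alpha = 0.05) {
  if (is.null(observations$w)) {
    observations$w <- relativeFitness(observations$x1, observations$x2)
  }
  obs <- observations[!is.na(observations$w), , drop = FALSE]
  if (nrow(obs) < 5 || length(unique(obs$x1)) < 3)
    stop("need at least 5 observations spanning 3 distinct x1 values")
  ct <- suppressWarnings(cor.test(obs$x1, obs$w, method = "spearman"))
  rho <- unname(ct$estimate)
  declared <- !is.na(rho) && rho < 0 && ct$p.value < alpha

  xs <- sort(unique(obs$x1))
  med <- vapply(xs, function(x) median(obs$w[obs$x1 == x]), numeric(1))
  # antitonic fit (monotone non-increasing median fitness)
  iso <- isoreg(xs, -med)
  fit <- -iso$yf
  crossover <- NA_real_
  if (any(fit > 1) && any(fit < 1)) {
    above <- which(fit > 1)
    below <- which(fit < 1)
    i <- max(above[above < min(below)])
    j <- min(below[below > i])
    crossover <- approx(fit[c(i, j)], xs[c(i, j)], xout = 1)$y
  }
  list(rho = rho, p_value = ct$p.value,
       negative_freq_dependence = declared,
       n_w_above_1 = sum(obs$w > 1), n_w_below_1 = sum(obs$w < 1),
       crossover = crossover)
}

#' Summarize a phenotype trajectory
#'
#' Deterministic report over a phenotype series: maximum and minimum
#' solvent concentrations with their subculture indices, signed percent
#' changes of solvents and acids from the first to the last subculture,
#' the log10 heat-resistant spore trajectory, and the dominant morphotype
#' per subculture (ties broken by the fixed order RD, DCOG, CIC, FW).
#'
#' @param series data.frame in the layout of [seriesPhenotypes()]:
#'   columns `subculture, solvents_gl, acids_gl, spores_cfu` and
#'   `frac_RD, frac_DCOG, frac_CIC, frac_FW`.
#' @return List with `solvent_max`, `solvent_min` (value + subculture),
#'   `solvent_change_pct`, `acid_change_pct`, `spore_log10` (vector), and
#'   `dominant_morphotype` (character vector by subculture).
#' @examples
#' res <- simulateSeries(defaultClasses(), regimeConfig(nSubcultures = 2,
#'                       carryingCapacity = 1e5, mutationRate = 0), seed = 1)
#' summarizeSeries(seriesPhenotypes(res))
#' @export
summarizeSeries <- function(series) {
  if (is.null(series) || nrow(series) < 2)
    stop("phenotype series must cover at least 2 subcultures")
  series <- series[order(series$subculture), , drop = FALSE]
  solv <- series$solvents_gl
  iMax <- which.max(solv); iMin <- which.min(solv)
  fracCols <- paste0("frac_", MORPHOTYPES)
  dom <- apply(series[, fracCols, drop = FALSE], 1L, function(fr)
    MORPHOTYPES[which.max(fr)])
  first <- series[1L, ]; last <- series[nrow(series), ]
  list(
    solvent_max = list(value = solv[iMax],
                       subculture = series$subculture[iMax]),
    solvent_min = list(value = solv[iMin],
                       subculture = series$subculture[iMin]),
    solvent_change_pct = if (first$solvents_gl > 0)
      percentChange(first$solvents_gl, last$solvents_gl) else NA_real_,
    acid_change_pct = if (first$acids_gl > 0)
      percentChange(first$acids_gl, last$acids_gl) else NA_real_,
    spore_log10 = ifelse(series$spores_cfu > 0,
                         log10(series$spores_cfu), -Inf),
    dominant_morphotype = setNames(dom, series$subculture)
  )
}
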