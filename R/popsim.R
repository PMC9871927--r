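## Serial-passage population simulator.
##
## Growth is discrete Wright-Fisher: a 1:10 transfer regrows to carrying
## capacity in g = log2(K/N0) ~ 3.3 generations, so five transfers give the
## ~16-17 generations of the standard degeneration experiment. All draws use
## R's global RNG; simulateSeries() seeds it once and documents draw order.

stopExtinction <- function(msg) {
  stop(structure(class = c("degeneR_extinction", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

classIds <- function(classes) vapply(classes, function(cl) cl@id, character(1))

classesByState <- function(state, classes) {
  ids <- names(state@vegetative)
  have <- classIds(classes)
  if (!all(ids %in% have))
    stop("classes must cover every genotype id in the state: missing ",
         paste(setdiff(ids, have), collapse = ", "))
  setNames(classes[match(ids, have)], ids)
}

#' Grow a culture through one transfer
#'
#' Regrows the inoculated vegetative population to carrying capacity by
#' multinomial Wright-Fisher sampling over `g = log2(K / N0)` generations,
#' with per-class realized fitness
#' `w_i(x) = baselineFitness * (1 - freqDependence * x_i)` where `x_i` is
#' the class's current frequency. After growth, each class converts
#' `sporulationFraction` of its vegetative cells to spores (binomially);
#' for transfer intervals beyond 24 h, vegetative cells then survive each
#' extra hour with probability `post24hViability` (spores are unaffected).
#' Solvent and acid outputs are frequency-weighted sums of class yields at
#' the end of growth, before sporulation.
#'
#' @param state a [PopulationState-class] describing the inoculum.
#' @param classes list of [GenotypeClass-class] covering every id in `state`.
#' @param regime a [RegimeConfig-class].
#' @return A new [PopulationState-class] with `cultureAgeH` equal to the
#'   transfer interval, carrying an attribute `"births"` (cells produced
#'   during growth) used for mutation spawning.
#' @examples
#' set.seed(1)
#' st <- populationState(c(WT = 1e5))
#' growTransfer(st, list(genotypeClass("WT")),
#'              regimeConfig(carryingCapacity = 1e6))
#' @export
growTransfer <- function(state, classes, regime) {
  cls <- classesByState(state, classes)
  veg <- state@vegetative
  n0 <- sum(veg)
  if (n0 <= 0)
    stopExtinction("no vegetative cells to grow: population extinct")
  K <- regime@carryingCapacity
  if (K <= n0)
    stop("invalid regime: carrying capacity K must exceed inoculum size N0")

  bf <- vapply(cls, function(cl) cl@baselineFitness, numeric(1))
  fd <- vapply(cls, function(cl) cl@freqDependence, numeric(1))

  # Doubling steps capped at K; the final partial step lands exactly on K.
  n <- n0
  while (n < K) {
    size <- min(2 * n, K)
    x <- veg / sum(veg)
    w <- pmax(bf * (1 - fd * x), 1e-12)
    p <- x * w
    veg <- setNames(as.numeric(rmultinom(1, size, p)), names(veg))
    n <- size
  }
  births <- K - n0

  x <- veg / sum(veg)
  solvents <- sum(x * vapply(cls, function(cl) cl@solventYield, numeric(1)))
  acids <- sum(x * vapply(cls, function(cl) cl@acidYield, numeric(1)))

  sporFrac <- vapply(cls, function(cl) cl@sporulationFraction, numeric(1))
  newSpores <- rbinom(length(veg), size = as.integer(veg), prob = sporFrac)
  veg <- veg - newSpores
  spores <- state@spores + newSpores

  if (regime@transferIntervalH > 24) {
    extra <- regime@transferIntervalH - 24
    surv <- vapply(cls, function(cl) cl@post24hViability, numeric(1))^extra
    veg <- as.numeric(rbinom(length(veg), size = as.integer(veg),
                             prob = surv))
    names(veg) <- names(spores)
  }

  out <- populationState(vegetative = veg, spores = spores,
                         subcultureIndex = state@subcultureIndex,
                         solventsGL = solvents, acidsGL = acids,
                         cultureAgeH = regime@transferIntervalH)
  attr(out, "births") <- births
  out
}

#' Dilute a culture into fresh medium
#'
#' Each genotype's transferred vegetative and spore counts are drawn
#' binomially with success probability `dilutionFactor` (binomial thinning,
#' so expected composition is preserved). Phenotype accumulators are reset
#' and culture age returns to 0.
#'
#' @param state a [PopulationState-class].
#' @param regime a [RegimeConfig-class]; only `dilutionFactor` is used.
#' @return The transferred [PopulationState-class].
#' @examples
#' set.seed(1)
#' applyDilution(populationState(c(WT = 1e6)), regimeConfig())
#' @export
applyDilution <- function(state, regime) {
  d <- regime@dilutionFactor
  if (d <= 0 || d >= 1)
    stop("dilutionFactor must be strictly inside (0, 1)")
  veg <- setNames(as.numeric(
    rbinom(length(state@vegetative), as.integer(state@vegetative), d)),
    names(state@vegetative))
  spores <- setNames(as.numeric(
    rbinom(length(state@spores), as.integer(state@spores), d)),
    names(state@spores))
  populationState(vegetative = veg, spores = spores,
                  subcultureIndex = state@subcultureIndex,
                  solventsGL = 0, acidsGL = 0, cultureAgeH = 0)
}

#' Heat-shock a transfer aliquot
#'
#' Models the 80 degree C / 10 min bottleneck: all vegetative cells are
#' inactivated, and viable spores germinate (binomial thinning at
#' `germinationEfficiency`) to found the next vegetative population. Spore
#' counts are zeroed. Classes that cannot sporulate are thereby eliminated
#' in every realization.
#'
#' @param state a [PopulationState-class].
#' @param germinationEfficiency fraction of spores germinating, in `(0, 1]`.
#' @return The post-shock [PopulationState-class].
#' @examples
#' set.seed(1)
#' st <- populationState(c(WT = 1e8, FW = 1e7), spores = c(WT = 1e6, FW = 0))
#' applyHeatShock(st, 1.0)
#' @export
applyHeatShock <- function(state, germinationEfficiency = 0.8) {
  if (germinationEfficiency <= 0 || germinationEfficiency > 1)
    stop("germinationEfficiency must be in (0, 1]")
  if (sum(state@spores) <= 0)
    stopExtinction("heat shock with no viable spores: population extinct")
  veg <- setNames(as.numeric(
    rbinom(length(state@spores), as.integer(state@spores),
           germinationEfficiency)),
    names(state@spores))
  spores <- setNames(numeric(length(veg)), names(veg))
  populationState(vegetative = veg, spores = spores,
                  subcultureIndex = state@subcultureIndex,
                  solventsGL = state@solventsGL, acidsGL = state@acidsGL,
                  cultureAgeH = state@cultureAgeH)
}

#' Germinate transferred spores in fresh medium
#'
#' Spores carried into fresh medium germinate with probability
#' `germinationEfficiency` and rejoin the vegetative pool; the remainder
#' stay dormant. This is what lets sporulating classes persist across
#' transfers without a heat shock.
#'
#' @param state a [PopulationState-class].
#' @param germinationEfficiency fraction germinating, in `(0, 1]`.
#' @return The updated [PopulationState-class].
#' @export
germinateSpores <- function(state, germinationEfficiency = 0.8) {
  if (germinationEfficiency <= 0 || germinationEfficiency > 1)
    stop("germinationEfficiency must be in (0, 1]")
  germ <- as.numeric(rbinom(length(state@spores), as.integer(state@spores),
                            germinationEfficiency))
  populationState(vegetative = state@vegetative + germ,
                  spores = state@spores - germ,
                  subcultureIndex = state@subcultureIndex,
                  solventsGL = state@solventsGL, acidsGL = state@acidsGL,
                  cultureAgeH = state@cultureAgeH)
}

#' Default substitution spectrum for spawned mutations
#'
#' Named probability vector over the six strand-collapsed SNP classes plus
#' insertions and deletions, matching the observed catalogue composition:
#' 211/225 SNPs of which 87% are G:C>T:A transversions, 12/225 deletions
#' and 2/225 insertions.
#'
#' @return Named numeric vector summing to 1.
#' @export
defaultSpectrum <- function() {
  snp <- 211 / 225
  others <- snp * 0.13 / 5
  c("G:C>T:A" = snp * 0.87,
    "G:C>A:T" = others, "G:C>C:G" = others,
    "A:T>T:A" = others, "A:T>G:C" = others, "A:T>C:G" = others,
    deletion = 12 / 225, insertion = 2 / 225)
}

#' Default mutation target regions and weights
#'
#' Four synthetic hotspot regions on a 6 Mb chromosome (a sensor histidine
#' kinase, the spo0A master regulator, a hybrid kinase/response regulator,
#' and the abrB/hypothetical-protein region with its intergenic spacer)
#' plus a residual "other" region for neutral carrier mutations. Weights
#' concentrate ~65% of hits in the hotspots, with the spo0A region the
#' most frequently hit.
#'
#' @param genomeLength chromosome length in bp (default 6e6).
#' @return data.frame with columns `region, chrom, start, end, weight`.
#' @export
defaultTargetWeights <- function(genomeLength = 6e6) {
  data.frame(
    region = c("hotspot1_kinase", "hotspot2_spo0A", "hotspot3_hybrid",
               "hotspot4_abrB", "other"),
    chrom = "chr",
    start = c(20001L, 1950001L, 3540001L, 5718001L, 1L),
    end = c(23000L, 1953000L, 3543000L, 5722000L, as.integer(genomeLength)),
    weight = c(0.05, 0.35, 0.15, 0.10, 0.35),
    stringsAsFactors = FALSE
  )
}

#' Default region effect templates
#'
#' Parameter presets applied to a lineage hit in each target region: a
#' spo0A hit produces a Spo0A-null class (no sporulation, no solvents,
#' elevated frequency-dependent fitness, FW morphotype); hits in the other
#' hotspots reduce sporulation with milder fitness effects; non-hotspot
#' hits are neutral carrier mutations.
#'
#' @return Named list of parameter-override lists keyed by region.
#' @export
defaultRegionTemplates <- function() {
  list(
    hotspot1_kinase = list(sporulationFraction = 0.3, morphotype = "RD"),
    hotspot2_spo0A = list(baselineFitness = 1.9, freqDependence = 0.6,
                          sporulationFraction = 0, post24hViability = 0.953,
                          solventYield = 0, acidYield = 5.8,
                          morphotype = "FW"),
    hotspot3_hybrid = list(baselineFitness = 1.3, freqDependence = 0.3,
                           sporulationFraction = 0.2, solventYield = 6.5,
                           acidYield = 2.5, morphotype = "DCOG"),
    hotspot4_abrB = list(baselineFitness = 1.6, freqDependence = 0.35,
                         sporulationFraction = 0, post24hViability = 0.96,
                         solventYield = 2.0, acidYield = 4.0,
                         morphotype = "CIC"),
    other = list()
  )
}

#' Default genotype classes
#'
#' The wild type (RD morphotype: full sporulation and solvent production)
#' and, when `withNull = TRUE`, a pre-formed Spo0A-null class built from
#' the spo0A region template.
#'
#' @param withNull include a Spo0A-null class (default `FALSE`: the study
#'   regimes start from a homogeneous single-colony wild type and nulls
#'   arise by mutation).
#' @return List of [GenotypeClass-class].
#' @export
defaultClasses <- function(withNull = FALSE) {
  wt <- genotypeClass("WT")
  if (!withNull) return(list(wt))
  tmpl <- defaultRegionTemplates()$hotspot2_spo0A
  null <- genotypeClass("spo0A_null",
                        baselineFitness = tmpl$baselineFitness,
                        freqDependence = tmpl$freqDependence,
                        sporulationFraction = tmpl$sporulationFraction,
                        post24hViability = tmpl$post24hViability,
                        solventYield = tmpl$solventYield,
                        acidYield = tmpl$acidYield,
                        morphotype = tmpl$morphotype)
  list(wt, null)
}

applyTemplate <- function(parent, id, overrides, mutation) {
  cl <- parent
  slot(cl, "id", check = FALSE) <- id
  for (nm in names(overrides))
    slot(cl, nm, check = FALSE) <- overrides[[nm]]
  slot(cl, "mutations", check = FALSE) <- rbind(parent@mutations, mutation)
  validObject(cl)
  cl
}

drawMutationRecord <- function(region, spectrum) {
  kind <- sample(names(spectrum), 1L, prob = spectrum)
  pos <- as.integer(floor(runif(1, region$start, region$end + 1)))
  if (kind == "deletion") {
    ref <- paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                 collapse = "")
    alt <- substr(ref, 1L, 1L)
    k <- "deletion"
  } else if (kind == "insertion") {
    ref <- sample(c("A", "C", "G", "T"), 1L)
    alt <- paste0(ref, sample(c("A", "C", "G", "T"), 1L))
    k <- "insertion"
  } else {
    pair <- strsplit(sub(".*>", "", kind), ":")[[1]]     # e.g. T:A
    from <- strsplit(sub(">.*", "", kind), ":")[[1]]     # e.g. G:C
    strandPick <- sample(1:2, 1L)
    ref <- from[strandPick]
    alt <- pair[strandPick]
    k <- "SNP"
  }
  data.frame(chrom = region$chrom, pos = pos, ref = ref, alt = alt,
             kind = k, region = region$region, stringsAsFactors = FALSE)
}

#' Spawn new mutant lineages during a transfer
#'
#' The number of new mutant lineages is Poisson with mean
#' `mutationRate * births`. Each event picks a target region by weight and
#' a mutation type from the substitution spectrum, and founds a new
#' [GenotypeClass-class] (one cell, taken from a parent class sampled by
#' frequency) whose parameters are the parent's modified by the region's
#' effect template. Non-hotspot hits are neutral carrier lineages.
#'
#' @param state a [PopulationState-class] after growth.
#' @param regime a [RegimeConfig-class]; supplies `mutationRate`.
#' @param spectrum named probability vector as [defaultSpectrum()].
#' @param targetWeights data.frame as [defaultTargetWeights()].
#' @param templates named list as [defaultRegionTemplates()].
#' @param classes list of [GenotypeClass-class] covering the state.
#' @param births number of cell divisions this transfer (defaults to the
#'   `"births"` attribute set by [growTransfer()]).
#' @return List with elements `state` (founders moved into new classes),
#'   `classes` (input plus spawned classes) and `ledger` (data.frame of new
#'   mutation events, possibly empty).
#' @export
spawnMutations <- function(state, regime, spectrum = defaultSpectrum(),
                           targetWeights = defaultTargetWeights(),
                           templates = defaultRegionTemplates(),
                           classes, births = attr(state, "births")) {
  if (abs(sum(spectrum) - 1) > 1e-8)
    stop("spectrum probabilities must sum to 1")
  if (all(targetWeights$weight <= 0))
    stop("configuration error: all target weights are zero")
  if (is.null(births)) births <- sum(state@vegetative)
  emptyLedger <- data.frame(class_id = character(), parent_id = character(),
                            chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            kind = character(), region = character(),
                            stringsAsFactors = FALSE)
  nNew <- rpois(1L, regime@mutationRate * births)
  if (nNew == 0L)
    return(list(state = state, classes = classes, ledger = emptyLedger))

  cls <- classesByState(state, classes)
  veg <- state@vegetative
  ledger <- vector("list", nNew)
  newClasses <- list()
  existing <- length(classes)
  for (i in seq_len(nNew)) {
    if (sum(veg) <= 0) break
    parentId <- sample(names(veg), 1L, prob = veg)
    ri <- sample(nrow(targetWeights), 1L, prob = targetWeights$weight)
    region <- targetWeights[ri, ]
    rec <- drawMutationRecord(region, spectrum)
    newId <- sprintf("mut%03d_%s", existing + length(newClasses) + 1L,
                     region$region)
    overrides <- templates[[region$region]]
    if (is.null(overrides)) overrides <- list()
    newCl <- applyTemplate(cls[[parentId]], newId, overrides,
                           cbind(rec, row.names = NULL))
    newClasses[[newId]] <- newCl
    veg[parentId] <- veg[parentId] - 1
    veg[newId] <- 1
    cls[[newId]] <- newCl
    ledger[[i]] <- cbind(data.frame(class_id = newId, parent_id = parentId,
                                    stringsAsFactors = FALSE), rec)
  }
  ledger <- do.call(rbind, ledger[!vapply(ledger, is.null, logical(1))])
  if (is.null(ledger)) ledger <- emptyLedger
  spores <- state@spores
  spores[setdiff(names(veg), names(spores))] <- 0
  out <- populationState(vegetative = veg, spores = spores[names(veg)],
                         subcultureIndex = state@subcultureIndex,
                         solventsGL = state@solventsGL,
                         acidsGL = state@acidsGL,
                         cultureAgeH = state@cultureAgeH)
  list(state = out, classes = c(classes, unname(newClasses)),
       ledger = ledger)
}

morphotypeFractions <- function(state, classes) {
  cls <- classesByState(state, classes)
  morph <- vapply(cls, function(cl) cl@morphotype, character(1))
  veg <- state@vegetative
  tot <- sum(veg)
  fr <- vapply(MORPHOTYPES, function(m) {
    if (tot <= 0) 0 else sum(veg[morph == m]) / tot
  }, numeric(1))
  setNames(fr, paste0("frac_", MORPHOTYPES))
}

#' Simulate a full subculture series
#'
#' Composes the transfer cycle: (optional heat shock of the transfer
#' aliquot) -> dilution into fresh medium -> spore germination -> growth
#' with sporulation and post-24 h decay -> mutation spawning. Records, at
#' every subculture, per-class counts, phenotype outputs (solvents, acids,
#' heat-resistant spores, morphotype fractions) and the true allele
#' frequency of every spawned mutation (lineage vegetative count over total
#' vegetative count). Deterministic given `seed`.
#'
#' Draw order per cycle: heat-shock germination (if any), dilution
#' (vegetative then spores), fresh-medium germination, one multinomial per
#' Wright-Fisher step, sporulation, post-24 h survival, then the Poisson
#' mutation count and per-event draws.
#'
#' @param classes list of [GenotypeClass-class] present at subculture 0.
#' @param regime a [RegimeConfig-class].
#' @param spectrum,targetWeights,templates mutation model, see
#'   [spawnMutations()].
#' @param seed integer RNG seed.
#' @param initialFractions named numeric of starting vegetative fractions
#'   (defaults to all inoculum in the first class, the single-colony start).
#' @return A [SeriesResult-class].
#' @examples
#' res <- simulateSeries(defaultClasses(),
#'                       regimeConfig(nSubcultures = 3,
#'                                    carryingCapacity = 1e5,
#'                                    mutationRate = 0), seed = 42)
#' seriesPhenotypes(res)
#' @export
simulateSeries <- function(classes, regime, spectrum = defaultSpectrum(),
                           targetWeights = defaultTargetWeights(),
                           templates = defaultRegionTemplates(),
                           seed = 1L, initialFractions = NULL) {
  validObject(regime)
  set.seed(as.integer(seed))
  ids <- classIds(classes)
  n0 <- regime@carryingCapacity * regime@dilutionFactor
  if (is.null(initialFractions))
    initialFractions <- setNames(c(1, numeric(length(ids) - 1L)), ids)
  if (!all(names(initialFractions) %in% ids))
    stop("initialFractions names must match class ids")
  veg <- setNames(numeric(length(ids)), ids)
  veg[names(initialFractions)] <- round(n0 * initialFractions)
  state <- populationState(veg)

  # subculture 0 is itself a grown culture (single-colony inoculum grown to
  # capacity), so it already carries spores and phenotype readouts
  state <- growTransfer(state, classes, regime)
  sp0 <- spawnMutations(state, regime, spectrum, targetWeights, templates,
                        classes = classes)
  state <- sp0$state
  classes <- sp0$classes

  stateRows <- list()
  phenoRows <- list()
  ledgers <- list()

  record <- function(state, classes, sc) {
    cls <- classesByState(state, classes)
    morph <- vapply(cls, function(cl) cl@morphotype, character(1))
    stateRows[[length(stateRows) + 1L]] <<- data.frame(
      subculture = sc, genotype = names(state@vegetative),
      morphotype = unname(morph),
      vegetative = unname(state@vegetative),
      spores = unname(state@spores), stringsAsFactors = FALSE)
    phenoRows[[length(phenoRows) + 1L]] <<- data.frame(
      subculture = sc, solvents_gl = state@solventsGL,
      acids_gl = state@acidsGL, spores_cfu = sum(state@spores),
      t(morphotypeFractions(state, classes)), stringsAsFactors = FALSE)
  }

  # registry of every class ever spawned, for the truth table
  mutationsOf <- list()
  registerClasses <- function(classes) {
    for (cl in classes)
      if (nrow(cl@mutations) && is.null(mutationsOf[[cl@id]]))
        mutationsOf[[cl@id]] <<- cl@mutations
  }

  registerClasses(classes)
  record(state, classes, 0L)
  ledgers <- if (nrow(sp0$ledger))
    list(cbind(data.frame(subculture = 0L), sp0$ledger)) else list()

  for (sc in seq_len(regime@nSubcultures)) {
    if (regime@heatShock)
      state <- applyHeatShock(state, regime@germinationEfficiency)
    state <- applyDilution(state, regime)
    if (!regime@heatShock)
      state <- germinateSpores(state, regime@germinationEfficiency)
    if (sum(state@vegetative) <= 0)
      stopExtinction(sprintf("population extinct at subculture %d", sc))
    state <- growTransfer(state, classes, regime)
    sp <- spawnMutations(state, regime, spectrum, targetWeights, templates,
                         classes = classes)
    state <- sp$state
    classes <- sp$classes
    if (nrow(sp$ledger))
      ledgers[[length(ledgers) + 1L]] <-
        cbind(data.frame(subculture = sc), sp$ledger)
    # prune extinct mutant classes (keep founders listed at subculture 0)
    alive <- state@vegetative > 0 | state@spores > 0 |
      names(state@vegetative) %in% ids
    state <- populationState(state@vegetative[alive],
                             state@spores[alive],
                             subcultureIndex = as.integer(sc),
                             solventsGL = state@solventsGL,
                             acidsGL = state@acidsGL,
                             cultureAgeH = state@cultureAgeH)
    classes <- classes[classIds(classes) %in% names(state@vegetative)]
    state@subcultureIndex <- as.integer(sc)
    registerClasses(classes)
    record(state, classes, sc)
  }

  ledger <- if (length(ledgers)) do.call(rbind, ledgers) else
    data.frame(subculture = integer(), class_id = character(),
               parent_id = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               kind = character(), region = character(),
               stringsAsFactors = FALSE)
  rownames(ledger) <- NULL
  states <- do.call(rbind, stateRows)
  # truth table: per-mutation lineage frequency at each recorded subculture
  trueAF <- local({
    empty <- data.frame(class_id = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character(), subculture = integer(),
                        af = numeric(), stringsAsFactors = FALSE)
    if (!length(mutationsOf)) return(empty)
    totals <- tapply(states$vegetative, states$subculture, sum)
    mut <- states[states$genotype %in% names(mutationsOf), ]
    if (!nrow(mut)) return(empty)
    af <- mut$vegetative / pmax(as.numeric(totals[as.character(mut$subculture)]), 1)
    nm <- vapply(mutationsOf[mut$genotype], nrow, integer(1))
    muts <- do.call(rbind, mutationsOf[mut$genotype])
    idx <- rep(seq_len(nrow(mut)), nm)
    out <- data.frame(class_id = mut$genotype[idx],
                      chrom = muts$chrom, pos = muts$pos, ref = muts$ref,
                      alt = muts$alt, subculture = mut$subculture[idx],
                      af = af[idx], stringsAsFactors = FALSE)
    out[order(out$class_id, out$subculture), ]
  })
  rownames(trueAF) <- NULL
  phen <- do.call(rbind, phenoRows)
  rownames(states) <- rownames(phen) <- NULL
  new("SeriesResult", states = states, phenotypes = phen,
      mutationLedger = ledger, trueAF = trueAF, classes = classes,
      regime = regime, seed = as.integer(seed))
}

#' Simulate one pairwise competition assay
#'
#' Mixes a mutant and a reference class at initial mutant proportion `x1`,
#' grows the co-culture for `generations` Wright-Fisher generations with
#' frequency-dependent realized fitness (no sporulation: the assay counts
#' colony-forming units of each morphotype), and reports the final mutant
#' proportion `x2` and the relative fitness `w = [x2(1-x1)]/[x1(1-x2)]`.
#'
#' @param mutant,reference [GenotypeClass-class] competitors.
#' @param x1 initial mutant proportion, in `(0, 1)`.
#' @param inoculumSize total cells at mixing (default 1e7).
#' @param generations growth generations (default `log2(10)`, one 1:10
#'   regrowth cycle; halve for a 12 h readout).
#' @return List with `x1` (realized), `x2` and `w`.
#' @examples
#' set.seed(1)
#' fw <- defaultClasses(withNull = TRUE)[[2]]
#' simulateCompetition(fw, genotypeClass("WT"), x1 = 0.1)
#' @export
simulateCompetition <- function(mutant, reference, x1,
                                inoculumSize = 1e7,
                                generations = log2(10)) {
  if (x1 <= 0 || x1 >= 1) stop("x1 must be strictly inside (0, 1)")
  veg <- c(mut = round(inoculumSize * x1),
           ref = round(inoculumSize * (1 - x1)))
  if (any(veg == 0)) stop("inoculumSize too small for this x1")
  x1real <- veg[["mut"]] / sum(veg)
  bf <- c(mutant@baselineFitness, reference@baselineFitness)
  fd <- c(mutant@freqDependence, reference@freqDependence)
  n <- sum(veg)
  steps <- ceiling(generations)
  target <- n * 2^generations
  for (s in seq_len(steps)) {
    size <- min(2 * n, target)
    x <- veg / sum(veg)
    w <- pmax(bf * (1 - fd * x), 1e-12)
    veg <- setNames(as.numeric(rmultinom(1, round(size), x * w)),
                    names(veg))
    n <- size
  }
  x2 <- veg[["mut"]] / sum(veg)
  w <- relativeFitness(x1real, x2)
  list(x1 = x1real, x2 = x2, w = as.numeric(w))
}
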