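#' @import methods
#' @importFrom stats rbinom rmultinom rpois rnbinom rnorm runif cor.test
#'   pbinom p.adjust fisher.test setNames median approx isoreg ppois
#' @importFrom utils read.delim write.table modifyList packageVersion
NULL

MORPHOTYPES <- c("RD", "DCOG", "CIC", "FW")

SITE_FILTER_LABELS <- c("low_qual", "no_consensus", "low_orientation_af",
                        "low_reads")
TRAJECTORY_FILTER_LABELS <- c("rrna", "starter_background",
                              "insufficient_recurrence", "depth_artifact")
FILTER_LABELS <- c(SITE_FILTER_LABELS, TRAJECTORY_FILTER_LABELS)

#' GenotypeClass: one population subtype and its defining parameters
#'
#' A `GenotypeClass` describes one genotype class in a degenerating
#' *Clostridium* culture: the wild type, a partial-Spo0A mutant, a
#' Spo0A-null mutant, or a neutral carrier lineage. Fitness is expressed as
#' a per-generation growth factor relative to the wild type (WT = 1);
#' `freqDependence` is the linear coefficient by which a class's realized
#' fitness declines as its own frequency rises (negative frequency-dependent
#' selection when > 0): `w_i(x) = baselineFitness * (1 - freqDependence * x_i)`.
#'
#' @slot id character label, unique within a simulation.
#' @slot baselineFitness relative per-generation growth factor (> 0, WT = 1).
#' @slot freqDependence linear own-frequency fitness-decline coefficient.
#' @slot sporulationFraction fraction of vegetative cells converting to
#'   spores at the end of a transfer, in `[0, 1]`.
#' @slot post24hViability per-hour survival factor applied for each hour of
#'   culture age beyond 24 h, in `(0, 1]`.
#' @slot solventYield g/L solvents produced per transfer by a pure culture.
#' @slot acidYield g/L organic acids produced per transfer by a pure culture.
#' @slot morphotype colony morphotype, one of `"RD"`, `"DCOG"`, `"CIC"`, `"FW"`.
#' @slot mutations data.frame of defining mutations with columns
#'   `chrom, pos, ref, alt, kind, region`.
#'
#' @seealso [genotypeClass()], [defaultClasses()]
#' @export
setClass("GenotypeClass",
  representation(
    id = "character",
    baselineFitness = "numeric",
    freqDependence = "numeric",
    sporulationFraction = "numeric",
    post24hViability = "numeric",
    solventYield = "numeric",
    acidYield = "numeric",
    morphotype = "character",
    mutations = "data.frame"
  ),
  prototype(
    baselineFitness = 1, freqDependence = 0, sporulationFraction = 0.9,
    post24hViability = 0.995, solventYield = 7.2, acidYield = 1.95,
    morphotype = "RD",
    mutations = data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           kind = character(), region = character())
  )
)

setValidity("GenotypeClass", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "id must be a single non-empty string")
  if (object@baselineFitness <= 0)
    msgs <- c(msgs, "baselineFitness must be > 0")
  if (object@sporulationFraction < 0 || object@sporulationFraction > 1)
    msgs <- c(msgs, "sporulationFraction must be in [0, 1]")
  if (object@post24hViability <= 0 || object@post24hViability > 1)
    msgs <- c(msgs, "post24hViability must be in (0, 1]")
  if (!object@morphotype %in% MORPHOTYPES)
    msgs <- c(msgs, sprintf("morphotype must be one of %s",
                            paste(MORPHOTYPES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeClass
#'
#' @param id class label.
#' @param baselineFitness,freqDependence,sporulationFraction,post24hViability,solventYield,acidYield,morphotype,mutations
#'   see [GenotypeClass-class].
#' @return A [GenotypeClass-class] object.
#' @examples
#' wt <- genotypeClass("WT")
#' fw <- genotypeClass("FW7", baselineFitness = 1.9, freqDependence = 0.6,
#'                     sporulationFraction = 0, solventYield = 0,
#'                     morphotype = "FW")
#' @export
genotypeClass <- function(id, baselineFitness = 1, freqDependence = 0,
                          sporulationFraction = 0.9, post24hViability = 0.995,
                          solventYield = 7.2, acidYield = 1.95,
                          morphotype = "RD",
                          mutations = NULL) {
  if (is.null(mutations))
    mutations <- data.frame(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            kind = character(), region = character())
  new("GenotypeClass", id = id, baselineFitness = baselineFitness,
      freqDependence = freqDependence,
      sporulationFraction = sporulationFraction,
      post24hViability = post24hViability, solventYield = solventYield,
      acidYield = acidYield, morphotype = morphotype, mutations = mutations)
}

#' RegimeConfig: one serial-transfer regime
#'
#' Parameters of a subculturing regime: dilution into fresh medium,
#' transfer interval, optional heat-shock bottleneck before each transfer,
#' carrying capacity and per-cell per-generation mutation rate.
#'
#' @slot dilutionFactor fraction of the culture transferred (default 1/10).
#' @slot transferIntervalH hours between transfers (24 or 72 in the study
#'   designs; any value > 0 accepted).
#' @slot heatShock if `TRUE`, an 80 degree C heat shock is applied to the
#'   transfer aliquot, killing vegetative cells and germinating spores.
#' @slot nSubcultures number of serial transfers to simulate.
#' @slot carryingCapacity K, cells per ml at the end of growth.
#' @slot mutationRate per-cell per-generation probability of a tracked,
#'   phenotype-relevant mutation (default 1e-6; this is the rate of
#'   degeneration-linked and carrier lineage-founding events, not the
#'   genomic per-base rate).
#' @slot germinationEfficiency fraction of spores that germinate when
#'   returned to fresh medium (used by both heat shock and fresh-medium
#'   germination), in `(0, 1]`.
#' @seealso [regimeConfig()]
#' @export
setClass("RegimeConfig",
  representation(
    dilutionFactor = "numeric",
    transferIntervalH = "numeric",
    heatShock = "logical",
    nSubcultures = "integer",
    carryingCapacity = "numeric",
    mutationRate = "numeric",
    germinationEfficiency = "numeric"
  ),
  prototype(dilutionFactor = 0.1, transferIntervalH = 24, heatShock = FALSE,
            nSubcultures = 15L, carryingCapacity = 1e8, mutationRate = 1e-6,
            germinationEfficiency = 0.8)
)

setValidity("RegimeConfig", function(object) {
  msgs <- character()
  if (object@dilutionFactor <= 0 || object@dilutionFactor >= 1)
    msgs <- c(msgs, "dilutionFactor must be in (0, 1)")
  if (object@transferIntervalH <= 0)
    msgs <- c(msgs, "transferIntervalH must be > 0")
  if (object@nSubcultures < 1L)
    msgs <- c(msgs, "nSubcultures must be >= 1")
  if (object@carryingCapacity <= 0)
    msgs <- c(msgs, "carryingCapacity must be > 0")
  if (object@mutationRate < 0)
    msgs <- c(msgs, "mutationRate must be >= 0")
  if (object@germinationEfficiency <= 0 || object@germinationEfficiency > 1)
    msgs <- c(msgs, "germinationEfficiency must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegimeConfig
#'
#' Defaults describe the standard degeneration-promoting regime: 1:10
#' dilution every 24 h, no heat shock, K = 1e8 CFU/ml.
#'
#' @param dilutionFactor,transferIntervalH,heatShock,nSubcultures,carryingCapacity,mutationRate,germinationEfficiency
#'   see [RegimeConfig-class].
#' @return A [RegimeConfig-class] object.
#' @examples
#' regimeConfig()                       # 24 h serial transfer
#' regimeConfig(heatShock = TRUE)       # heat-shock bottleneck regime
#' regimeConfig(transferIntervalH = 72) # extended-transfer regime
#' @export
regimeConfig <- function(dilutionFactor = 0.1, transferIntervalH = 24,
                         heatShock = FALSE, nSubcultures = 15L,
                         carryingCapacity = 1e8, mutationRate = 1e-6,
                         germinationEfficiency = 0.8) {
  new("RegimeConfig", dilutionFactor = dilutionFactor,
      transferIntervalH = transferIntervalH, heatShock = heatShock,
      nSubcultures = as.integer(nSubcultures),
      carryingCapacity = carryingCapacity, mutationRate = mutationRate,
      germinationEfficiency = germinationEfficiency)
}

#' PopulationState: per-genotype counts at one subculture
#'
#' Vegetative and spore counts (CFU/ml) per genotype class at one point of
#' a subculture series, together with the phenotype readouts emitted over
#' the preceding transfer.
#'
#' @slot subcultureIndex integer >= 0.
#' @slot vegetative named numeric vector, genotype id -> vegetative count.
#' @slot spores named numeric vector, genotype id -> spore count.
#' @slot solventsGL solvents produced over the transfer (g/L).
#' @slot acidsGL acids produced over the transfer (g/L).
#' @slot cultureAgeH hours since inoculation.
#' @seealso [populationState()]
#' @export
setClass("PopulationState",
  representation(
    subcultureIndex = "integer",
    vegetative = "numeric",
    spores = "numeric",
    solventsGL = "numeric",
    acidsGL = "numeric",
    cultureAgeH = "numeric"
  ),
  prototype(subcultureIndex = 0L, solventsGL = 0, acidsGL = 0,
            cultureAgeH = 0)
)

setValidity("PopulationState", function(object) {
  msgs <- character()
  if (object@subcultureIndex < 0L)
    msgs <- c(msgs, "subcultureIndex must be >= 0")
  if (is.null(names(object@vegetative)) || is.null(names(object@spores)))
    msgs <- c(msgs, "vegetative and spores must be named by genotype id")
  if (!identical(sort(names(object@vegetative)), sort(names(object@spores))))
    msgs <- c(msgs, "vegetative and spores must cover the same genotype ids")
  if (any(object@vegetative < 0) || any(object@spores < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (any(object@vegetative != round(object@vegetative)) ||
      any(object@spores != round(object@spores)))
    msgs <- c(msgs, "counts must be integer-valued")
  if (object@solventsGL < 0 || object@acidsGL < 0)
    msgs <- c(msgs, "phenotype concentrations must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PopulationState
#'
#' @param vegetative,spores named counts per genotype id; `spores` defaults
#'   to zeros over the same ids.
#' @param subcultureIndex,solventsGL,acidsGL,cultureAgeH see
#'   [PopulationState-class].
#' @return A [PopulationState-class] object.
#' @examples
#' populationState(c(WT = 1e8))
#' @export
populationState <- function(vegetative, spores = NULL, subcultureIndex = 0L,
                            solventsGL = 0, acidsGL = 0, cultureAgeH = 0) {
  if (is.null(spores))
    spores <- setNames(numeric(length(vegetative)), names(vegetative))
  new("PopulationState", subcultureIndex = as.integer(subcultureIndex),
      vegetative = vegetative, spores = spores[names(vegetative)],
      solventsGL = solventsGL, acidsGL = acidsGL, cultureAgeH = cultureAgeH)
}

#' SeqParams: pooled ultra-deep sequencing model parameters
#'
#' Parameters of the synthetic pileup generator. Depth at a site is drawn
#' from a negative binomial with mean `meanDepth` and size `depthDispersion`
#' (the default size of 27 gives a coefficient of variation of about 0.2 at
#' the default 368x depth, mimicking real coverage overdispersion). Reads
#' are split between the first-forward and first-reverse orientation strata
#' binomially at `orientationBalance`.
#'
#' @slot meanDepth expected total depth (default 368, the study's median).
#' @slot depthDispersion negative-binomial size parameter.
#' @slot errorRate per-base miscall probability epsilon, in `[0, 0.05]`;
#'   a miscall lands on any specific alternative base with probability
#'   epsilon/3.
#' @slot orientationBalance expected forward-stratum fraction, in `(0, 1)`.
#' @slot bqMean mean Phred base quality emitted.
#' @slot bqFloor minimum emitted mean base quality.
#' @seealso [seqParams()], [simulatePileup()]
#' @export
setClass("SeqParams",
  representation(
    meanDepth = "numeric",
    depthDispersion = "numeric",
    errorRate = "numeric",
    orientationBalance = "numeric",
    bqMean = "numeric",
    bqFloor = "numeric"
  ),
  prototype(meanDepth = 368, depthDispersion = 27, errorRate = 0.001,
            orientationBalance = 0.5, bqMean = 33, bqFloor = 20)
)

setValidity("SeqParams", function(object) {
  msgs <- character()
  if (object@meanDepth <= 0) msgs <- c(msgs, "meanDepth must be > 0")
  if (object@depthDispersion <= 0)
    msgs <- c(msgs, "depthDispersion must be > 0")
  if (object@errorRate < 0 || object@errorRate > 0.05)
    msgs <- c(msgs, "errorRate must be in [0, 0.05]")
  if (object@orientationBalance <= 0 || object@orientationBalance >= 1)
    msgs <- c(msgs, "orientationBalance must be in (0, 1)")
  if (object@bqFloor < 0 || object@bqMean < object@bqFloor)
    msgs <- c(msgs, "bqMean must be >= bqFloor >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SeqParams
#'
#' @param meanDepth,depthDispersion,errorRate,orientationBalance,bqMean,bqFloor
#'   see [SeqParams-class].
#' @return A [SeqParams-class] object.
#' @examples
#' seqParams()                 # study defaults: 368x, epsilon = 0.001
#' seqParams(errorRate = 0)    # error-free sequencing
#' @export
seqParams <- function(meanDepth = 368, depthDispersion = 27,
                      errorRate = 0.001, orientationBalance = 0.5,
                      bqMean = 33, bqFloor = 20) {
  new("SeqParams", meanDepth = meanDepth, depthDispersion = depthDispersion,
      errorRate = errorRate, orientationBalance = orientationBalance,
      bqMean = bqMean, bqFloor = bqFloor)
}

#' FilterParams: thresholds of the variant-filtering cascade
#'
#' Defaults are the study's published thresholds: dual-criterion consensus
#' (Phred site score >= 100 plus a strand-exactness/minimum-AF criterion),
#' allele frequency strictly above 0.04 in both read orientations with at
#' least 4 reads per orientation and mean base quality >= 20, trajectory
#' recurrence in at least 3 subcultures with AF strictly above 0.08, a
#' starter-culture (subculture 0) background cap of AF 0.5, and a
#' depth-correlation artifact screen (|Spearman rho| >= 0.8 across at least
#' 6 subcultures).
#'
#' @slot qualMin minimum Phred site score (criterion A), default 100.
#' @slot qualMax cap applied to the Phred site score, default 1000.
#' @slot afOrientationMin per-orientation AF threshold (strict >), 0.04.
#' @slot minReads minimum read count, default 4.
#' @slot minReadsMode `"per_orientation"` (each stratum depth >= minReads,
#'   the conservative reading) or `"total"`.
#' @slot minBq minimum mean base quality, default 20.
#' @slot consensusAfMin minimum combined AF for criterion B, default 0.005.
#' @slot strandBiasP Fisher-exact strand-bias p-value below which criterion
#'   B fails, default 0.001.
#' @slot recurrenceAf trajectory AF threshold (strict >), default 0.08.
#' @slot recurrenceCount subcultures required above `recurrenceAf`, 3.
#' @slot consecutiveRecurrence if `TRUE` the recurrent subcultures must be
#'   consecutive; default `FALSE`.
#' @slot starterAfMax maximum AF allowed at subculture 0, default 0.5.
#' @slot depthCorrThreshold |Spearman rho| at or above which a trajectory is
#'   labelled a depth artifact, default 0.8.
#' @slot depthCorrMinPoints minimum subcultures for the depth screen, 6.
#' @slot depthScreen whether the depth-artifact screen is applied, `TRUE`.
#' @seealso [filterParams()], [runFilterCascade()]
#' @export
setClass("FilterParams",
  representation(
    qualMin = "numeric", qualMax = "numeric",
    afOrientationMin = "numeric", minReads = "numeric",
    minReadsMode = "character", minBq = "numeric",
    consensusAfMin = "numeric", strandBiasP = "numeric",
    recurrenceAf = "numeric", recurrenceCount = "integer",
    consecutiveRecurrence = "logical", starterAfMax = "numeric",
    depthCorrThreshold = "numeric", depthCorrMinPoints = "integer",
    depthScreen = "logical"
  ),
  prototype(qualMin = 100, qualMax = 1000, afOrientationMin = 0.04,
            minReads = 4, minReadsMode = "per_orientation", minBq = 20,
            consensusAfMin = 0.005, strandBiasP = 0.001,
            recurrenceAf = 0.08, recurrenceCount = 3L,
            consecutiveRecurrence = FALSE, starterAfMax = 0.5,
            depthCorrThreshold = 0.8, depthCorrMinPoints = 6L,
            depthScreen = TRUE)
)

setValidity("FilterParams", function(object) {
  msgs <- character()
  if (object@qualMin < 0) msgs <- c(msgs, "qualMin must be >= 0")
  if (object@afOrientationMin < 0 || object@afOrientationMin > 1)
    msgs <- c(msgs, "afOrientationMin must be in [0, 1]")
  if (!object@minReadsMode %in% c("per_orientation", "total"))
    msgs <- c(msgs, "minReadsMode must be 'per_orientation' or 'total'")
  if (object@recurrenceCount < 1L)
    msgs <- c(msgs, "recurrenceCount must be >= 1")
  if (object@starterAfMax < 0 || object@starterAfMax > 1)
    msgs <- c(msgs, "starterAfMax must be in [0, 1]")
  if (object@depthCorrThreshold <= 0 || object@depthCorrThreshold > 1)
    msgs <- c(msgs, "depthCorrThreshold must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FilterParams
#'
#' @param qualMin,qualMax,afOrientationMin,minReads,minReadsMode,minBq,consensusAfMin,strandBiasP,recurrenceAf,recurrenceCount,consecutiveRecurrence,starterAfMax,depthCorrThreshold,depthCorrMinPoints,depthScreen
#'   see [FilterParams-class].
#' @return A [FilterParams-class] object.
#' @examples
#' filterParams()                       # study defaults
#' filterParams(minReadsMode = "total") # alternative min-reads reading
#' @export
filterParams <- function(qualMin = 100, qualMax = 1000,
                         afOrientationMin = 0.04, minReads = 4,
                         minReadsMode = "per_orientation", minBq = 20,
                         consensusAfMin = 0.005, strandBiasP = 0.001,
                         recurrenceAf = 0.08, recurrenceCount = 3L,
                         consecutiveRecurrence = FALSE, starterAfMax = 0.5,
                         depthCorrThreshold = 0.8, depthCorrMinPoints = 6L,
                         depthScreen = TRUE) {
  new("FilterParams", qualMin = qualMin, qualMax = qualMax,
      afOrientationMin = afOrientationMin, minReads = minReads,
      minReadsMode = minReadsMode, minBq = minBq,
      consensusAfMin = consensusAfMin, strandBiasP = strandBiasP,
      recurrenceAf = recurrenceAf,
      recurrenceCount = as.integer(recurrenceCount),
      consecutiveRecurrence = consecutiveRecurrence,
      starterAfMax = starterAfMax,
      depthCorrThreshold = depthCorrThreshold,
      depthCorrMinPoints = as.integer(depthCorrMinPoints),
      depthScreen = depthScreen)
}

#' SeriesResult: one simulated subculture series
#'
#' The full record of one simulated serial-passage series: per-subculture
#' population states, the mutation ledger (one row per lineage-founding
#' mutation event), the true allele-frequency table of every mutation at
#' every subculture, and the phenotype trajectory.
#'
#' @slot states data.frame, one row per (subculture, genotype) with columns
#'   `subculture, genotype, morphotype, vegetative, spores`.
#' @slot phenotypes data.frame, one row per subculture with columns
#'   `subculture, solvents_gl, acids_gl, spores_cfu` plus one
#'   `frac_<morphotype>` column per morphotype.
#' @slot mutationLedger data.frame, one row per mutation event with columns
#'   `class_id, parent_id, subculture, chrom, pos, ref, alt, kind, region`.
#' @slot trueAF data.frame with columns `class_id, chrom, pos, ref, alt,
#'   subculture, af` (lineage vegetative count over total vegetative count).
#' @slot classes list of [GenotypeClass-class] present at any point.
#' @slot regime the [RegimeConfig-class] used.
#' @slot seed integer seed the series was generated from.
#' @seealso [simulateSeries()]
#' @export
setClass("SeriesResult",
  representation(
    states = "data.frame",
    phenotypes = "data.frame",
    mutationLedger = "data.frame",
    trueAF = "data.frame",
    classes = "list",
    regime = "RegimeConfig",
    seed = "integer"
  )
)

setValidity("SeriesResult", function(object) {
  msgs <- character()
  need <- c("subculture", "genotype", "morphotype", "vegetative", "spores")
  if (!all(need %in% names(object@states)))
    msgs <- c(msgs, "states must have subculture/genotype/morphotype/vegetative/spores columns")
  if (nrow(object@trueAF) &&
      (any(object@trueAF$af < 0) || any(object@trueAF$af > 1)))
    msgs <- c(msgs, "true allele frequencies must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "GenotypeClass", function(object) {
  cat(sprintf(
    "GenotypeClass '%s' (%s): fitness %.3g, freq.dep %.3g, spor %.2f, solvents %.2f g/L\n",
    object@id, object@morphotype, object@baselineFitness,
    object@freqDependence, object@sporulationFraction, object@solventYield))
  if (nrow(object@mutations))
    cat(sprintf("  %d defining mutation(s)\n", nrow(object@mutations)))
})

setMethod("show", "RegimeConfig", function(object) {
  cat(sprintf(
    "RegimeConfig: 1:%d dilution every %g h%s, %d subcultures, K = %.3g, mu = %.3g\n",
    round(1 / object@dilutionFactor), object@transferIntervalH,
    if (object@heatShock) " with heat shock" else "",
    object@nSubcultures, object@carryingCapacity, object@mutationRate))
})

setMethod("show", "PopulationState", function(object) {
  cat(sprintf("PopulationState, subculture %d (%g h): %d classes, %.3g vegetative, %.3g spores\n",
              object@subcultureIndex, object@cultureAgeH,
              length(object@vegetative), sum(object@vegetative),
              sum(object@spores)))
})

setMethod("show", "SeqParams", function(object) {
  cat(sprintf("SeqParams: mean depth %g (NB size %g), error %.4g, fwd balance %.2f\n",
              object@meanDepth, object@depthDispersion, object@errorRate,
              object@orientationBalance))
})

setMethod("show", "FilterParams", function(object) {
  cat(sprintf(
    "FilterParams: qual >= %g; AF > %.2g both orientations; >= %g reads (%s); bq >= %g\n",
    object@qualMin, object@afOrientationMin, object@minReads,
    object@minReadsMode, object@minBq))
  cat(sprintf(
    "  trajectory: >= %d subcultures AF > %.2g%s; starter AF <= %.2g; depth screen %s (|rho| >= %.2g)\n",
    object@recurrenceCount, object@recurrenceAf,
    if (object@consecutiveRecurrence) " (consecutive)" else "",
    object@starterAfMax, if (object@depthScreen) "on" else "off",
    object@depthCorrThreshold))
})

setMethod("show", "SeriesResult", function(object) {
  cat(sprintf(
    "SeriesResult: %d subcultures, %d genotype classes, %d mutation events (seed %d)\n",
    max(object@states$subculture), length(object@classes),
    nrow(object@mutationLedger), object@seed))
})

## ---- accessors --------------------------------------------------------

#' Accessors for simulation result components
#'
#' @param x a [SeriesResult-class] (or, for `vegetativeCounts`/`sporeCounts`,
#'   a [PopulationState-class]).
#' @return `seriesStates`, `seriesPhenotypes`, `mutationLedger` and
#'   `trueAlleleFrequencies` return the corresponding data.frame;
#'   `vegetativeCounts` and `sporeCounts` return named numeric vectors.
#' @name series-accessors
#' @examples
#' res <- simulateSeries(defaultClasses(), regimeConfig(nSubcultures = 2,
#'                       carryingCapacity = 1e5), seed = 1)
#' head(seriesPhenotypes(res))
NULL

#' @rdname series-accessors
#' @export
seriesStates <- function(x) x@states

#' @rdname series-accessors
#' @export
seriesPhenotypes <- function(x) x@phenotypes

#' @rdname series-accessors
#' @export
mutationLedger <- function(x) x@mutationLedger

#' @rdname series-accessors
#' @export
trueAlleleFrequencies <- function(x) x@trueAF

#' @rdname series-accessors
#' @export
vegetativeCounts <- function(x) x@vegetative

#' @rdname series-accessors
#' @export
sporeCounts <- function(x) x@spores
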