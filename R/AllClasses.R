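#' SpeedModifierConfig: distance-dependent fork-speed modifier settings
#'
#' Configuration of the empirical fork-speed modifier. An emerging fork's
#' speed is scaled by a factor that grows linearly with the distance D to the
#' nearest approaching fork (or, when none approaches, to the chromosome
#' end), saturating at \code{rampScale} kb; the resulting speed never exceeds
#' \code{capFactor} times the population mean speed. By default the modifier
#' is a pure on-top acceleration: base speeds keep their configured
#' distribution and only gap-facing forks are boosted. With
#' \code{calibrateMean = TRUE} the base-speed distribution is instead
#' rescaled via a pilot run so the realized mean effective speed equals the
#' configured mean.
#'
#' @slot capFactor numeric(1), maximal speed as a multiple of the mean fork
#'   speed (default 1.9).
#' @slot rampScale numeric(1), kb; distance at which the modifier saturates.
#' @slot calibrateMean logical(1); rescale base speeds so the population mean
#'   effective speed equals the configured mean.
#' @slot reevalPerStep logical(1); re-evaluate the modifier at every time
#'   step instead of only at fork birth.
#' @exportClass SpeedModifierConfig
setClass("SpeedModifierConfig",
  representation(capFactor = "numeric", rampScale = "numeric",
                 calibrateMean = "logical", reevalPerStep = "logical"),
  prototype(capFactor = 1.9, rampScale = 100, calibrateMean = FALSE,
            reevalPerStep = FALSE))

setValidity("SpeedModifierConfig", function(object) {
  msg <- character()
  if (length(object@capFactor) != 1 || object@capFactor < 1)
    msg <- c(msg, "capFactor must be a single value >= 1")
  if (length(object@rampScale) != 1 || object@rampScale <= 0)
    msg <- c(msg, "rampScale must be a single positive value (kb)")
  if (length(msg)) msg else TRUE
})

#' Create a speed-modifier configuration
#'
#' @param capFactor maximal speed as a multiple of the mean fork speed.
#' @param rampScale kb; distance to an approaching fork at which the speed
#'   factor saturates at \code{capFactor}.
#' @param calibrateMean rescale base speeds (pilot-run calibration) so the
#'   realized mean effective speed equals the configured mean speed; off by
#'   default (the modifier is then a pure capped acceleration).
#' @param reevalPerStep re-evaluate the modifier every time step rather than
#'   once at fork birth.
#' @return A \linkS4class{SpeedModifierConfig} object.
#' @examples
#' speedModifierConfig(capFactor = 1.9, rampScale = 100)
#' @export
speedModifierConfig <- function(capFactor = 1.9, rampScale = 100,
                                calibrateMean = FALSE, reevalPerStep = FALSE) {
  new("SpeedModifierConfig", capFactor = capFactor, rampScale = rampScale,
      calibrateMean = calibrateMean, reevalPerStep = reevalPerStep)
}

setClassUnion("SpeedModifierConfigOrNULL", c("SpeedModifierConfig", "NULL"))

#' ReplicationParams: global replication kinetics parameters
#'
#' The global (genome-wide) parameters of the replication model: mean fork
#' speed and its variance, firing-time variance, observation time, an
#' optional per-minute fork termination probability, and an optional
#' distance-dependent speed modifier.
#'
#' @slot muV numeric(1), mean fork speed (kb/min), > 0.
#' @slot varV numeric(1), fork-speed variance ((kb/min)^2), >= 0.
#' @slot varT numeric(1), firing-time variance (min^2), >= 0.
#' @slot tExp numeric(1), observation time (min from S-phase start), > 0.
#' @slot pEnd numeric(1) in [0,1], per-minute per-fork termination
#'   probability (default 0).
#' @slot modifier a \linkS4class{SpeedModifierConfig} or NULL.
#' @exportClass ReplicationParams
setClass("ReplicationParams",
  representation(muV = "numeric", varV = "numeric", varT = "numeric",
                 tExp = "numeric", pEnd = "numeric",
                 modifier = "SpeedModifierConfigOrNULL"),
  prototype(muV = 1.5, varV = 0.9, varT = 9.7, tExp = 42, pEnd = 0,
            modifier = NULL))

setValidity("ReplicationParams", function(object) {
  msg <- character()
  if (length(object@muV) != 1 || object@muV <= 0)
    msg <- c(msg, "muV (mean fork speed) must be a single positive value")
  if (length(object@varV) != 1 || object@varV < 0)
    msg <- c(msg, "varV (speed variance) must be >= 0")
  if (length(object@varT) != 1 || object@varT < 0)
    msg <- c(msg, "varT (firing-time variance) must be >= 0")
  if (length(object@tExp) != 1 || object@tExp <= 0)
    msg <- c(msg, "tExp (observation time) must be > 0")
  if (length(object@pEnd) != 1 || object@pEnd < 0 || object@pEnd > 1)
    msg <- c(msg, "pEnd must be a probability in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a set of global replication parameters
#'
#' Defaults correspond to a wild-type-like parameterisation (mean fork speed
#' 1.5 kb/min, speed variance 0.9 (kb/min)^2, firing-time variance
#' 9.7 min^2, observation at 42 min).
#'
#' @param muV mean fork speed, kb/min.
#' @param varV fork-speed variance, (kb/min)^2; 0 gives the constant-speed
#'   model.
#' @param varT firing-time variance, min^2 (global, shared by all origins).
#' @param tExp observation time, min from S-phase start.
#' @param pEnd per-minute per-fork termination probability.
#' @param modifier optional \linkS4class{SpeedModifierConfig}.
#' @return A \linkS4class{ReplicationParams} object.
#' @examples
#' replicationParams(muV = 1.5, varV = 0.9, varT = 9.7, tExp = 42)
#' @export
replicationParams <- function(muV = 1.5, varV = 0.9, varT = 9.7, tExp = 42,
                              pEnd = 0, modifier = NULL) {
  new("ReplicationParams", muV = muV, varV = varV, varT = varT, tExp = tExp,
      pEnd = pEnd, modifier = modifier)
}

setMethod("show", "ReplicationParams", function(object) {
  cat("ReplicationParams\n")
  cat(sprintf("  mean fork speed muV : %.4g kb/min (variance %.4g)\n",
              object@muV, object@varV))
  cat(sprintf("  firing-time variance: %.4g min^2\n", object@varT))
  cat(sprintf("  observation time    : %.4g min\n", object@tExp))
  if (object@pEnd > 0)
    cat(sprintf("  fork termination    : p_end = %.3g per min\n", object@pEnd))
  if (!is.null(object@modifier))
    cat(sprintf("  speed modifier      : cap %.3g x muV, ramp %.4g kb\n",
                object@modifier@capFactor, object@modifier@rampScale))
  invisible(NULL)
})

#' OriginMap: replication origins with per-origin local parameters
#'
#' An ordered per-chromosome collection of replication origins. Each origin
#' carries its genomic position (kb from the chromosome start, 0-based),
#' the experimentally measured activation frequency (efficiency), the mean
#' firing time (min from S-phase start), and -- once assigned -- a licensing
#' competence in [efficiency, 1].
#'
#' @slot chrom character, chromosome identifier per origin.
#' @slot position numeric, kb from chromosome start; strictly increasing
#'   within each chromosome.
#' @slot efficiency numeric in [0,1], measured activation frequency.
#' @slot muT numeric >= 0, mean firing time (min).
#' @slot competence numeric in [efficiency, 1], or NA before assignment.
#' @slot chromLengths named numeric, chromosome lengths in kb.
#' @exportClass OriginMap
setClass("OriginMap",
  representation(chrom = "character", position = "numeric",
                 efficiency = "numeric", muT = "numeric",
                 competence = "numeric", chromLengths = "numeric"))

setValidity("OriginMap", function(object) {
  msg <- character()
  n <- length(object@chrom)
  if (length(object@position) != n || length(object@efficiency) != n ||
      length(object@muT) != n || length(object@competence) != n)
    return("all per-origin slots must have equal length")
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromLengths must be a named vector of positive kb lengths")
  if (!all(object@chrom %in% names(object@chromLengths)))
    msg <- c(msg, "every origin chromosome must appear in chromLengths")
  bad <- which(object@efficiency < 0 | object@efficiency > 1)
  if (length(bad))
    msg <- c(msg, sprintf("efficiency outside [0,1] for origin %d (%s:%g)",
                          bad[1], object@chrom[bad[1]], object@position[bad[1]]))
  if (any(object@muT < 0)) msg <- c(msg, "mean firing times must be >= 0")
  ok <- !is.na(object@competence)
  if (any(object@competence[ok] < object@efficiency[ok] - 1e-12) ||
      any(object@competence[ok] > 1 + 1e-12))
    msg <- c(msg, "competence must lie in [efficiency, 1]")
  for (ch in unique(object@chrom)) {
    p <- object@position[object@chrom == ch]
    if (any(diff(p) <= 0))
      msg <- c(msg, sprintf("origins on %s must be strictly ordered with unique positions", ch))
    if (any(p < 0) || any(p > object@chromLengths[ch]))
      msg <- c(msg, sprintf("origin positions on %s outside [0, %g] kb", ch,
                            object@chromLengths[ch]))
  }
  if (length(msg)) msg else TRUE
})

#' Create an origin map
#'
#' Origins are sorted by chromosome and position; duplicated positions on a
#' chromosome are an error.
#'
#' @param chrom chromosome identifier per origin.
#' @param position origin position, kb from chromosome start (0-based).
#' @param efficiency measured activation frequency in [0,1].
#' @param muT mean firing time, min.
#' @param chromLengths named numeric vector of chromosome lengths (kb).
#' @param competence optional pre-assigned competences (default NA; see
#'   \code{\link{assignCompetences}}).
#' @return An \linkS4class{OriginMap}.
#' @examples
#' originMap(chrom = "chrI", position = c(30, 70), efficiency = c(0.8, 0.6),
#'           muT = c(10, 20), chromLengths = c(chrI = 230))
#' @export
originMap <- function(chrom, position, efficiency, muT, chromLengths,
                      competence = NA_real_) {
  n <- length(position)
  chrom <- rep_len(as.character(chrom), n)
  efficiency <- rep_len(as.numeric(efficiency), n)
  muT <- rep_len(as.numeric(muT), n)
  competence <- rep_len(as.numeric(competence), n)
  ord <- order(match(chrom, names(chromLengths)), position)
  new("OriginMap", chrom = chrom[ord], position = as.numeric(position)[ord],
      efficiency = as.numeric(efficiency)[ord], muT = as.numeric(muT)[ord],
      competence = competence[ord],
      chromLengths = chromLengths[unique(chrom[ord])])
}

setMethod("show", "OriginMap", function(object) {
  cat(sprintf("OriginMap: %d origins on %d chromosome(s), %.0f kb total\n",
              length(object@position), length(object@chromLengths),
              sum(object@chromLengths)))
  if (all(is.na(object@competence)))
    cat("  competences: not yet assigned\n")
  invisible(NULL)
})

setMethod("length", "OriginMap", function(x) length(x@position))

#' CellProgram: one cell's sampled replication program
#'
#' The stochastic draw for a single cell: per-origin licensing, firing time,
#' and the two independent base speeds of the divergent forks. Lifetimes are
#' the pre-drawn fork survival times used when the per-minute termination
#' probability is positive.
#'
#' @slot licensed logical per origin.
#' @slot t0 numeric, sampled firing times (min), >= 0.
#' @slot vLeft,vRight numeric, base fork speeds (kb/min), > 0.
#' @slot lifeLeft,lifeRight numeric, fork lifetimes (min; Inf when pEnd = 0).
#' @exportClass CellProgram
setClass("CellProgram",
  representation(licensed = "logical", t0 = "numeric", vLeft = "numeric",
                 vRight = "numeric", lifeLeft = "numeric",
                 lifeRight = "numeric"))

setValidity("CellProgram", function(object) {
  n <- length(object@licensed)
  if (any(lengths(list(object@t0, object@vLeft, object@vRight,
                       object@lifeLeft, object@lifeRight)) != n))
    return("all program slots must have equal length")
  if (any(object@t0 < 0)) return("firing times must be >= 0")
  if (any(object@vLeft <= 0) || any(object@vRight <= 0))
    return("fork speeds must be > 0")
  TRUE
})

#' CellOutcome: one simulated cell
#'
#' The realized state of one cell: merged replicated segments at the
#' observation time, per-origin status, fork records, and the completion time
#' (NA when the cell did not finish within the simulated horizon).
#'
#' @slot segments data.frame with columns chrom, start, end (kb; disjoint,
#'   merged intervals).
#' @slot originStatus factor per origin with levels unlicensed,
#'   not-yet-fired, active, passive.
#' @slot forks data.frame of fork records (chrom, origin, dir, vBase, vEff,
#'   birth, term, xStart, xEnd).
#' @slot completionTime numeric(1), min, or NA.
#' @slot tExp numeric(1), observation time used.
#' @exportClass CellOutcome
setClass("CellOutcome",
  representation(segments = "data.frame", originStatus = "factor",
                 forks = "data.frame", completionTime = "numeric",
                 tExp = "numeric"))

setValidity("CellOutcome", function(object) {
  seg <- object@segments
  if (!all(c("chrom", "start", "end") %in% names(seg)))
    return("segments must have columns chrom, start, end")
  if (nrow(seg) && any(seg$end < seg$start))
    return("segment end must be >= start")
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)] - 1e-9))
      return(sprintf("segments overlap on %s", ch))
  }
  TRUE
})

setMethod("show", "CellOutcome", function(object) {
  cat(sprintf("CellOutcome at t = %.4g min: %d segment(s), %d active / %d passive origin(s)%s\n",
              object@tExp, nrow(object@segments),
              sum(object@originStatus == "active"),
              sum(object@originStatus == "passive"),
              if (is.na(object@completionTime)) ""
              else sprintf(", completed at %.4g min", object@completionTime)))
  invisible(NULL)
})

#' PopulationEnsemble: a population of simulated cells
#'
#' @slot originMap the \linkS4class{OriginMap} simulated.
#' @slot params the \linkS4class{ReplicationParams} used.
#' @slot cells list of \linkS4class{CellOutcome}.
#' @slot seed integer master seed.
#' @exportClass PopulationEnsemble
setClass("PopulationEnsemble",
  representation(originMap = "OriginMap", params = "ReplicationParams",
                 cells = "list", seed = "numeric"))

setMethod("show", "PopulationEnsemble", function(object) {
  cat(sprintf("PopulationEnsemble: %d cells, %d origins, t_exp = %.4g min\n",
              length(object@cells), length(object@originMap),
              object@params@tExp))
  invisible(NULL)
})

setMethod("length", "PopulationEnsemble", function(x) length(x@cells))

#' TrackSample: a sample of DNA track lengths
#'
#' DNA tracks are maximal continuous stretches of replicated DNA (kb), the
#' quantity measured by DNA combing.
#'
#' @slot lengths numeric, track lengths in kb, all > 0.
#' @slot label character(1) source label.
#' @slot tExp numeric(1), observation time (min) or NA.
#' @exportClass TrackSample
setClass("TrackSample",
  representation(lengths = "numeric", label = "character", tExp = "numeric"),
  prototype(label = "", tExp = NA_real_))

setValidity("TrackSample", function(object) {
  if (any(object@lengths <= 0)) return("track lengths must be > 0")
  TRUE
})

#' Create a track sample
#' @param lengths track lengths, kb (> 0).
#' @param label source label.
#' @param tExp observation time in min (optional).
#' @return A \linkS4class{TrackSample}.
#' @export
trackSample <- function(lengths, label = "", tExp = NA_real_) {
  new("TrackSample", lengths = as.numeric(lengths), label = label,
      tExp = as.numeric(tExp))
}

setMethod("show", "TrackSample", function(object) {
  cat(sprintf("TrackSample%s: %d tracks, mean %.2f kb, sd %.2f kb\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              length(object@lengths), mean(object@lengths),
              stats::sd(object@lengths)))
  invisible(NULL)
})

setMethod("length", "TrackSample", function(x) length(x@lengths))

#' TrackHistogram: binned, normalized track-length distribution
#'
#' Half-open bins [k*w, (k+1)*w) kb with frequencies summing to one.
#'
#' @slot binWidth numeric(1), kb.
#' @slot binStart numeric, left bin edges (kb).
#' @slot frequency numeric >= 0, sums to 1.
#' @exportClass TrackHistogram
setClass("TrackHistogram",
  representation(binWidth = "numeric", binStart = "numeric",
                 frequency = "numeric"))

setValidity("TrackHistogram", function(object) {
  if (length(object@binStart) != length(object@frequency))
    return("binStart and frequency must have equal length")
  if (any(object@frequency < 0)) return("frequencies must be >= 0")
  if (abs(sum(object@frequency) - 1) > 1e-9)
    return("frequencies must sum to 1")
  TRUE
})

setMethod("show", "TrackHistogram", function(object) {
  cat(sprintf("TrackHistogram: %d bins of %.3g kb, mass over [%g, %g) kb\n",
              length(object@binStart), object@binWidth,
              min(object@binStart), max(object@binStart) + object@binWidth))
  invisible(NULL)
})

#' CopyNumberProfile: a per-position copy-number / BrdU signal track
#'
#' @slot chrom character(1) chromosome identifier.
#' @slot position numeric, kb, strictly ascending.
#' @slot value numeric, finite signal values.
#' @exportClass CopyNumberProfile
setClass("CopyNumberProfile",
  representation(chrom = "character", position = "numeric",
                 value = "numeric"))

setValidity("CopyNumberProfile", function(object) {
  if (length(object@position) != length(object@value))
    return("position and value must have equal length")
  if (any(diff(object@position) <= 0))
    return("positions must be strictly ascending")
  if (any(!is.finite(object@value))) return("values must be finite")
  TRUE
})

#' Create a copy-number profile
#' @param chrom chromosome identifier.
#' @param position positions in kb, strictly ascending.
#' @param value signal values (copy number or BrdU intensity).
#' @return A \linkS4class{CopyNumberProfile}.
#' @export
copyNumberProfile <- function(chrom, position, value) {
  new("CopyNumberProfile", chrom = as.character(chrom)[1],
      position = as.numeric(position), value = as.numeric(value))
}

setMethod("show", "CopyNumberProfile", function(object) {
  cat(sprintf("CopyNumberProfile [%s]: %d points over [%.1f, %.1f] kb\n",
              object@chrom, length(object@position),
              min(object@position), max(object@position)))
  invisible(NULL)
})

#' GaussianFit: Gaussian fit of a per-fork track-length density
#'
#' @slot peak numeric(1), kb, profile peak position (origin location).
#' @slot muDx numeric(1), kb, fitted mean per-fork replicated distance.
#' @slot sigmaDx numeric(1), kb, fitted sd (> 0).
#' @slot amplitude numeric(1), fitted amplitude.
#' @slot residual numeric(1), residual norm of the fit.
#' @slot ok logical(1); FALSE when the fit failed or was degenerate.
#' @exportClass GaussianFit
setClass("GaussianFit",
  representation(peak = "numeric", muDx = "numeric", sigmaDx = "numeric",
                 amplitude = "numeric", residual = "numeric", ok = "logical"))

setMethod("show", "GaussianFit", function(object) {
  if (object@ok)
    cat(sprintf("GaussianFit: peak %.2f kb, muDx %.2f kb, sigma %.2f kb\n",
                object@peak, object@muDx, object@sigmaDx))
  else cat("GaussianFit: failed (flagged)\n")
  invisible(NULL)
})

#' SearchConfig: genetic-algorithm search settings
#'
#' @slot populationSize integer(1) >= 2.
#' @slot generations integer(1) >= 1.
#' @slot bounds named list of c(lower, upper) per free parameter.
#' @slot mutationScale numeric(1), mutation sd as a fraction of bound range.
#' @slot mutationProb numeric(1), per-gene mutation probability.
#' @slot crossoverRate numeric(1), per-gene uniform-crossover probability.
#' @slot elitism numeric(1), elite fraction carried over unchanged.
#' @slot seed numeric(1) master seed.
#' @slot cellsPerEval integer(1), simulated cells per fitness evaluation.
#' @exportClass SearchConfig
setClass("SearchConfig",
  representation(populationSize = "numeric", generations = "numeric",
                 bounds = "list", mutationScale = "numeric",
                 mutationProb = "numeric", crossoverRate = "numeric",
                 elitism = "numeric", seed = "numeric",
                 cellsPerEval = "numeric"))

setValidity("SearchConfig", function(object) {
  msg <- character()
  if (object@populationSize < 2) msg <- c(msg, "populationSize must be >= 2")
  if (length(object@bounds) == 0) msg <- c(msg, "bounds must be non-empty")
  if (is.null(names(object@bounds)) || any(!nzchar(names(object@bounds))))
    msg <- c(msg, "bounds must be a named list")
  for (b in object@bounds)
    if (length(b) != 2 || b[1] > b[2])
      msg <- c(msg, "each bound must be an ordered pair c(lower, upper)")
  if (length(msg)) msg else TRUE
})

#' Create a GA search configuration
#'
#' Defaults follow a population of 5000 candidate parameter sets; tests and
#' examples scale the population down.
#'
#' @param bounds named list of c(lower, upper) per free parameter; names are
#'   matched to \code{\link{replicationParams}} arguments (muV, varV, varT,
#'   tExp, pEnd).
#' @param populationSize number of candidate parameter sets per generation.
#' @param generations number of generations.
#' @param mutationScale Gaussian mutation sd as a fraction of each bound
#'   range.
#' @param mutationProb per-gene mutation probability.
#' @param crossoverRate per-gene uniform crossover probability.
#' @param elitism fraction of the population carried over unchanged.
#' @param seed master seed (fitness evaluations use a common derived seed so
#'   fitness is deterministic within a run).
#' @param cellsPerEval simulated cells per fitness evaluation.
#' @return A \linkS4class{SearchConfig}.
#' @export
searchConfig <- function(bounds, populationSize = 5000, generations = 30,
                         mutationScale = 0.1, mutationProb = 0.2,
                         crossoverRate = 0.5, elitism = 0.01, seed = 1,
                         cellsPerEval = 500) {
  new("SearchConfig", populationSize = populationSize,
      generations = generations, bounds = bounds,
      mutationScale = mutationScale, mutationProb = mutationProb,
      crossoverRate = crossoverRate, elitism = elitism, seed = seed,
      cellsPerEval = cellsPerEval)
}
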