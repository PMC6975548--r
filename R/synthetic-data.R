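# Synthetic yeast-like fixtures: origin maps, combing-like track samples,
# and BrdU-like copy-number profiles, each emitted together with its ground
# truth so that recovery can be tested without any external download.
#
# Default scales emulate S. cerevisiae: ~12 Mb over 16 chromosomes, ~400
# origins at ~30 kb mean spacing, mean firing times spread over early-to-mid
# S phase, efficiencies skewed high (Beta), fork speed ~1.5 kb/min.

#' Specification of a synthetic yeast-like data set
#'
#' @param nChromosomes number of chromosomes.
#' @param genomeLength total genome length, kb.
#' @param nOrigins total number of origins.
#' @param spacingJitter fraction of the mean inter-origin spacing used as
#'   uniform positional jitter.
#' @param firingTimeRange min; origin mean firing times are drawn uniformly
#'   over this range.
#' @param efficiencyShape1,efficiencyShape2 Beta parameters of the origin
#'   efficiency distribution (defaults skew high, mean ~0.77).
#' @param params true \linkS4class{ReplicationParams} of the generator.
#' @param trackNoiseSd kb; Gaussian measurement noise added to track
#'   lengths.
#' @param minDetectable kb; tracks shorter than this are dropped (combing
#'   resolution limit).
#' @param profileNoiseSd additive Gaussian noise on copy-number profiles.
#' @param seed generator seed.
#' @return A classed list (\code{SyntheticSpec}).
#' @export
syntheticSpec <- function(nChromosomes = 16, genomeLength = 12000,
                          nOrigins = 400, spacingJitter = 0.4,
                          firingTimeRange = c(5, 35),
                          efficiencyShape1 = 5, efficiencyShape2 = 1.5,
                          params = replicationParams(muV = 1.5, varV = 0.9,
                                                     varT = 9.7, tExp = 42),
                          trackNoiseSd = 1, minDetectable = 1,
                          profileNoiseSd = 0.02, seed = 1) {
  stopifnot(nOrigins >= 1, genomeLength > 0, nChromosomes >= 1,
            firingTimeRange[1] >= 0, firingTimeRange[2] >= firingTimeRange[1])
  if (nOrigins / genomeLength > 1)
    stop("origins denser than 1 per kb")
  structure(list(nChromosomes = nChromosomes, genomeLength = genomeLength,
                 nOrigins = nOrigins, spacingJitter = spacingJitter,
                 firingTimeRange = firingTimeRange,
                 efficiencyShape1 = efficiencyShape1,
                 efficiencyShape2 = efficiencyShape2, params = params,
                 trackNoiseSd = trackNoiseSd, minDetectable = minDetectable,
                 profileNoiseSd = profileNoiseSd, seed = seed),
            class = "SyntheticSpec")
}

#' Generate a yeast-like origin map
#'
#' Chromosome lengths are drawn around the mean chromosome size; origins are
#' placed at jittered regular spacing, with efficiencies Beta-distributed
#' and mean firing times uniform over the configured range. Deterministic
#' under the spec's seed.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return An \linkS4class{OriginMap} (competences unassigned).
#' @export
makeOriginMap <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(deriveSeed(spec$seed, 11L), {
    nc <- spec$nChromosomes
    w <- runif(nc, 0.6, 1.4)
    lens <- round(spec$genomeLength * w / sum(w), 1)
    lens[nc] <- spec$genomeLength - sum(lens[-nc])
    names(lens) <- sprintf("chr%02d", seq_len(nc))
    nOri <- pmax(1, round(spec$nOrigins * lens / sum(lens)))
    # adjust rounding so the total is honored
    while (sum(nOri) != spec$nOrigins) {
      i <- if (sum(nOri) > spec$nOrigins) which.max(nOri) else which.min(nOri)
      nOri[i] <- nOri[i] + sign(spec$nOrigins - sum(nOri))
    }
    chrom <- character(0); pos <- numeric(0)
    for (i in seq_len(nc)) {
      n <- nOri[i]
      spacing <- lens[i] / (n + 1)
      p <- spacing * seq_len(n) +
        runif(n, -spec$spacingJitter, spec$spacingJitter) * spacing
      p <- sort(pmin(pmax(p, 1), lens[i] - 1))
      # enforce >= 1 kb separation
      if (n > 1) for (j in 2:n) p[j] <- max(p[j], p[j - 1] + 1)
      p <- pmin(p, lens[i] - 0.5)
      chrom <- c(chrom, rep(names(lens)[i], n))
      pos <- c(pos, round(p, 2))
    }
    eff <- rbeta(length(pos), spec$efficiencyShape1, spec$efficiencyShape2)
    muT <- runif(length(pos), spec$firingTimeRange[1],
                 spec$firingTimeRange[2])
    originMap(chrom = chrom, position = pos, efficiency = round(eff, 3),
              muT = round(muT, 2), chromLengths = lens)
  })
}

#' Generate a combing-like DNA-track sample
#'
#' Simulates the population under the spec's true parameters, extracts
#' tracks, adds Gaussian measurement noise and applies the minimum
#' detectable length filter.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param nCells cells to simulate.
#' @param tObs observation time, min; defaults to the spec's tExp.
#' @param map optional pre-built origin map (with or without competences).
#' @return list(sample = \linkS4class{TrackSample}, truth = list(params,
#'   map)).
#' @export
makeCombingSample <- function(spec, nCells = 500, tObs = NULL, map = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (is.null(map)) map <- makeOriginMap(spec)
  map <- assignCompetences(map, seed = deriveSeed(spec$seed, 12L))
  params <- spec$params
  if (!is.null(tObs)) params@tExp <- tObs
  res <- .simulateTracksLean(map, params, nCells,
                             seed = deriveSeed(spec$seed, 13L))
  len <- res$tracks
  if (spec$trackNoiseSd > 0)
    len <- withSeed(deriveSeed(spec$seed, 14L),
                    len + rnorm(length(len), 0, spec$trackNoiseSd))
  len <- len[len >= spec$minDetectable & len > 0]
  list(sample = trackSample(len, label = "synthetic-combing",
                            tExp = params@tExp),
       truth = list(params = params, map = map,
                    activeOrigins = mean(res$active)))
}

#' Generate a BrdU-like copy-number profile
#'
#' Simulates the population to the observation time, computes the fraction
#' of cells in which each grid position is replicated, scales it to a
#' BrdU-like signal and adds noise. The first origin of the chromosome is
#' designated as the calibration origin (a stand-in for a qPCR-verified
#' origin such as ARS305) and its true signal fraction is reported for
#' normalization.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param tObs observation time, min.
#' @param nCells cells to simulate.
#' @param gridStep profile resolution, kb.
#' @param chrom chromosome to profile (default: first).
#' @param gain arbitrary signal gain emulating un-normalized microarray
#'   units.
#' @param map optional pre-built origin map.
#' @return list(profile = \linkS4class{CopyNumberProfile}, truth = list(map,
#'   params, calibration = list(position, efficiency, signal))).
#' @export
makeCopyNumberData <- function(spec, tObs, nCells = 300, gridStep = 1,
                               chrom = NULL, gain = 2.5, map = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (is.null(map)) map <- makeOriginMap(spec)
  map <- assignCompetences(map, seed = deriveSeed(spec$seed, 12L))
  params <- spec$params
  params@tExp <- tObs
  if (is.null(chrom)) chrom <- names(chromLengths(map))[1]
  ens <- simulatePopulation(map, params, nCells,
                            seed = deriveSeed(spec$seed, 15L),
                            recordForks = TRUE)
  grids <- .ensembleTimeGrids(ens, gridStep)[[chrom]]
  frac <- rowMeans(grids$times <= tObs)
  # calibration origin: first origin on the profiled chromosome
  ori <- positions(map)[chroms(map) == chrom]
  calPos <- ori[1]
  calSignalTrue <- frac[which.min(abs(grids$grid - calPos))]
  value <- frac * gain
  if (spec$profileNoiseSd > 0)
    value <- withSeed(deriveSeed(spec$seed, 16L),
                      pmax(0, value + rnorm(length(value), 0,
                                            spec$profileNoiseSd * gain)))
  list(profile = copyNumberProfile(chrom, grids$grid, value),
       truth = list(map = map, params = params,
                    calibration = list(position = calPos,
                                       efficiency = calSignalTrue,
                                       gain = gain)))
}
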