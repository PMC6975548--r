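# Genetic-algorithm fitting of the global replication parameters against a
# target DNA-track histogram, with model selection by active-origin count.
# Fitness is the residual sum of squares between normalized 1-kb track
# histograms. All candidates are evaluated with a common derived seed
# (common random numbers), so fitness is deterministic within a run and the
# GA does not churn on Monte-Carlo noise.

#' RSS fitness of a candidate parameter set
#'
#' Simulates \code{nCells} cells under the candidate parameters, extracts
#' tracks, histograms them in the target's bins, and returns the RSS against
#' the target histogram together with the mean number of active (fired)
#' origins per cell.
#'
#' @param candidate \linkS4class{ReplicationParams}.
#' @param map \linkS4class{OriginMap} with competences assigned.
#' @param targetHist normalized \linkS4class{TrackHistogram} (1-kb bins by
#'   convention).
#' @param nCells cells per evaluation.
#' @param seed evaluation seed.
#' @param minLength minimum detectable track length (kb) applied before
#'   histogramming; match the preprocessing of the target.
#' @return list(rss = , activeOrigins = ) where activeOrigins is the mean
#'   per-cell count of fired origins.
#' @export
objectiveRss <- function(candidate, map, targetHist, nCells, seed = 1,
                         minLength = 1) {
  res <- .simulateTracksLean(map, candidate, nCells, seed)
  keep <- res$tracks[res$tracks >= minLength]
  if (length(keep) == 0)
    return(list(rss = sum(frequencies(targetHist)^2) + 1,
                activeOrigins = mean(res$active)))
  h <- histogramTracks(keep, binWidth = binWidth(targetHist),
                       minLength = minLength)
  list(rss = rssDistance(h, targetHist), activeOrigins = mean(res$active))
}

#' Genetic-algorithm search
#'
#' Real-coded GA with tournament selection (size 3), uniform crossover,
#' Gaussian mutation and elitism. The objective receives a named numeric
#' vector (one element per bound) and must return a list with elements
#' \code{rss} (minimized) and optionally \code{activeOrigins}.
#'
#' @param config \linkS4class{SearchConfig}.
#' @param objective function(namedNumeric) -> list(rss=, activeOrigins=).
#' @return data.frame of all evaluated candidates, ranked by RSS: one column
#'   per parameter plus \code{rss}, \code{active_origins},
#'   \code{generation}.
#' @export
gaSearch <- function(config, objective) {
  stopifnot(is(config, "SearchConfig"))
  validObject(config)
  bounds <- config@bounds
  pn <- names(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  npar <- length(pn)
  popn <- as.integer(config@populationSize)
  nelite <- max(1L, as.integer(ceiling(config@elitism * popn)))

  evalOne <- function(v) {
    r <- objective(setNames(v, pn))
    c(rss = r$rss,
      active = if (is.null(r$activeOrigins)) NA_real_ else r$activeOrigins)
  }

  withSeed(deriveSeed(config@seed, 1L), {
    pop <- matrix(runif(popn * npar, rep(lo, each = popn),
                        rep(hi, each = popn)), nrow = popn)
    colnames(pop) <- pn
    archive <- vector("list", config@generations)
    fit <- t(apply(pop, 1, evalOne))
    archive[[1]] <- data.frame(pop, rss = fit[, "rss"],
                               active_origins = fit[, "active"],
                               generation = 1L)
    for (gen in seq_len(config@generations)[-1]) {
      ord <- order(fit[, "rss"])
      newpop <- pop[ord[seq_len(nelite)], , drop = FALSE]
      while (nrow(newpop) < popn) {
        pick <- function() {  # tournament of 3
          cand <- sample.int(popn, 3)
          cand[which.min(fit[cand, "rss"])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        swap <- runif(npar) < config@crossoverRate
        child <- ifelse(swap, p2, p1)
        mut <- runif(npar) < config@mutationProb
        child[mut] <- child[mut] +
          rnorm(sum(mut), 0, config@mutationScale * (hi - lo)[mut])
        child <- pmin(pmax(child, lo), hi)
        newpop <- rbind(newpop, child)
      }
      # elites keep their fitness; only fresh candidates are re-evaluated
      elfit <- fit[ord[seq_len(nelite)], , drop = FALSE]
      fresh <- t(apply(newpop[-seq_len(nelite), , drop = FALSE], 1, evalOne))
      pop <- newpop
      fit <- rbind(elfit, fresh)
      archive[[gen]] <- data.frame(pop[-seq_len(nelite), , drop = FALSE],
                                   rss = fresh[, "rss"],
                                   active_origins = fresh[, "active"],
                                   generation = gen)
    }
    all <- do.call(rbind, archive)
    rownames(all) <- NULL
    all[order(all$rss), ]
  })
}

#' Fit global replication parameters to a target track histogram
#'
#' Convenience wrapper: builds the RSS objective for a target histogram and
#' runs \code{\link{gaSearch}}. Bound names select the free parameters
#' (\code{muV}, \code{varV}, \code{varT}, \code{tExp}, \code{pEnd});
#' parameters without bounds are held at the values in \code{fixed}.
#'
#' @param map \linkS4class{OriginMap} with competences assigned.
#' @param targetHist normalized target \linkS4class{TrackHistogram}.
#' @param config \linkS4class{SearchConfig}.
#' @param fixed \linkS4class{ReplicationParams} providing the non-searched
#'   parameter values.
#' @param minLength minimum detectable track length (kb).
#' @return Ranked candidate data.frame as from \code{\link{gaSearch}}.
#' @export
fitReplicationParams <- function(map, targetHist, config,
                                 fixed = replicationParams(),
                                 minLength = 1) {
  evalSeed <- deriveSeed(config@seed, 2L)
  nCells <- as.integer(config@cellsPerEval)
  objective <- function(v) {
    cand <- fixed
    for (nm in names(v)) slot(cand, nm) <- unname(v[nm])
    validObject(cand)
    objectiveRss(cand, map, targetHist, nCells, seed = evalSeed,
                 minLength = minLength)
  }
  gaSearch(config, objective)
}

#' Select the final model by active-origin count
#'
#' Among candidates with RSS below the threshold, returns the one whose mean
#' active-origin count is closest to the experimental target; ties are
#' broken by lower RSS. Returns NULL (with a message) when no candidate is
#' admissible.
#'
#' @param candidates ranked candidate data.frame (from
#'   \code{\link{gaSearch}}), with columns \code{rss} and
#'   \code{active_origins}.
#' @param rssThreshold admissibility threshold on RSS.
#' @param originTarget target mean number of active origins per cell.
#' @param originTol reported tolerance band (informational).
#' @return One-row data.frame, or NULL if no admissible model exists.
#' @export
selectModel <- function(candidates, rssThreshold, originTarget,
                        originTol = 10) {
  adm <- candidates[candidates$rss < rssThreshold &
                      is.finite(candidates$active_origins), , drop = FALSE]
  if (nrow(adm) == 0) {
    message("no admissible model: no candidate with RSS < ", rssThreshold)
    return(NULL)
  }
  dev <- abs(adm$active_origins - originTarget)
  best <- adm[order(dev, adm$rss), , drop = FALSE][1, , drop = FALSE]
  if (abs(best$active_origins - originTarget) > originTol)
    warning(sprintf(
      "selected model's active-origin count %.1f is outside %g +/- %g",
      best$active_origins, originTarget, originTol))
  best
}
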