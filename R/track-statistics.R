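# DNA-track extraction, histogramming, distribution distances, and the
# closed-form moment predictions for per-fork replicated distances.
#
# Two track semantics coexist deliberately: the closed-form moments describe
# a SINGLE fork's distance v * (tExp - t0), while DNA combing measures the
# full merged track grown by both forks (and possibly fused bubbles). Use
# sampleForkDistances()/trackMoments() for the former and
# extractTracks()/histogramTracks() for the latter.

#' Extract DNA tracks from simulated cells
#'
#' One track per maximal merged replicated segment; segments fused by fork
#' collisions count once, as in DNA combing where only contiguous labeled
#' stretches are visible.
#'
#' @param x a \linkS4class{CellOutcome} or \linkS4class{PopulationEnsemble}.
#' @param label source label for the returned sample.
#' @return A \linkS4class{TrackSample} (kb).
#' @export
setGeneric("extractTracks", function(x, label = "simulated")
  standardGeneric("extractTracks"))

#' @rdname extractTracks
setMethod("extractTracks", "CellOutcome", function(x, label = "simulated") {
  len <- x@segments$end - x@segments$start
  trackSample(len[len > 0], label = label, tExp = x@tExp)
})

#' @rdname extractTracks
setMethod("extractTracks", "PopulationEnsemble",
          function(x, label = "simulated") {
  len <- unlist(lapply(x@cells, function(cell) {
    l <- cell@segments$end - cell@segments$start
    l[l > 0]
  }), use.names = FALSE)
  trackSample(len, label = label, tExp = x@params@tExp)
})

#' Closed-form moments of the per-fork replicated distance
#'
#' For an origin with mean firing time \code{muT} observed at \code{tExp},
#' the per-fork distance v * (tExp - t0) has, to first order (valid when
#' sigma_t * sigma_v << muDt * muV),
#' mean \code{muDx = muV * muDt} and variance
#' \code{varDx = muV^2 * varT + muDt^2 * varV}, with
#' \code{muDt = tExp - muT}. With \code{varV = 0} (constant-speed model) the
#' second term vanishes and the variance collapses to \code{muV^2 * varT}:
#' a constant-speed fit to stochastic-speed data must therefore inflate
#' varT to compensate.
#'
#' @param params \linkS4class{ReplicationParams}.
#' @param muT origin mean firing time, min; must be < \code{params@tExp}.
#' @return A list with elements \code{muDx} (kb), \code{varDx} (kb^2) and
#'   \code{muDt} (min).
#' @examples
#' trackMoments(replicationParams(muV = 1.5, varV = 0.9, varT = 9.7,
#'                                tExp = 45), muT = 10)
#' @export
trackMoments <- function(params, muT) {
  stopifnot(is(params, "ReplicationParams"))
  muDt <- params@tExp - muT
  if (any(muDt <= 0))
    stop("tExp must exceed muT (origin not yet fired on average)")
  list(muDx = params@muV * muDt,
       varDx = params@muV^2 * params@varT + muDt^2 * params@varV,
       muDt = muDt)
}

#' Histogram a track sample
#'
#' Half-open 1-kb bins [k*w, (k+1)*w) by default, normalized to unit mass.
#' Tracks below the minimum detectable length are dropped first, emulating
#' the resolution limit of DNA combing.
#'
#' @param sample a \linkS4class{TrackSample} or numeric vector of lengths.
#' @param binWidth bin width, kb.
#' @param minLength minimum detectable track length, kb; shorter tracks are
#'   discarded before binning.
#' @return A \linkS4class{TrackHistogram}.
#' @examples
#' histogramTracks(trackSample(c(0.5, 0.7, 1.2)), minLength = 0)
#' @export
histogramTracks <- function(sample, binWidth = 1, minLength = 1) {
  len <- if (is(sample, "TrackSample")) trackLengths(sample) else
    as.numeric(sample)
  len <- len[len >= minLength]
  if (length(len) == 0)
    stop("no tracks to histogram (empty sample after detection filter)")
  bin <- floor(len / binWidth)
  tab <- table(bin)
  starts <- as.numeric(names(tab)) * binWidth
  freq <- as.numeric(tab) / length(len)
  new("TrackHistogram", binWidth = binWidth, binStart = starts,
      frequency = freq)
}

# align two histograms on the union of occupied bins (missing bins = 0)
.alignHist <- function(h1, h2) {
  if (abs(h1@binWidth - h2@binWidth) > 1e-12)
    stop("histograms have mismatched bin widths")
  keys <- sort(union(round(h1@binStart / h1@binWidth),
                     round(h2@binStart / h2@binWidth)))
  f1 <- setNames(numeric(length(keys)), keys)
  f2 <- f1
  f1[as.character(round(h1@binStart / h1@binWidth))] <- h1@frequency
  f2[as.character(round(h2@binStart / h2@binWidth))] <- h2@frequency
  list(f1 = f1, f2 = f2)
}

#' Residual sum of squares between two track histograms
#'
#' Sum of squared differences of normalized bin frequencies over the union
#' of occupied bins. Symmetric; zero iff the histograms are identical.
#'
#' @param h1,h2 \linkS4class{TrackHistogram} objects with equal bin width.
#' @return Nonnegative scalar.
#' @export
rssDistance <- function(h1, h2) {
  a <- .alignHist(h1, h2)
  sum((a$f1 - a$f2)^2)
}

#' Kolmogorov-Smirnov distance between two track samples
#'
#' The maximal absolute distance between the two empirical cumulative
#' distribution functions, used as a model-selection distance (no p-value).
#'
#' @param a,b \linkS4class{TrackSample} objects or numeric vectors.
#' @return Scalar in [0, 1].
#' @export
ksStatistic <- function(a, b) {
  xa <- if (is(a, "TrackSample")) trackLengths(a) else as.numeric(a)
  xb <- if (is(b, "TrackSample")) trackLengths(b) else as.numeric(b)
  if (length(xa) == 0 || length(xb) == 0)
    stop("both samples must be nonempty")
  grid <- sort(unique(c(xa, xb)))
  Fa <- findInterval(grid, sort(xa)) / length(xa)
  Fb <- findInterval(grid, sort(xb)) / length(xb)
  max(abs(Fa - Fb))
}
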