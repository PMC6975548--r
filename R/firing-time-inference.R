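# Per-origin mean-firing-time inference from BrdU copy-number profiles:
# calibrate the signal scale against a reference origin, Savitzky-Golay
# smooth, locate the origin peak, transform the flanks into the probability
# density of the per-fork replicated distance, fit a Gaussian, and invert
# muT = tExp - muDx / muV.
#
# The flank-to-density transformation: around an isolated origin the
# (efficiency-scaled) coverage at distance d from the origin is the survival
# function P(per-fork distance >= d), so minus its derivative in d is the
# per-fork distance density, whose mode the Gaussian fit estimates as muDx.

#' Normalize a copy-number profile against a calibration origin
#'
#' Scales all values by a single factor so that the signal level at the
#' calibration origin equals its independently known efficiency (the role
#' played by a qPCR-verified origin such as ARS305).
#'
#' @param profile a \linkS4class{CopyNumberProfile}.
#' @param refEfficiency known efficiency of the calibration origin, in [0,1].
#' @param refSignal signal level at the calibration origin; if omitted it is
#'   read off the profile at \code{refPosition}.
#' @param refPosition position (kb) of the calibration origin; used when
#'   \code{refSignal} is not given.
#' @return The rescaled profile.
#' @export
normalizeProfile <- function(profile, refEfficiency, refSignal = NULL,
                             refPosition = NULL) {
  stopifnot(is(profile, "CopyNumberProfile"))
  if (is.null(refSignal)) {
    if (is.null(refPosition))
      stop("provide refSignal or refPosition for the calibration origin")
    i <- which.min(abs(positions(profile) - refPosition))
    refSignal <- profileValues(profile)[i]
  }
  if (!is.finite(refSignal) || refSignal == 0)
    stop("calibration origin has zero reference signal")
  copyNumberProfile(chroms(profile), positions(profile),
                    profileValues(profile) * (refEfficiency / refSignal))
}

#' Savitzky-Golay smoothing of a copy-number profile
#'
#' Least-squares local-polynomial smoothing (convolution form), chosen
#' because it minimally distorts peak shapes; the maximum of the smoothed
#' peak marks the origin position.
#'
#' @param profile a \linkS4class{CopyNumberProfile} on a regular grid.
#' @param window odd filter length in grid points, must exceed
#'   \code{polyorder}.
#' @param polyorder polynomial order of the local fit.
#' @return The smoothed profile.
#' @export
smoothProfile <- function(profile, window = 11, polyorder = 3) {
  stopifnot(is(profile, "CopyNumberProfile"))
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  v <- profileValues(profile)
  if (length(v) < window) stop("profile shorter than the filter window")
  sm <- signal::sgolayfilt(v, p = polyorder, n = window)
  copyNumberProfile(chroms(profile), positions(profile), sm)
}

#' Fit a Gaussian to the per-fork distance density around one origin
#'
#' Takes a profile segment containing a single dominant peak, differentiates
#' the two flanks to obtain the per-fork distance density, and least-squares
#' fits a Gaussian \code{A * exp(-(d - muDx)^2 / (2 s^2))} to the pooled
#' flank densities. The fitted mean is the estimate of the mean per-fork
#' replicated distance muDx.
#'
#' @param profile a (normalized, ideally smoothed)
#'   \linkS4class{CopyNumberProfile} segment.
#' @param center peak position (kb); defaults to the profile argmax.
#' @param window half-width (kb) of the flank region used; defaults to the
#'   full segment.
#' @param baseline signal level of unreplicated DNA, subtracted before the
#'   transformation (0 for BrdU-type signals, 1 for absolute copy number).
#' @return A \linkS4class{GaussianFit}; \code{ok = FALSE} flags a failed or
#'   degenerate fit (e.g. a flat segment).
#' @export
fitTrackPdf <- function(profile, center = NULL, window = NULL, baseline = 0) {
  stopifnot(is(profile, "CopyNumberProfile"))
  pos <- positions(profile)
  val <- profileValues(profile) - baseline
  if (is.null(center)) center <- pos[which.max(val)]
  if (is.null(window)) window <- max(center - min(pos), max(pos) - center)
  keep <- abs(pos - center) <= window
  pos <- pos[keep]; val <- val[keep]
  bad <- new("GaussianFit", peak = center, muDx = NA_real_,
             sigmaDx = NA_real_, amplitude = NA_real_, residual = NA_real_,
             ok = FALSE)
  if (length(pos) < 7) return(bad)
  if (max(val) - min(val) < 1e-3 * max(abs(val), 1e-12)) return(bad)  # flat
  # flank densities: -d(signal)/dd on each side of the peak, d = |x - center|
  mid <- pos - center
  dens <- function(side) {
    idx <- if (side > 0) which(mid >= 0) else rev(which(mid <= 0))
    if (length(idx) < 4) return(NULL)
    d <- abs(mid[idx])
    y <- val[idx]
    dd <- diff(d)
    if (any(dd <= 0)) return(NULL)
    data.frame(d = (d[-1] + d[-length(d)]) / 2, f = -diff(y) / dd)
  }
  pts <- rbind(dens(+1), dens(-1))
  if (is.null(pts) || nrow(pts) < 6) return(bad)
  pts$f[pts$f < 0] <- 0
  if (all(pts$f == 0)) return(bad)
  mu0 <- pts$d[which.max(pts$f)]
  s0 <- max(stats::weighted.mean(abs(pts$d - mu0), pts$f), 1)
  a0 <- max(pts$f)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ A * exp(-(d - mu)^2 / (2 * s^2)), data = pts,
                      start = list(A = a0, mu = mu0, s = s0),
                      lower = c(A = 0, mu = 0, s = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- coef(fit)
  if (!is.finite(cf["s"]) || cf["s"] <= 0 || !is.finite(cf["mu"])) return(bad)
  new("GaussianFit", peak = center, muDx = unname(cf["mu"]),
      sigmaDx = unname(cf["s"]), amplitude = unname(cf["A"]),
      residual = sqrt(sum(stats::resid(fit)^2)), ok = TRUE)
}

#' Invert the mean per-fork distance into a mean firing time
#'
#' \code{muT = tExp - muDx / muV}. Negative results (which would mean the
#' origin fired before S-phase start) are clamped to 0 with a warning.
#'
#' @param tExp observation time, min.
#' @param muDx mean per-fork replicated distance, kb (>= 0).
#' @param muV mean fork speed, kb/min (> 0).
#' @return Mean firing time, min.
#' @examples
#' meanFiringTime(tExp = 52, muDx = 2.4, muV = 0.12)  # 32 min
#' @export
meanFiringTime <- function(tExp, muDx, muV) {
  if (any(muV <= 0)) stop("muV must be positive")
  if (any(muDx < 0)) stop("muDx must be >= 0")
  mt <- tExp - muDx / muV
  if (any(mt < 0)) {
    warning("negative inferred firing time(s) clamped to 0")
    mt <- pmax(mt, 0)
  }
  mt
}

#' Full firing-time inference pipeline
#'
#' normalize -> Savitzky-Golay smooth -> per-origin peak refinement ->
#' flank-density Gaussian fit -> muT = tExp - muDx / muV.
#'
#' @param profile a raw \linkS4class{CopyNumberProfile}.
#' @param originPositions candidate origin positions, kb (e.g. from an
#'   \linkS4class{OriginMap}).
#' @param tExp observation time of the profile, min.
#' @param muV mean fork speed, kb/min.
#' @param refEfficiency,refPosition calibration origin (see
#'   \code{\link{normalizeProfile}}); when both are NULL the profile is used
#'   as-is.
#' @param window odd Savitzky-Golay window (grid points).
#' @param polyorder Savitzky-Golay polynomial order.
#' @param baseline unreplicated signal level.
#' @param peakSearch kb; half-width of the window in which each origin's
#'   peak is refined to the local argmax of the smoothed signal.
#' @return data.frame with one row per origin: chrom, position_kb,
#'   peak_kb, mu_dx_kb, mu_t_min, fit_ok.
#' @export
inferFiringTimes <- function(profile, originPositions, tExp, muV,
                             refEfficiency = NULL, refPosition = NULL,
                             window = 11, polyorder = 3, baseline = 0,
                             peakSearch = 10) {
  stopifnot(is(profile, "CopyNumberProfile"))
  if (!is.null(refEfficiency))
    profile <- normalizeProfile(profile, refEfficiency,
                                refPosition = refPosition)
  sm <- smoothProfile(profile, window = window, polyorder = polyorder)
  pos <- positions(sm)
  originPositions <- sort(originPositions)
  n <- length(originPositions)
  # flank half-width per origin: half the distance to the nearest neighbor
  gaps <- diff(originPositions)
  halfw <- pmin(c(gaps, Inf), c(Inf, gaps)) / 2
  halfw[!is.finite(halfw)] <- max(pos) - min(pos)
  out <- data.frame(chrom = chroms(sm), position_kb = originPositions,
                    peak_kb = NA_real_, mu_dx_kb = NA_real_,
                    mu_t_min = NA_real_, fit_ok = FALSE)
  for (i in seq_len(n)) {
    x0 <- originPositions[i]
    near <- which(abs(pos - x0) <= peakSearch)
    if (length(near) == 0) next
    peak <- pos[near[which.max(profileValues(sm)[near])]]
    fit <- fitTrackPdf(sm, center = peak, window = halfw[i],
                       baseline = baseline)
    out$peak_kb[i] <- peak
    if (fit@ok) {
      out$mu_dx_kb[i] <- fit@muDx
      out$mu_t_min[i] <- suppressWarnings(meanFiringTime(tExp, fit@muDx, muV))
      out$fit_ok[i] <- TRUE
    }
  }
  out
}
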