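# Population-level replication analytics: per-position replication-time
# grids, timing (t50) profiles, copy-number-vs-time, completion curves, and
# the slope-vs-approaching-fork-distance analysis.

# per-cell replication time on a regular grid, from fork records; positions
# never covered within the cell's horizon are Inf
.cellTimeGrid <- function(outcome, chrom, grid) {
  tgrid <- rep(Inf, length(grid))
  fk <- outcome@forks
  fk <- fk[fk$chrom == chrom, , drop = FALSE]
  if (nrow(fk) == 0) return(tgrid)
  for (i in seq_len(nrow(fk))) {
    lo <- min(fk$xStart[i], fk$xEnd[i])
    hi <- max(fk$xStart[i], fk$xEnd[i])
    idx <- which(grid >= lo & grid <= hi)
    if (length(idx) == 0) next
    tt <- fk$birth[i] + abs(grid[idx] - fk$xStart[i]) / fk$vEff[i]
    tgrid[idx] <- pmin(tgrid[idx], tt)
  }
  tgrid
}

# grid replication times for every cell of an ensemble: list per chromosome
# of matrices [position, cell]
.ensembleTimeGrids <- function(ensemble, gridStep = 1) {
  map <- ensemble@originMap
  out <- list()
  for (ch in names(chromLengths(map))) {
    grid <- seq(0, chromLengths(map)[[ch]], by = gridStep)
    mat <- vapply(ensemble@cells, .cellTimeGrid, numeric(length(grid)),
                  chrom = ch, grid = grid)
    out[[ch]] <- list(grid = grid, times = matrix(mat, nrow = length(grid)))
  }
  out
}

#' Replication timing profile (t50)
#'
#' Per grid position, the median across cells of the time at which the
#' position was replicated -- the time at which 50\% of the cells have
#' replicated that location. Positions not replicated in at least half of
#' the cells within the simulated horizon are NA; local minima of the
#' profile mark origins.
#'
#' @param ensemble \linkS4class{PopulationEnsemble}, ideally simulated with
#'   \code{until = "completion"} and \code{recordForks = TRUE}.
#' @param gridStep grid step, kb.
#' @return data.frame(chrom, position_kb, t50_min).
#' @export
timingProfile <- function(ensemble, gridStep = 1) {
  grids <- .ensembleTimeGrids(ensemble, gridStep)
  do.call(rbind, lapply(names(grids), function(ch) {
    t50 <- apply(grids[[ch]]$times, 1, median)
    t50[!is.finite(t50)] <- NA_real_
    data.frame(chrom = ch, position_kb = grids[[ch]]$grid, t50_min = t50)
  }))
}

#' DNA copy number at a time point
#'
#' Per grid position, 1 + the fraction of cells whose copy of that position
#' is replicated at time t, i.e. a value in [1, 2].
#'
#' @param ensemble \linkS4class{PopulationEnsemble} (with fork records).
#' @param t time point, min.
#' @param gridStep grid step, kb.
#' @return data.frame(chrom, position_kb, copy_number).
#' @export
copyNumberAt <- function(ensemble, t, gridStep = 1) {
  grids <- .ensembleTimeGrids(ensemble, gridStep)
  do.call(rbind, lapply(names(grids), function(ch) {
    cn <- 1 + rowMeans(grids[[ch]]$times <= t)
    data.frame(chrom = ch, position_kb = grids[[ch]]$grid, copy_number = cn)
  }))
}

#' Genome replication completion curve
#'
#' Fraction of the genome replicated, averaged over cells, as a function of
#' time; nondecreasing and starting at 0.
#'
#' @param ensemble \linkS4class{PopulationEnsemble} (with fork records).
#' @param timeStep curve resolution, min.
#' @param gridStep spatial grid step, kb.
#' @return data.frame(t_min, fraction).
#' @export
completionCurve <- function(ensemble, timeStep = 0.5, gridStep = 2) {
  grids <- .ensembleTimeGrids(ensemble, gridStep)
  alltimes <- unlist(lapply(grids, function(g) as.numeric(g$times)),
                     use.names = FALSE)
  finite <- alltimes[is.finite(alltimes)]
  tmax <- if (length(finite)) max(finite) else 0
  tg <- seq(0, tmax + timeStep, by = timeStep)
  sorted <- sort(finite)
  frac <- findInterval(tg, sorted) / length(alltimes)
  data.frame(t_min = tg, fraction = frac)
}

#' Time at which a replicated fraction is reached
#'
#' First time at which the mean replicated fraction reaches q, with linear
#' interpolation between curve points.
#'
#' @param curve data.frame(t_min, fraction) from
#'   \code{\link{completionCurve}}.
#' @param q target fraction in (0, 1].
#' @return Time in min, or NA (with a message) when q is not reached within
#'   the simulated horizon.
#' @export
timeToFraction <- function(curve, q) {
  stopifnot(q > 0, q <= 1)
  if (max(curve$fraction) < q) {
    message(sprintf("fraction %.3g not reached within the horizon", q))
    return(NA_real_)
  }
  i <- which(curve$fraction >= q)[1]
  if (i == 1) return(curve$t_min[1])
  x0 <- curve$t_min[i - 1]; x1 <- curve$t_min[i]
  y0 <- curve$fraction[i - 1]; y1 <- curve$fraction[i]
  if (y1 == y0) return(x1)
  x0 + (q - y0) / (y1 - y0) * (x1 - x0)
}

#' Local profile slope versus distance to the approaching fork
#'
#' For each origin (a local minimum of the timing profile), estimates the
#' apparent fork speed on each side as the inverse slope of t50 over the
#' monotone run between the minimum and the adjacent local maximum (least
#' squares, noise-robust), and pairs it with D, the distance from the
#' minimum to that maximum (the inter-fork meeting zone). Under
#' location-independent speeds these slopes still vary substantially between
#' regions; a distance-dependent speed modifier additionally induces a
#' positive slope-vs-D correlation.
#'
#' @param profile data.frame from \code{\link{timingProfile}}.
#' @param map \linkS4class{OriginMap} providing candidate origin positions.
#' @param searchWindow kb; half-width around each origin in which its t50
#'   minimum is located.
#' @param emergingFraction fraction of the min-to-max run, measured from the
#'   origin, over which the slope is regressed. Near the origin the profile
#'   slope reflects the emerging fork's speed; toward the maximum it is
#'   dominated by the meeting zone and by cell-to-cell mixing, so the
#'   default uses the origin-proximal 35\% of the run. Set to 1 for the full
#'   run.
#' @return list(table = data.frame(chrom, origin_kb, side, D_kb,
#'   speed_kb_min), correlation = Pearson cor of speed vs D, NA when
#'   degenerate).
#' @export
slopeVsDistance <- function(profile, map, searchWindow = 10,
                            emergingFraction = 0.35) {
  rows <- list()
  for (ch in unique(profile$chrom)) {
    pr <- profile[profile$chrom == ch & is.finite(profile$t50_min), ,
                  drop = FALSE]
    if (nrow(pr) < 5) next
    x <- pr$position_kb; y <- pr$t50_min
    ori <- positions(map)[chroms(map) == ch]
    for (o in ori) {
      near <- which(abs(x - o) <= searchWindow)
      if (length(near) == 0) next
      imin <- near[which.min(y[near])]
      for (side in c(-1, 1)) {
        idx <- imin
        repeat {  # walk the monotone run up to the adjacent maximum
          nxt <- idx + side
          if (nxt < 1 || nxt > length(x)) break
          if (y[nxt] < y[idx]) break
          idx <- nxt
        }
        run <- if (side > 0) imin:idx else idx:imin
        if (length(run) < 3) next
        D <- abs(x[idx] - x[imin])
        run <- run[abs(x[run] - x[imin]) <= D * emergingFraction]
        if (length(run) < 3) next
        fitc <- coef(lm(y[run] ~ x[run]))[2]
        if (!is.finite(fitc) || fitc == 0) next
        rows[[length(rows) + 1]] <-
          data.frame(chrom = ch, origin_kb = o, side = side, D_kb = D,
                     speed_kb_min = 1 / abs(fitc))
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), origin_kb = numeric(), side = numeric(),
               D_kb = numeric(), speed_kb_min = numeric())
  corr <- if (nrow(tab) >= 3 && sd(tab$D_kb) > 0 &&
              sd(tab$speed_kb_min) > 0)
    cor(tab$D_kb, tab$speed_kb_min) else NA_real_
  list(table = tab, correlation = corr)
}
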