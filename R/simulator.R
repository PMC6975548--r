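# R-level surface of the Monte-Carlo replication engine. Per-cell programs
# are sampled in C++ from counter-based RNG streams derived from the master
# seed, so ensembles are reproducible independently of R's RNG state and of
# the number of cells requested.

.chromIndex <- function(map) {
  match(chroms(map), names(chromLengths(map))) - 1L
}

.engineParams <- function(params, dt = 0.1, toCompletion = FALSE,
                          horizon = NULL, speedScale = 1) {
  mod <- params@modifier
  list(mu_v = params@muV, var_v = params@varV, var_t = params@varT,
       t_exp = if (toCompletion) horizon else params@tExp,
       to_completion = toCompletion,
       p_end = params@pEnd,
       use_mod = !is.null(mod),
       cap_factor = if (is.null(mod)) 1.9 else mod@capFactor,
       ramp_scale = if (is.null(mod)) 100 else mod@rampScale,
       speed_scale = speedScale,
       reeval_mod = if (is.null(mod)) FALSE else mod@reevalPerStep,
       dt = dt)
}

# pilot-run calibration of the base-speed scale so that the population mean
# effective fork speed equals muV when the distance modifier is active
.calibrateScale <- function(map, params, dt, seed, pilotCells = 50) {
  mod <- params@modifier
  if (is.null(mod) || !mod@calibrateMean) return(1)
  scale <- 1
  # fixed-point iteration: the cap makes the mean effective speed a
  # nonlinear function of the base-speed scale
  for (it in 1:3) {
    ep <- .engineParams(params, dt = dt, speedScale = scale)
    res <- .simulate_tracks_cpp(as.numeric(chromLengths(map)),
                                .chromIndex(map), positions(map),
                                competences(map), meanFiringTimes(map),
                                ep, as.integer(pilotCells),
                                as.numeric(deriveSeed(seed, 997L)))
    mv <- res$mean_v_eff
    if (!is.finite(mv) || mv <= 0) return(scale)
    scale <- scale * params@muV / mv
  }
  scale
}

.checkCompetences <- function(map) {
  if (anyNA(competences(map)))
    stop("competences not assigned; call assignCompetences() first")
}

#' Sample one cell's replication program
#'
#' Draws per-origin licensing flags (Bernoulli with the origin's competence),
#' firing times (normal with the origin's mean firing time and the global
#' firing-time variance, truncated to >= 0 by resampling), and two
#' independent base fork speeds per origin (normal with the global mean and
#' variance, truncated to > 0 by resampling).
#'
#' @param map an \linkS4class{OriginMap} with competences assigned.
#' @param params \linkS4class{ReplicationParams}.
#' @param seed master seed.
#' @param cellIndex stream index; \code{simulatePopulation} uses streams
#'   1..nCells of the same master seed.
#' @return A \linkS4class{CellProgram}.
#' @export
sampleCellProgram <- function(map, params, seed = 1, cellIndex = 1) {
  stopifnot(is(map, "OriginMap"), is(params, "ReplicationParams"))
  .checkCompetences(map)
  ep <- .engineParams(params)
  pr <- .sample_program_cpp(competences(map), meanFiringTimes(map), ep,
                            as.numeric(seed), as.numeric(cellIndex))
  new("CellProgram", licensed = as.logical(pr$licensed), t0 = pr$t0,
      vLeft = pr$v_left, vRight = pr$v_right, lifeLeft = pr$life_left,
      lifeRight = pr$life_right)
}

.outcomeFromRaw <- function(raw, map, tExp) {
  seg <- data.frame(chrom = names(chromLengths(map))[raw$seg_chrom + 1L],
                    start = raw$seg_start, end = raw$seg_end,
                    stringsAsFactors = FALSE)
  seg <- seg[order(match(seg$chrom, names(chromLengths(map))), seg$start), ,
             drop = FALSE]
  rownames(seg) <- NULL
  status <- factor(c("unlicensed", "not-yet-fired", "active",
                     "passive")[raw$status + 1L],
                   levels = c("unlicensed", "not-yet-fired", "active",
                              "passive"))
  forks <- if (!is.null(raw$forks)) {
    f <- raw$forks
    data.frame(chrom = names(chromLengths(map))[f$chrom + 1L],
               origin = f$origin, dir = f$dir, vBase = f$v_base,
               vEff = f$v_eff, birth = f$birth, term = f$term,
               xStart = f$x_start, xEnd = f$x_end, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), origin = numeric(), dir = numeric(),
               vBase = numeric(), vEff = numeric(), birth = numeric(),
               term = numeric(), xStart = numeric(), xEnd = numeric())
  }
  new("CellOutcome", segments = seg, originStatus = status, forks = forks,
      completionTime = raw$completion, tExp = tExp)
}

#' Replicate a single cell from an explicit program
#'
#' Propagates the forks of one sampled \linkS4class{CellProgram} with the
#' fixed-step kinetic engine. Forks advance at their effective speeds from
#' their firing times; a fork terminates when it meets an oncoming fork (the
#' meeting point is placed at the exact weighted collision point), reaches a
#' chromosome end or an already-replicated segment, or -- when
#' \code{pEnd > 0} -- at its pre-drawn lifetime. Origins covered before their
#' own firing time are marked passive and never fire.
#'
#' @param program a \linkS4class{CellProgram}.
#' @param map the \linkS4class{OriginMap} the program was sampled for.
#' @param params \linkS4class{ReplicationParams}.
#' @param until either \code{"tExp"} (observe at \code{params@tExp}) or
#'   \code{"completion"}.
#' @param dt time step in minutes (> 0).
#' @param horizon safety cap (min) used when \code{until = "completion"}.
#' @param speedScale internal base-speed scale (modifier calibration).
#' @return A \linkS4class{CellOutcome}.
#' @export
replicateCell <- function(program, map, params, until = c("tExp", "completion"),
                          dt = 0.1, horizon = 200, speedScale = 1) {
  stopifnot(is(program, "CellProgram"), is(map, "OriginMap"))
  until <- match.arg(until)
  if (!is.numeric(dt) || dt <= 0) stop("time step dt must be positive")
  ep <- .engineParams(params, dt = dt, toCompletion = until == "completion",
                      horizon = horizon, speedScale = speedScale)
  prog <- list(licensed = as.integer(program@licensed), t0 = program@t0,
               v_left = program@vLeft, v_right = program@vRight,
               life_left = program@lifeLeft, life_right = program@lifeRight)
  raw <- .replicate_program_cpp(as.numeric(chromLengths(map)),
                                .chromIndex(map), positions(map), prog, ep,
                                TRUE)
  .outcomeFromRaw(raw, map, ep$t_exp)
}

#' Distance-dependent effective fork speed
#'
#' The empirical speed modifier: an emerging fork's speed is multiplied by
#' \code{min(capFactor, 1 + (capFactor - 1) * min(1, D / rampScale))}, where
#' D is the distance (kb) to the nearest approaching fork, and the result is
#' capped at \code{capFactor * muV}. With no modifier configured the base
#' speed is returned unchanged.
#'
#' @param baseSpeed base fork speed(s), kb/min.
#' @param D distance(s) to the approaching fork, kb, >= 0.
#' @param params \linkS4class{ReplicationParams}; the modifier settings are
#'   taken from \code{params@modifier}.
#' @return Effective speed(s), kb/min.
#' @examples
#' p <- replicationParams(muV = 1.5, modifier = speedModifierConfig())
#' modifiedSpeed(1.5, D = c(0, 50, 200), p)
#' @export
modifiedSpeed <- function(baseSpeed, D, params) {
  if (any(D < 0)) stop("distance D to the approaching fork must be >= 0")
  mod <- params@modifier
  if (is.null(mod)) return(baseSpeed)
  f <- pmin(mod@capFactor,
            1 + (mod@capFactor - 1) * pmin(1, D / mod@rampScale))
  pmin(baseSpeed * f, mod@capFactor * params@muV)
}

#' Simulate a population of cells
#'
#' Runs \code{nCells} independent single-cell replications. Each cell uses
#' its own RNG stream derived from the master seed, so the ensemble is
#' reproducible given \code{(seed, nCells, params)} and cell i of a larger
#' ensemble equals cell i of a smaller one.
#'
#' @param map an \linkS4class{OriginMap} with competences assigned.
#' @param params \linkS4class{ReplicationParams}.
#' @param nCells number of cells (>= 1).
#' @param seed master seed.
#' @param until \code{"tExp"} or \code{"completion"}.
#' @param dt time step, min.
#' @param horizon safety cap (min) for completion mode.
#' @param recordForks keep per-fork records in each
#'   \linkS4class{CellOutcome} (needed for timing profiles).
#' @return A \linkS4class{PopulationEnsemble}.
#' @examples
#' m <- assignCompetences(originMap("chrI", 115, 0.9, 10, c(chrI = 230)))
#' p <- replicationParams(muV = 1.5, varV = 0.3, varT = 4, tExp = 30)
#' simulatePopulation(m, p, nCells = 5, seed = 1)
#' @export
simulatePopulation <- function(map, params, nCells, seed = 1,
                               until = c("tExp", "completion"), dt = 0.1,
                               horizon = 200, recordForks = TRUE) {
  stopifnot(is(map, "OriginMap"), is(params, "ReplicationParams"),
            nCells >= 1)
  .checkCompetences(map)
  until <- match.arg(until)
  scale <- .calibrateScale(map, params, dt, seed)
  ep <- .engineParams(params, dt = dt, toCompletion = until == "completion",
                      horizon = horizon, speedScale = scale)
  raws <- .simulate_population_cpp(as.numeric(chromLengths(map)),
                                   .chromIndex(map), positions(map),
                                   competences(map), meanFiringTimes(map),
                                   ep, as.integer(nCells), as.numeric(seed),
                                   recordForks)
  outs <- lapply(raws, .outcomeFromRaw, map = map, tExp = ep$t_exp)
  new("PopulationEnsemble", originMap = map, params = params, cells = outs,
      seed = as.numeric(seed))
}

# Lean fitness-evaluation path: pooled track lengths and per-cell active
# origin counts without per-cell S4 construction.
.simulateTracksLean <- function(map, params, nCells, seed, dt = 0.1) {
  .checkCompetences(map)
  scale <- .calibrateScale(map, params, dt, seed)
  ep <- .engineParams(params, dt = dt, speedScale = scale)
  .simulate_tracks_cpp(as.numeric(chromLengths(map)), .chromIndex(map),
                       positions(map), competences(map),
                       meanFiringTimes(map), ep, as.integer(nCells),
                       as.numeric(seed))
}

#' Sample per-fork replicated distances under the kinetic model
#'
#' Draws firing times and fork speeds exactly as the simulator does
#' (truncated normals) and returns the per-fork distance
#' v * (tExp - t0) for an unobstructed fork of an origin with mean firing
#' time \code{muT}. This is the quantity whose moments the closed-form
#' track theory predicts (see \code{\link{trackMoments}}).
#'
#' @param params \linkS4class{ReplicationParams}.
#' @param muT the origin's mean firing time, min.
#' @param n number of draws.
#' @param seed seed.
#' @return Numeric vector of n distances (kb); draws with t0 > tExp
#'   (origin not yet fired) are returned as NA.
#' @export
sampleForkDistances <- function(params, muT, n, seed = 1) {
  stopifnot(is(params, "ReplicationParams"), n >= 1)
  withSeed(seed, {
    t0 <- rnorm(n, muT, sqrt(params@varT))
    while (any(neg <- t0 < 0))
      t0[neg] <- rnorm(sum(neg), muT, sqrt(params@varT))
    v <- rnorm(n, params@muV, sqrt(params@varV))
    while (any(neg <- v <= 0))
      v[neg] <- rnorm(sum(neg), params@muV, sqrt(params@varV))
    ifelse(t0 <= params@tExp, v * (params@tExp - t0), NA_real_)
  })
}
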