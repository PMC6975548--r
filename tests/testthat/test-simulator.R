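test_that("degenerate sampling gives the configured means exactly", {
  m <- tinyMap(muT = 10)
  p <- detParams(muV = 1.5, tExp = 30)
  pr <- sampleCellProgram(m, p, seed = 1)
  expect_true(all(pr@licensed))                 # competence 1 everywhere
  expect_equal(pr@t0, rep(10, 3))
  expect_equal(pr@vLeft, rep(1.5, 3))
  expect_equal(pr@vRight, rep(1.5, 3))
})

test_that("truncated sampling reproduces the configured moments", {
  # 10/sqrt(9.7) ~ 3.2 sd: truncation negligible
  m <- assignCompetences(originMap("c", seq(2, 2000, by = 2), 1, 10,
                                   c(c = 2002)))
  p <- replicationParams(muV = 1.5, varV = 0.09, varT = 9.7, tExp = 45)
  t0s <- vs <- NULL
  for (i in 1:100) {
    pr <- sampleCellProgram(m, p, seed = 7, cellIndex = i)
    t0s <- c(t0s, pr@t0); vs <- c(vs, pr@vLeft, pr@vRight)
  }
  expect_lt(abs(mean(t0s) - 10), 0.05)
  expect_lt(abs(var(t0s) - 9.7) / 9.7, 0.02)
  expect_lt(abs(mean(vs) - 1.5), 0.01)
  expect_lt(abs(var(vs) - 0.09) / 0.09, 0.03)
  expect_true(all(t0s >= 0) && all(vs > 0))
})

test_that("single free origin expands symmetrically", {
  m <- tinyMap(positions = 50, len = 200)
  out <- replicateCell(detProgram(0, 1, 1), m, detParams(muV = 1, tExp = 30))
  expect_equal(segments(out),
               data.frame(chrom = "chrI", start = 20, end = 80))
  expect_equal(trackLengths(extractTracks(out)), 60)
})

test_that("unequal-speed forks meet at the exact weighted point", {
  m <- tinyMap(positions = c(0.0001, 90), len = 200)
  # right fork of A at speed 2, left fork of B at speed 1: meet at 60, t=30
  out <- replicateCell(detProgram(c(0, 0), c(1, 1), c(2, 1)), m,
                       detParams(tExp = 100), until = "completion")
  fk <- forkRecords(out)
  meet <- fk[fk$origin == 1 & fk$dir == 1, ]
  expect_equal(meet$xEnd, 60, tolerance = 1e-4)
  expect_equal(meet$term, 30, tolerance = 1e-4)
})

test_that("an origin covered before firing is passive and never fires", {
  m <- tinyMap(positions = c(0.0001, 60), muT = c(0, 100), len = 200)
  out <- replicateCell(detProgram(c(0, 100), c(1, 1), c(1, 1)), m,
                       detParams(tExp = 80))
  expect_equal(as.character(originStatus(out)), c("active", "passive"))
  expect_equal(nrow(forkRecords(out)), 2)   # only origin A's forks exist
})

test_that("population simulation is deterministic and stream-stable", {
  m <- tinyMap(eff = 0.7, muT = 10)
  p <- replicationParams(muV = 1.5, varV = 0.3, varT = 4, tExp = 25)
  e1 <- simulatePopulation(m, p, 10, seed = 5)
  e2 <- simulatePopulation(m, p, 10, seed = 5)
  expect_identical(lapply(cells(e1), segments), lapply(cells(e2), segments))
  # cell i does not depend on how many cells were requested
  e3 <- simulatePopulation(m, p, 3, seed = 5)
  expect_identical(segments(cells(e1)[[3]]), segments(cells(e3)[[3]]))
  # and equals replicateCell on the same program stream
  pr <- sampleCellProgram(m, p, seed = 5, cellIndex = 1)
  solo <- replicateCell(pr, m, p)
  expect_equal(segments(cells(e1)[[1]]), segments(solo))
})

test_that("constant-speed mode matches the event-driven oracle cell by cell", {
  m <- tinyMap(positions = c(60, 180, 300, 420), eff = 1, muT = 15, len = 500)
  p <- replicationParams(muV = 1.5, varV = 0, varT = 25, tExp = 35)
  ens <- simulatePopulation(m, p, 20, seed = 9)
  for (i in seq_len(20)) {
    pr <- sampleCellProgram(m, p, seed = 9, cellIndex = i)
    oracle <- eventOracleSegments(positions(m), pr@t0, pr@vLeft, pr@vRight,
                                  500, 35)
    seg <- segments(cells(ens)[[i]])
    expect_equal(nrow(seg), nrow(oracle))
    expect_equal(seg$start, oracle$start, tolerance = 0.2)
    expect_equal(seg$end, oracle$end, tolerance = 0.2)
  }
})

test_that("unobstructed fork distance equals speed times elapsed time", {
  m <- tinyMap(positions = 250, len = 500)
  out <- replicateCell(detProgram(3, 0.7, 1.3), m,
                       detParams(muV = 1, tExp = 40))
  fk <- forkRecords(out)
  expect_equal(abs(fk$xEnd - fk$xStart), fk$vEff * (40 - 3),
               tolerance = 1e-9)
})

test_that("per-minute termination probability stops forks early", {
  m <- tinyMap(positions = 250, len = 500, muT = 0)
  p <- replicationParams(muV = 1, varV = 0, varT = 0, tExp = 100, pEnd = 0.05)
  lens <- trackLengths(extractTracks(simulatePopulation(m, p, 200, seed = 2)))
  # mean two-fork distance with per-minute kill rate ~ 2/rate << 200
  expect_lt(mean(lens), 100)
  p0 <- replicationParams(muV = 1, varV = 0, varT = 0, tExp = 100)
  lens0 <- trackLengths(extractTracks(simulatePopulation(m, p0, 5, seed = 2)))
  expect_equal(lens0, rep(200, 5), tolerance = 1e-9)  # free expansion
})

test_that("speed modifier is monotone in D, neutral at D=0, and capped", {
  p <- replicationParams(muV = 1.5,
                         modifier = speedModifierConfig(capFactor = 1.9,
                                                        rampScale = 100))
  expect_equal(modifiedSpeed(1.2, 0, p), 1.2)
  v <- modifiedSpeed(1.2, seq(0, 300, by = 5), p)
  expect_true(all(diff(v) >= 0))
  expect_true(all(modifiedSpeed(runif(100, 0.1, 5),
                                runif(100, 0, 500), p) <= 1.9 * 1.5 + 1e-12))
  expect_error(modifiedSpeed(1, -1, p), "D")
  # no modifier configured: identity
  expect_equal(modifiedSpeed(1.2, 50, replicationParams()), 1.2)
})

test_that("mean-speed calibration keeps the effective mean speed at muV", {
  spec <- syntheticSpec(nChromosomes = 2, genomeLength = 2000, nOrigins = 60,
                        seed = 3)
  map <- assignCompetences(makeOriginMap(spec), seed = 3)
  p <- spec$params
  p@modifier <- speedModifierConfig(calibrateMean = TRUE)
  ens <- simulatePopulation(map, p, 30, seed = 6)
  ve <- unlist(lapply(cells(ens), function(x) forkRecords(x)$vEff))
  expect_lt(abs(mean(ve) - p@muV) / p@muV, 0.1)
})
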