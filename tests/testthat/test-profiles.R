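test_that("deterministic single origin yields the exact linear wedge", {
  m <- tinyMap(positions = 100, len = 200, muT = 5)
  out <- simulatePopulation(m, detParams(muV = 2, tExp = 100), 3, seed = 1,
                            until = "completion")
  tp <- timingProfile(out, gridStep = 1)
  expect_equal(tp$t50_min, 5 + abs(tp$position_kb - 100) / 2,
               tolerance = 1e-6)
})

test_that("t50 at an origin approximates its mean firing time", {
  m <- tinyMap(positions = 250, len = 500, muT = 12)
  p <- replicationParams(muV = 1.5, varV = 0, varT = 9, tExp = 100)
  ens <- simulatePopulation(m, p, 400, seed = 3, until = "completion",
                            horizon = 600)
  tp <- timingProfile(ens)
  expect_lt(abs(tp$t50_min[tp$position_kb == 250] - 12), 0.5)
  # profile minima sit at origin positions in a two-origin config
  m2 <- tinyMap(positions = c(120, 380), len = 500, muT = c(5, 10))
  ens2 <- simulatePopulation(m2, detParams(tExp = 400), 3, seed = 1,
                             until = "completion", horizon = 500)
  tp2 <- timingProfile(ens2)
  for (o in c(120, 380)) {
    local <- tp2[abs(tp2$position_kb - o) <= 30, ]
    expect_equal(local$position_kb[which.min(local$t50_min)], o)
  }
})

test_that("copy number interpolates between 1 and 2 and matches t50", {
  m <- tinyMap(positions = 250, len = 500, muT = 10)
  p <- replicationParams(muV = 1.5, varV = 0.04, varT = 9, tExp = 100)
  ens <- simulatePopulation(m, p, 200, seed = 5, until = "completion",
                            horizon = 800)
  cn0 <- copyNumberAt(ens, 0)
  expect_true(all(cn0$copy_number == 1))
  cnEnd <- copyNumberAt(ens, 800)
  expect_true(all(cnEnd$copy_number == 2))
  # deterministic single origin: step profile
  # fires at muT = 10, so by t = 30 each fork has traveled 20 kb
  ensd <- simulatePopulation(m, detParams(muV = 1, tExp = 50), 3, seed = 1)
  cnd <- copyNumberAt(ensd, 30)
  inside <- abs(cnd$position_kb - 250) <= 20 - 1e-9
  expect_true(all(cnd$copy_number[inside] == 2))
  expect_true(all(cnd$copy_number[abs(cnd$position_kb - 250) > 20] == 1))
  # consistency: copy number crosses 1.5 at t50
  tp <- timingProfile(ens)
  pos <- 300
  t50 <- tp$t50_min[tp$position_kb == pos]
  below <- copyNumberAt(ens, t50 - 1)$copy_number[tp$position_kb == pos]
  above <- copyNumberAt(ens, t50 + 1)$copy_number[tp$position_kb == pos]
  expect_lte(below, 1.5 + 0.1)
  expect_gte(above, 1.5 - 0.1)
})

test_that("completion curve is monotone and hits exact geometry", {
  m <- tinyMap(positions = 100, len = 200, muT = 0)
  ens <- simulatePopulation(m, detParams(muV = 2, tExp = 100), 3, seed = 1,
                            until = "completion")
  cc <- completionCurve(ens, timeStep = 0.5, gridStep = 1)
  expect_true(all(diff(cc$fraction) >= 0))
  expect_equal(cc$fraction[1], 0, tolerance = 0.02)
  # centered origin, speed 2, half-length 100 -> completion at 50 min
  expect_equal(timeToFraction(cc, 1), 50, tolerance = 1)
  expect_equal(timeToFraction(cc, 1e-9), 0, tolerance = 0.6)
  expect_message(na <- timeToFraction(cc[cc$t_min < 20, ], 0.99),
                 "not reached")
  expect_true(is.na(na))
})

test_that("profile slopes vary even with location-independent speeds", {
  spec <- syntheticSpec(nChromosomes = 1, genomeLength = 1500, nOrigins = 40,
                        seed = 19)
  map <- assignCompetences(makeOriginMap(spec), seed = 19)
  p <- spec$params
  ens <- simulatePopulation(map, p, 120, seed = 23, until = "completion",
                            horizon = 500)
  tp <- timingProfile(ens)
  sv <- slopeVsDistance(tp, map)
  expect_gt(nrow(sv$table), 10)
  cv <- sd(sv$table$speed_kb_min) / mean(sv$table$speed_kb_min)
  expect_gt(cv, 0.1)
})

test_that("homogeneous deterministic spacing gives uniform slopes", {
  m <- tinyMap(positions = c(100, 300), len = 400, muT = 0)
  ens <- simulatePopulation(m, detParams(muV = 1.5, tExp = 300), 3, seed = 1,
                            until = "completion", horizon = 400)
  sv <- slopeVsDistance(timingProfile(ens), m)
  expect_true(all(abs(sv$table$speed_kb_min - 1.5) < 0.05))
  expect_true(is.na(sv$correlation))  # zero variance: reported as undefined
})

test_that("the distance modifier induces a stronger slope-distance link", {
  spec <- syntheticSpec(nChromosomes = 1, genomeLength = 3000, nOrigins = 80,
                        seed = 29)
  map <- assignCompetences(makeOriginMap(spec), seed = 29)
  base <- spec$params
  mod <- base
  mod@modifier <- speedModifierConfig(capFactor = 1.9, rampScale = 100)
  e1 <- simulatePopulation(map, base, 100, seed = 31, until = "completion",
                           horizon = 600)
  e2 <- simulatePopulation(map, mod, 100, seed = 31, until = "completion",
                           horizon = 600)
  c1 <- slopeVsDistance(timingProfile(e1), map)$correlation
  c2 <- slopeVsDistance(timingProfile(e2), map)$correlation
  expect_gt(c2, c1)
  expect_gt(c2, 0)
})
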