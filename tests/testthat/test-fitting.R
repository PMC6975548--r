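test_that("self-comparison RSS is zero and ordering is sane", {
  spec <- syntheticSpec(nChromosomes = 1, genomeLength = 600, nOrigins = 20,
                        trackNoiseSd = 0, minDetectable = 1, seed = 11)
  map <- assignCompetences(makeOriginMap(spec), seed = 4)
  gen <- spec$params; gen@tExp <- 20
  res <- replifork:::.simulateTracksLean(map, gen, 200, seed = 77)
  target <- histogramTracks(res$tracks[res$tracks >= 1])
  # same params, same seed, same n: identical tracks, RSS exactly 0
  self <- objectiveRss(gen, map, target, 200, seed = 77)
  expect_equal(self$rss, 0)
  expect_equal(self$activeOrigins, mean(res$active))
  # independent seed: generator beats a candidate with muV off by 50%
  good <- objectiveRss(gen, map, target, 500, seed = 78)
  off <- gen; off@muV <- gen@muV * 1.5
  worse <- objectiveRss(off, map, target, 500, seed = 78)
  expect_lt(good$rss, worse$rss)
  off2 <- gen; off2@muV <- gen@muV * 0.5
  expect_lt(good$rss, objectiveRss(off2, map, target, 500, seed = 78)$rss)
})

test_that("matched speed-stochasticity beats a constant-speed candidate", {
  spec <- syntheticSpec(nChromosomes = 1, genomeLength = 600, nOrigins = 20,
                        trackNoiseSd = 0, seed = 11)
  map <- assignCompetences(makeOriginMap(spec), seed = 4)
  gen <- spec$params; gen@tExp <- 20   # varV = 0.9 generator
  res <- replifork:::.simulateTracksLean(map, gen, 800, seed = 80)
  target <- histogramTracks(res$tracks[res$tracks >= 1])
  matched <- objectiveRss(gen, map, target, 500, seed = 81)
  const <- gen; const@varV <- 0
  expect_lt(matched$rss, objectiveRss(const, map, target, 500, seed = 81)$rss)
})

test_that("GA minimizes a convex toy objective", {
  cfg <- searchConfig(bounds = list(a = c(-5, 5)), populationSize = 50,
                      generations = 20, seed = 3)
  ranked <- gaSearch(cfg, function(v) list(rss = (v[["a"]] - 1.7)^2))
  expect_lt(abs(ranked$a[1] - 1.7), 0.01 * 10)  # within 1% of the range
  expect_lt(ranked$rss[1], 1e-3)
})

test_that("elitism makes the best fitness nonincreasing over generations", {
  cfg <- searchConfig(bounds = list(a = c(-4, 4), b = c(-4, 4)),
                      populationSize = 30, generations = 12, seed = 9)
  ranked <- gaSearch(cfg, function(v)
    list(rss = (v[["a"]] - 1)^2 + (v[["b"]] + 2)^2 + 0.5))
  bestByGen <- vapply(split(ranked$rss, ranked$generation), min, numeric(1))
  run <- cummin(bestByGen)
  expect_true(all(diff(run) <= 0))
  expect_true(all(bestByGen >= 0.5))
  # reproducible under the master seed
  ranked2 <- gaSearch(cfg, function(v)
    list(rss = (v[["a"]] - 1)^2 + (v[["b"]] + 2)^2 + 0.5))
  expect_equal(ranked$rss, ranked2$rss)
})

test_that("model selection applies the active-origin rule", {
  cands <- data.frame(muV = c(1.4, 1.5, 1.6), rss = c(0.3, 0.4, 0.9),
                      active_origins = c(300, 281, 280))
  best <- selectModel(cands, rssThreshold = 0.65, originTarget = 280)
  expect_equal(best$active_origins, 281)  # admissible and closest
  expect_warning(one <- selectModel(cands[1, ], 0.65, 280), "outside")
  expect_equal(one$rss, 0.3)
  expect_message(none <- selectModel(cands, 0, 280), "no admissible")
  expect_null(none)
  # tie on |count - target| broken by lower RSS
  tie <- data.frame(rss = c(0.4, 0.2), active_origins = c(279, 281))
  expect_equal(selectModel(tie, 0.65, 280)$rss, 0.2)
})

test_that("GA search errors on empty or malformed bounds", {
  expect_error(searchConfig(bounds = list()), "non-empty")
  expect_error(searchConfig(bounds = list(a = c(2, 1))), "ordered")
})
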