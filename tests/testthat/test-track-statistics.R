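test_that("track extraction merges fused bubbles and matches a union oracle", {
  # two bubbles that have merged into [0,130]
  m <- tinyMap(positions = c(40, 90), len = 300)
  out <- replicateCell(detProgram(c(0, 0), c(1, 1), c(1, 1)), m,
                       detParams(muV = 1, tExp = 40))
  expect_equal(trackLengths(extractTracks(out)), 130)
  # random deterministic configs: tracks equal union of per-fork intervals
  withr::with_seed(14, {
    for (rep in 1:5) {
      cfg <- randomDetConfig(5)
      out <- runDetConfig(cfg, tExp = 30)
      fk <- forkRecords(out)
      expect_equal(sort(trackLengths(extractTracks(out))),
                   mergedLengths(pmin(fk$xStart, fk$xEnd),
                                 pmax(fk$xStart, fk$xEnd)),
                   tolerance = 1e-6)
    }
  })
})

test_that("closed-form per-fork moments follow the variance decomposition", {
  p <- replicationParams(muV = 1.5, varV = 0.9, varT = 9.7, tExp = 45)
  mo <- trackMoments(p, muT = 10)
  expect_equal(mo$muDt, 35)
  expect_equal(mo$muDx, 1.5 * 35)
  expect_equal(mo$varDx, 1.5^2 * 9.7 + 35^2 * 0.9)  # = 1124.325
  # constant-speed reduction: second term vanishes
  p0 <- replicationParams(muV = 1.5, varV = 0, varT = 9.7, tExp = 45)
  expect_equal(trackMoments(p0, 10)$varDx, 1.5^2 * 9.7)
  expect_error(trackMoments(p, muT = 50), "tExp")
})

test_that("Monte-Carlo per-fork variance matches the closed form", {
  # regime sigma_t*sigma_v << muDt*muV, truncation negligible
  p <- replicationParams(muV = 1.5, varV = 0.09, varT = 9.7, tExp = 45)
  d <- sampleForkDistances(p, muT = 10, n = 2e5, seed = 8)
  mo <- trackMoments(p, 10)
  expect_lt(abs(var(d, na.rm = TRUE) - mo$varDx) / mo$varDx, 0.02)
  expect_lt(abs(mean(d, na.rm = TRUE) - mo$muDx) / mo$muDx, 0.01)
})

test_that("histograms bin half-open, normalize, and filter short tracks", {
  h <- histogramTracks(trackSample(c(0.5, 0.7, 1.2)), minLength = 0)
  expect_equal(binStarts(h), c(0, 1))
  expect_equal(frequencies(h), c(2 / 3, 1 / 3))
  # detection limit drops short tracks before binning
  h2 <- histogramTracks(trackSample(c(0.5, 0.7, 1.2)), minLength = 1)
  expect_equal(frequencies(h2), 1)
  expect_error(histogramTracks(trackSample(0.5), minLength = 1), "empty")
  # any sample normalizes; mean within half a bin of the sample mean
  x <- withr::with_seed(3, rnorm(1e4, 40, 6))
  h3 <- histogramTracks(trackSample(x), minLength = 0)
  expect_equal(sum(frequencies(h3)), 1, tolerance = 1e-12)
  hmean <- sum((binStarts(h3) + 0.5) * frequencies(h3))
  expect_lt(abs(hmean - mean(x)), 0.5)
})

test_that("RSS distance matches a naive loop and its axioms", {
  h1 <- histogramTracks(trackSample(c(0.5)), minLength = 0)
  h2 <- histogramTracks(trackSample(c(1.5)), minLength = 0)
  expect_equal(rssDistance(h1, h1), 0)
  expect_equal(rssDistance(h1, h2), 2)  # disjoint unit masses
  withr::with_seed(5, {
    a <- histogramTracks(trackSample(rexp(300, 0.05) + 1), minLength = 0)
    b <- histogramTracks(trackSample(rexp(400, 0.03) + 1), minLength = 0)
    expect_equal(rssDistance(a, b), naiveRss(a, b))
    expect_equal(rssDistance(a, b), rssDistance(b, a))
  })
  h4 <- histogramTracks(trackSample(2.5), binWidth = 2, minLength = 0)
  expect_error(rssDistance(h1, h4), "bin width")
})

test_that("KS statistic equals the pooled-grid evaluation", {
  expect_equal(ksStatistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ksStatistic(c(1, 2), c(10, 20)), 1)
  withr::with_seed(6, {
    a <- rnorm(50, 30, 5); b <- rnorm(60, 33, 7)
    expect_equal(ksStatistic(a, b), naiveKs(a, b))
    expect_equal(ksStatistic(a, b),
                 unname(stats::ks.test(a, b)$statistic))
  })
  expect_error(ksStatistic(numeric(0), 1), "nonempty")
})

test_that("track variance grows with speed stochasticity at matched mean", {
  # single isolated origin: matched muDt, increasing varV
  m <- tinyMap(positions = 500, len = 1000, muT = 10)
  lens <- lapply(c(0, 0.3, 0.9), function(vv) {
    p <- replicationParams(muV = 1.5, varV = vv, varT = 9.7, tExp = 45)
    trackLengths(extractTracks(simulatePopulation(m, p, 1500, seed = 31)))
  })
  means <- vapply(lens, mean, numeric(1))
  vars <- vapply(lens, var, numeric(1))
  # positivity truncation lifts the realized mean slightly at high varV,
  # so "similar" means within 10% here while the variance clearly grows
  expect_lt(max(abs(means - means[1])) / means[1], 0.1)
  expect_true(all(diff(vars) > 0))
})

test_that("regressing track variance on muDt^2 recovers the decomposition", {
  # regime where the cross term varV*varT is negligible
  p0 <- replicationParams(muV = 1.5, varV = 0.09, varT = 4, tExp = 60)
  muTs <- c(5, 15, 25, 35)
  vars <- vapply(muTs, function(mt) {
    var(sampleForkDistances(p0, mt, 1e5, seed = 40 + mt), na.rm = TRUE)
  }, numeric(1))
  fit <- coef(lm(vars ~ I((60 - muTs)^2)))
  expect_lt(abs(fit[2] - 0.09) / 0.09, 0.1)          # slope ~ varV
  expect_lt(abs(fit[1] - 1.5^2 * 4) / (1.5^2 * 4), 0.1)  # intercept ~ muV^2 varT
})
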