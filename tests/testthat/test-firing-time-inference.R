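test_that("profile normalization is a single-factor rescale", {
  pr <- copyNumberProfile("chrI", 1:100, rep(2, 100))
  out <- normalizeProfile(pr, refEfficiency = 0.8, refSignal = 2)
  expect_equal(profileValues(out), rep(0.8, 100))
  # already calibrated: identity
  out2 <- normalizeProfile(out, refEfficiency = 0.8, refPosition = 50)
  expect_equal(profileValues(out2), profileValues(out))
  expect_error(normalizeProfile(pr, 0.8, refSignal = 0), "zero")
})

test_that("Savitzky-Golay smoothing reproduces polynomials exactly", {
  x <- seq(0, 50, by = 0.5)
  quad <- copyNumberProfile("chrI", x, 2 + 0.3 * x - 0.01 * x^2)
  sm <- smoothProfile(quad, window = 11, polyorder = 3)
  inner <- 6:(length(x) - 5)
  expect_equal(profileValues(sm)[inner], profileValues(quad)[inner],
               tolerance = 1e-9)
  # degenerate filter (polyorder = window - 1) interpolates exactly
  sm2 <- smoothProfile(quad, window = 5, polyorder = 4)
  expect_equal(profileValues(sm2), profileValues(quad), tolerance = 1e-9)
  expect_error(smoothProfile(quad, window = 4, polyorder = 3), "odd")
  expect_error(smoothProfile(quad, window = 3, polyorder = 3), "polyorder")
})

test_that("smoothed argmax recovers a noisy peak position", {
  x <- seq(0, 200, by = 1)
  bump <- 1.5 * exp(-(x - 88)^2 / (2 * 8^2))
  noisy <- withr::with_seed(2, bump + rnorm(length(x), 0, 0.3 / 5))  # SNR 5
  sm <- smoothProfile(copyNumberProfile("chrI", x, noisy))
  expect_lt(abs(x[which.max(profileValues(sm))] - 88), 2)
})

test_that("Gaussian flank fit recovers the per-fork distance density", {
  # exact Gaussian survival flanks around an origin at 100
  x <- seq(50, 150, by = 0.5)
  muDx <- 20; sdDx <- 5
  cov <- 0.9 * stats::pnorm(abs(x - 100), muDx, sdDx, lower.tail = FALSE)
  fit <- fitTrackPdf(copyNumberProfile("chrI", x, cov), center = 100)
  expect_true(fit@ok)
  expect_equal(fit@muDx, muDx, tolerance = 1e-3)
  expect_equal(fit@sigmaDx, sdDx, tolerance = 1e-2)
  # noisy version, smoothed as in the pipeline, replicated: mean within 5%
  mus <- withr::with_seed(4, vapply(1:10, function(i) {
    noisy <- cov * (1 + rnorm(length(cov), 0, 0.05))
    sm <- smoothProfile(copyNumberProfile("chrI", x, noisy))
    fitTrackPdf(sm, center = 100)@muDx
  }, numeric(1)))
  expect_lt(abs(mean(mus) - muDx) / muDx, 0.05)
  # flat segment: flagged, no estimate
  flat <- fitTrackPdf(copyNumberProfile("chrI", x, rep(1, length(x))))
  expect_false(flat@ok)
  expect_true(is.na(flat@muDx))
})

test_that("firing-time inversion follows muT = tExp - muDx/muV", {
  expect_equal(meanFiringTime(52, 2.4, 0.12), 32)
  expect_equal(meanFiringTime(30, 0, 1.5), 30)     # unfired-origin limit
  expect_warning(mt <- meanFiringTime(10, 30, 1.5), "clamped")
  expect_equal(mt, 0)
  expect_error(meanFiringTime(30, 5, 0), "muV")
  expect_error(meanFiringTime(30, -1, 1.5), "muDx")
})

test_that("single-origin round trip recovers the firing time", {
  # simulate one isolated origin, measure mean per-fork distance, invert
  m <- tinyMap(positions = 500, len = 1000, muT = 12)
  p <- replicationParams(muV = 1.5, varV = 0.2, varT = 4, tExp = 30)
  ens <- simulatePopulation(m, p, 3000, seed = 17)
  fk <- do.call(rbind, lapply(cells(ens), forkRecords))
  free <- is.na(fk$term)  # unobstructed at the horizon
  muDx <- mean(abs(fk$xEnd - fk$xStart)[free])
  expect_lt(abs(meanFiringTime(30, muDx, 1.5) - 12), 1)
})

test_that("full pipeline recovers generating firing times from profiles", {
  spec <- syntheticSpec(nChromosomes = 1, genomeLength = 2000, nOrigins = 20,
                        spacingJitter = 0.25, firingTimeRange = c(10, 24),
                        params = replicationParams(muV = 1.5, varV = 0.2,
                                                   varT = 4, tExp = 28),
                        profileNoiseSd = 0.01, seed = 21)
  cn <- makeCopyNumberData(spec, tObs = 28, nCells = 300)
  cal <- cn$truth$calibration
  res <- inferFiringTimes(cn$profile, positions(cn$truth$map), tExp = 28,
                          muV = 1.5, refEfficiency = cal$efficiency,
                          refPosition = cal$position)
  truth <- meanFiringTimes(cn$truth$map)
  ok <- res$fit_ok
  expect_gt(mean(ok), 0.8)
  expect_gt(cor(truth[ok], res$mu_t_min[ok]), 0.9)
  early <- ok & truth <= median(truth)
  expect_lt(abs(mean(res$mu_t_min[early] - truth[early])), 2)
})
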