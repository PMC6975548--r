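test_that("competence assignment respects the [efficiency, 1] interval", {
  m <- originMap("chrI", c(10, 50, 90), c(1, 0, 0.6), c(5, 10, 15),
                 c(chrI = 200))
  a <- assignCompetences(m, seed = 3)
  expect_equal(competences(a)[1], 1)                # degenerate interval
  expect_true(all(competences(a) >= efficiencies(a)))
  expect_true(all(competences(a) <= 1))
  # reproducible under the seed, resampled under a different one
  expect_identical(competences(assignCompetences(m, seed = 3)),
                   competences(a))
  expect_false(identical(
    competences(assignCompetences(m, seed = 4)), competences(a)))
  # already assigned: held fixed unless resampling is requested
  expect_identical(competences(assignCompetences(a, seed = 99)),
                   competences(a))
})

test_that("competence of a fully inefficient origin is uniform on [0,1]", {
  m <- originMap("chrI", seq_len(1e5) * 0.001, rep(0, 1e5), rep(1, 1e5),
                 c(chrI = 200))
  comp <- competences(assignCompetences(m, seed = 11))
  mcse <- 1 / sqrt(12 * 1e5)
  expect_lt(abs(mean(comp) - 0.5), 3 * mcse)
})

test_that("origin table round-trips through the writer", {
  spec <- syntheticSpec(nChromosomes = 4, genomeLength = 3000,
                        nOrigins = 100, seed = 5)
  map <- makeOriginMap(spec)
  tf <- tempfile(fileext = ".tsv"); cf <- tempfile(fileext = ".tsv")
  writeOriginMap(map, tf, cf)
  back <- loadOriginMap(tf, cf)
  expect_equal(chroms(back), chroms(map))
  expect_equal(positions(back), positions(map))
  expect_equal(efficiencies(back), efficiencies(map))
  expect_equal(meanFiringTimes(back), meanFiringTimes(map))
  expect_equal(chromLengths(back), chromLengths(map))
  expect_equal(length(back), 100)
})

test_that("origin table validation rejects malformed input", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition_kb\tefficiency\tmean_firing_time_min",
               "chrI\t10\t0.5\t5", "chrI\t10\t0.7\t8"), tf)
  expect_error(loadOriginMap(tf, c(chrI = 100)), "duplicate")
  writeLines(c("chrom\tposition_kb\tefficiency\tmean_firing_time_min",
               "chrI\t10\tnot_a_number\t5"), tf)
  expect_error(loadOriginMap(tf, c(chrI = 100)), "line 2")
  # unsorted input is silently sorted
  writeLines(c("chrom\tposition_kb\tefficiency\tmean_firing_time_min",
               "chrI\t90\t0.5\t5", "chrI\t10\t0.7\t8"), tf)
  expect_equal(positions(loadOriginMap(tf, c(chrI = 100))), c(10, 90))
})

test_that("origin map invariants are enforced", {
  expect_error(originMap("chrI", 10, 1.2, 5, c(chrI = 100)), "efficiency")
  expect_error(originMap("chrI", 150, 0.5, 5, c(chrI = 100)), "outside")
  expect_error(originMap("chrI", 10, 0.5, -2, c(chrI = 100)), "firing")
  m <- originMap("chrI", 10, 0.5, 5, c(chrI = 100))
  expect_error(competences(m) <- 0.2, "competence")  # below efficiency
})
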