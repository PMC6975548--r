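Package: replifork
Title: Stochastic-Speed Simulation of DNA Replication Kinetics in Budding Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide Monte-Carlo simulation of S. cerevisiae DNA
    replication in which every replication fork is assigned its own constant
    speed drawn from a Gaussian distribution, together with the closed-form
    moment theory for the resulting DNA-track (combing fiber) length
    distributions, genetic-algorithm fitting of the global kinetic parameters
    against track-length histograms, inference of per-origin mean firing
    times from BrdU copy-number profiles, population-level replication-timing
    analytics, and a distance-to-approaching-fork speed modifier that
    promotes timely completion of replication. Includes a synthetic-data
    generator producing yeast-like origin maps, combing-like track samples
    and copy-number profiles for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
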