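# Shared fixtures: small deterministic maps and programs built in code.

tinyMap <- function(positions = c(100, 250, 400), eff = 1, muT = 0,
                    len = 500, chrom = "chrI") {
  m <- originMap(chrom = chrom, position = positions,
                 efficiency = rep_len(eff, length(positions)),
                 muT = rep_len(muT, length(positions)),
                 chromLengths = setNames(len, chrom))
  assignCompetences(m, seed = 1)
}

detParams <- function(muV = 1.5, tExp = 30, ...) {
  replicationParams(muV = muV, varV = 0, varT = 0, tExp = tExp, ...)
}

# explicit deterministic program (all licensed, no termination)
detProgram <- function(t0, vL, vR, licensed = TRUE) {
  n <- length(t0)
  new("CellProgram", licensed = rep_len(licensed, n), t0 = as.numeric(t0),
      vLeft = as.numeric(vL), vRight = as.numeric(vR),
      lifeLeft = rep(Inf, n), lifeRight = rep(Inf, n))
}

# random deterministic single-chromosome configuration
randomDetConfig <- function(nOrigins, len = 500) {
  x <- sort(runif(nOrigins, 5, len - 5))
  while (any(diff(x) < 2)) x <- sort(runif(nOrigins, 5, len - 5))
  list(x = x, t0 = runif(nOrigins, 0, 25),
       vL = runif(nOrigins, 0.3, 3), vR = runif(nOrigins, 0.3, 3),
       len = len)
}

runDetConfig <- function(cfg, tExp, dt = 0.1, until = "tExp") {
  m <- originMap("c", cfg$x, rep(1, length(cfg$x)), rep(0, length(cfg$x)),
                 c(c = cfg$len))
  competences(m) <- 1
  replicateCell(detProgram(cfg$t0, cfg$vL, cfg$vR), m,
                detParams(tExp = tExp), until = until, dt = dt,
                horizon = 5000)
}
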