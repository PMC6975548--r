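# Origin-map construction, licensing-competence assignment, and the origin
# table reader/writer. Coordinates are 0-based kilobases with half-open
# [start, end) segment semantics; chromosome ends absorb forks.

#' Assign licensing competences to an origin map
#'
#' Each origin's competence -- the a-priori probability that the origin is
#' licensed in G1 and therefore able to fire -- is drawn uniformly from
#' [measured efficiency, 1]. The draw is made once per condition and then
#' shared by all simulated cells of that condition; per-cell licensing is a
#' Bernoulli(competence) draw inside the simulator. Set
#' \code{resample = TRUE} to force a fresh draw on a map whose competences
#' are already assigned.
#'
#' @param map an \linkS4class{OriginMap}.
#' @param seed integer seed; the assignment is reproducible given the seed.
#' @param resample redraw even when competences are already assigned.
#' @return The map with the \code{competences} slot filled.
#' @examples
#' m <- originMap("chrI", c(30, 70), c(0.8, 0.6), c(10, 20),
#'                c(chrI = 230))
#' competences(assignCompetences(m, seed = 1))
#' @export
assignCompetences <- function(map, seed = 1, resample = FALSE) {
  stopifnot(is(map, "OriginMap"))
  if (!resample && !anyNA(competences(map))) return(map)
  eff <- efficiencies(map)
  bad <- which(eff < 0 | eff > 1)
  if (length(bad))
    stop(sprintf("efficiency outside [0,1] for origin %s:%g",
                 chroms(map)[bad[1]], positions(map)[bad[1]]))
  comp <- withSeed(seed, eff + runif(length(eff)) * (1 - eff))
  competences(map) <- comp
  map
}

#' Read an origin table
#'
#' Reads a tab-separated origin table with header columns \code{chrom},
#' \code{position_kb}, \code{efficiency}, \code{mean_firing_time_min},
#' together with a two-column chromosome-size table (\code{name},
#' \code{length_kb}). Unsorted rows are silently sorted; duplicate positions
#' on a chromosome are an error.
#'
#' @param path origin table (TSV with header).
#' @param chromLengths either a named numeric vector of chromosome lengths
#'   (kb) or the path to a two-column TSV (name, length_kb).
#' @return An \linkS4class{OriginMap}.
#' @seealso \code{\link{writeOriginMap}}
#' @export
loadOriginMap <- function(path, chromLengths) {
  if (is.character(chromLengths) && length(chromLengths) == 1 &&
      file.exists(chromLengths)) {
    cl <- read.table(chromLengths, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (ncol(cl) < 2)
      stop("chromosome-size file must have columns name, length_kb")
    chromLengths <- setNames(as.numeric(cl[[2]]), as.character(cl[[1]]))
  }
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse origin table '", path, "': ",
                             conditionMessage(e)))
  need <- c("chrom", "position_kb", "efficiency", "mean_firing_time_min")
  if (!all(need %in% names(tab)))
    stop("origin table must have columns: ", paste(need, collapse = ", "))
  for (col in need[-1]) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      ln <- which(is.na(v))[1] + 1L  # +1 for the header line
      stop(sprintf("malformed numeric value in column '%s' at line %d of %s",
                   col, ln, path))
    }
    tab[[col]] <- v
  }
  dup <- duplicated(tab[c("chrom", "position_kb")])
  if (any(dup))
    stop(sprintf("duplicate origin position %s:%g in %s",
                 tab$chrom[dup][1], tab$position_kb[dup][1], path))
  originMap(chrom = tab$chrom, position = tab$position_kb,
            efficiency = tab$efficiency, muT = tab$mean_firing_time_min,
            chromLengths = chromLengths)
}

#' Write an origin table
#'
#' @param map an \linkS4class{OriginMap}.
#' @param path output TSV path.
#' @param chromLengthsPath optional path for the companion chromosome-size
#'   TSV.
#' @return Invisibly, \code{path}.
#' @export
writeOriginMap <- function(map, path, chromLengthsPath = NULL) {
  tab <- data.frame(chrom = chroms(map), position_kb = positions(map),
                    efficiency = efficiencies(map),
                    mean_firing_time_min = meanFiringTimes(map))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(chromLengthsPath)) {
    cl <- data.frame(name = names(chromLengths(map)),
                     length_kb = as.numeric(chromLengths(map)))
    write.table(cl, chromLengthsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
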