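# Readers/writers: plain-text track lists (one kb value per line), bedGraph
# copy-number tracks (bp coordinates on disk, kb midpoints in memory),
# histogram TSVs, and JSON parameter files.

#' Read a plain-text track list
#'
#' One numeric track length (kb) per line; blank lines are ignored.
#'
#' @param path input path.
#' @param label label for the returned sample.
#' @return A \linkS4class{TrackSample}.
#' @export
readTrackList <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty track list: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    ln <- which(is.na(vals))[1]
    stop(sprintf("non-numeric track length at line %d of %s", ln, path))
  }
  trackSample(vals, label = label)
}

#' Write a plain-text track list
#' @param sample \linkS4class{TrackSample} or numeric vector (kb).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeTrackList <- function(sample, path) {
  len <- if (is(sample, "TrackSample")) trackLengths(sample) else
    as.numeric(sample)
  writeLines(format(len, trim = TRUE, scientific = FALSE, digits = 15), path)
  invisible(path)
}

#' Read a bedGraph file into a copy-number profile
#'
#' Four columns (chrom, start, end, value), bp coordinates; intervals are
#' converted to kb midpoints. Out-of-order intervals are sorted with a
#' warning; overlapping intervals are an error.
#'
#' @param path bedGraph path.
#' @param chrom optional chromosome to extract; defaults to the first seen.
#' @return A \linkS4class{CopyNumberProfile}.
#' @export
readBedGraph <- function(path, chrom = NULL) {
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("bedGraph must have 4 columns: ", path)
  names(tab)[1:4] <- c("chrom", "start", "end", "value")
  if (is.null(chrom)) chrom <- tab$chrom[1]
  tab <- tab[tab$chrom == chrom, , drop = FALSE]
  if (nrow(tab) == 0) stop("no intervals for chromosome ", chrom)
  if (is.unsorted(tab$start)) {
    warning("out-of-order bedGraph intervals sorted")
    tab <- tab[order(tab$start), , drop = FALSE]
  }
  if (any(tab$start[-1] < tab$end[-nrow(tab)]))
    stop("overlapping bedGraph intervals on ", chrom)
  copyNumberProfile(chrom, (tab$start + tab$end) / 2 / 1000, tab$value)
}

#' Write a copy-number profile as bedGraph
#'
#' Positions (kb midpoints) are emitted as adjacent bp intervals centered on
#' each midpoint (integer bp, x1000).
#'
#' @param profile \linkS4class{CopyNumberProfile}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBedGraph <- function(profile, path) {
  pos <- positions(profile) * 1000
  gaps <- diff(pos)
  half <- c(gaps[1], gaps) / 2
  halfr <- c(gaps, gaps[length(gaps)]) / 2
  if (length(pos) == 1) half <- halfr <- 500
  tab <- data.frame(chrom = chroms(profile),
                    start = as.integer(round(pos - half)),
                    end = as.integer(round(pos + halfr)),
                    value = profileValues(profile))
  tab$start <- pmax(tab$start, 0L)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a track histogram as TSV
#' @param hist \linkS4class{TrackHistogram}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeHistogram <- function(hist, path) {
  write.table(data.frame(bin_start_kb = binStarts(hist),
                         frequency = frequencies(hist)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write replication parameters as JSON
#'
#' @param path JSON path.
#' @return \code{readParams}: a \linkS4class{ReplicationParams}.
#' @export
readParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mod <- NULL
  if (!is.null(x$modifier))
    mod <- speedModifierConfig(
      capFactor = x$modifier$capFactor %||% 1.9,
      rampScale = x$modifier$rampScale %||% 100,
      calibrateMean = x$modifier$calibrateMean %||% TRUE,
      reevalPerStep = x$modifier$reevalPerStep %||% FALSE)
  replicationParams(muV = x$muV, varV = x$varV, varT = x$varT,
                    tExp = x$tExp, pEnd = x$pEnd %||% 0, modifier = mod)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readParams
#' @param params \linkS4class{ReplicationParams} to serialize.
#' @export
writeParams <- function(params, path) {
  x <- list(muV = params@muV, varV = params@varV, varT = params@varT,
            tExp = params@tExp, pEnd = params@pEnd)
  if (!is.null(params@modifier))
    x$modifier <- list(capFactor = params@modifier@capFactor,
                       rampScale = params@modifier@rampScale,
                       calibrateMean = params@modifier@calibrateMean,
                       reevalPerStep = params@modifier@reevalPerStep)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
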