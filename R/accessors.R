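#' @name accessors
#' @title Accessors for replifork classes
#' @description Accessor generics for the core data containers. Slot access
#'   via \code{@} is discouraged; use these instead.
#' @param x an object.
#' @param value replacement value.
#' @return The corresponding slot content.
NULL

#' @rdname accessors
#' @export
setGeneric("chroms", function(x) standardGeneric("chroms"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("efficiencies", function(x) standardGeneric("efficiencies"))
#' @rdname accessors
#' @export
setGeneric("competences", function(x) standardGeneric("competences"))
#' @rdname accessors
#' @export
setGeneric("competences<-", function(x, value) standardGeneric("competences<-"))
#' @rdname accessors
#' @export
setGeneric("meanFiringTimes", function(x) standardGeneric("meanFiringTimes"))
#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("originStatus", function(x) standardGeneric("originStatus"))
#' @rdname accessors
#' @export
setGeneric("forkRecords", function(x) standardGeneric("forkRecords"))
#' @rdname accessors
#' @export
setGeneric("completionTime", function(x) standardGeneric("completionTime"))
#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname accessors
#' @export
setGeneric("originMapOf", function(x) standardGeneric("originMapOf"))
#' @rdname accessors
#' @export
setGeneric("replicationParamsOf", function(x) standardGeneric("replicationParamsOf"))
#' @rdname accessors
#' @export
setGeneric("trackLengths", function(x) standardGeneric("trackLengths"))
#' @rdname accessors
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
setMethod("chroms", "OriginMap", function(x) x@chrom)
#' @rdname accessors
setMethod("positions", "OriginMap", function(x) x@position)
#' @rdname accessors
setMethod("efficiencies", "OriginMap", function(x) x@efficiency)
#' @rdname accessors
setMethod("competences", "OriginMap", function(x) x@competence)
#' @rdname accessors
setMethod("competences<-", "OriginMap", function(x, value) {
  x@competence <- rep_len(as.numeric(value), length(x@position))
  validObject(x)
  x
})
#' @rdname accessors
setMethod("meanFiringTimes", "OriginMap", function(x) x@muT)
#' @rdname accessors
setMethod("chromLengths", "OriginMap", function(x) x@chromLengths)

#' @rdname accessors
setMethod("segments", "CellOutcome", function(x) x@segments)
#' @rdname accessors
setMethod("originStatus", "CellOutcome", function(x) x@originStatus)
#' @rdname accessors
setMethod("forkRecords", "CellOutcome", function(x) x@forks)
#' @rdname accessors
setMethod("completionTime", "CellOutcome", function(x) x@completionTime)

#' @rdname accessors
setMethod("cells", "PopulationEnsemble", function(x) x@cells)
#' @rdname accessors
setMethod("originMapOf", "PopulationEnsemble", function(x) x@originMap)
#' @rdname accessors
setMethod("replicationParamsOf", "PopulationEnsemble", function(x) x@params)
#' @rdname accessors
setMethod("completionTime", "PopulationEnsemble",
          function(x) vapply(x@cells, completionTime, numeric(1)))

#' @rdname accessors
setMethod("trackLengths", "TrackSample", function(x) x@lengths)
#' @rdname accessors
setMethod("binStarts", "TrackHistogram", function(x) x@binStart)
#' @rdname accessors
setMethod("frequencies", "TrackHistogram", function(x) x@frequency)
#' @rdname accessors
setMethod("binWidth", "TrackHistogram", function(x) x@binWidth)

#' @rdname accessors
setMethod("chroms", "CopyNumberProfile", function(x) x@chrom)
#' @rdname accessors
setMethod("positions", "CopyNumberProfile", function(x) x@position)
#' @rdname accessors
setMethod("profileValues", "CopyNumberProfile", function(x) x@value)
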