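#' Accessors for poreflux S4 classes
#'
#' `peaks()` returns the peak table of a [PeakList-class]; `nPeaks()` its
#' number of rows; `sampleId()` and `polarity()` its metadata;
#' `seriesData()` the time/concentration table of a
#' [HeadspaceSeries-class]; `coreId()` its core label; `rewetEnd()` the
#' end of the rewetting phase in seconds; `schemeBoxes()` and
#' `schemePrecedence()` the box table and precedence of a
#' [ClassScheme-class].
#'
#' @param x the object.
#' @return The slot contents (a data.frame, character or numeric scalar).
#' @examples
#' pl <- PeakList(mz = 255.233, intensity = 1, snr = 10)
#' peaks(pl); nPeaks(pl); polarity(pl)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setMethod("peaks", "PeakList", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))
#' @rdname accessors
#' @export
setMethod("nPeaks", "PeakList", function(x) nrow(x@peaks))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "PeakList", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))
#' @rdname accessors
#' @export
setMethod("polarity", "PeakList", function(x) x@polarity)

#' @rdname accessors
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setMethod("seriesData", "HeadspaceSeries", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("coreId", function(x) standardGeneric("coreId"))
#' @rdname accessors
#' @export
setMethod("coreId", "HeadspaceSeries", function(x) x@coreId)

#' @rdname accessors
#' @export
setGeneric("rewetEnd", function(x) standardGeneric("rewetEnd"))
#' @rdname accessors
#' @export
setMethod("rewetEnd", "HeadspaceSeries", function(x) x@rewetEnd_s)

#' @rdname accessors
#' @export
setGeneric("schemeBoxes", function(x) standardGeneric("schemeBoxes"))
#' @rdname accessors
#' @export
setMethod("schemeBoxes", "ClassScheme", function(x) x@boxes)

#' @rdname accessors
#' @export
setGeneric("schemePrecedence", function(x) standardGeneric("schemePrecedence"))
#' @rdname accessors
#' @export
setMethod("schemePrecedence", "ClassScheme", function(x) x@precedence)

setMethod("show", "PeakList", function(object) {
  p <- object@peaks
  cat(sprintf("PeakList '%s' (%s mode): %d peaks",
              object@sampleId, object@polarity, nrow(p)))
  if (nrow(p))
    cat(sprintf(", m/z %.4f-%.4f", min(p$mz), max(p$mz)))
  cat("\n")
})

setMethod("show", "ClassScheme", function(object) {
  cat(sprintf("ClassScheme: %d boxes, precedence %s\n",
              nrow(object@boxes),
              paste(object@precedence, collapse = " > ")))
})

setMethod("show", "ChamberSpec", function(object) {
  cat(sprintf(
    "ChamberSpec: V=%g cm3, M=%g g, Pa=%g kPa, T=%g K, R=%g cm3 kPa/mol/K\n",
    object@V, object@M, object@Pa, object@T, object@R))
})

setMethod("show", "HeadspaceSeries", function(object) {
  d <- object@data
  cat(sprintf(
    "HeadspaceSeries '%s': %d points over %.1f min (rewetting ends %.0f min)\n",
    object@coreId, nrow(d),
    if (nrow(d)) diff(range(d$time_s)) / 60 else 0,
    object@rewetEnd_s / 60))
})
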