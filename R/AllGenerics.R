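#' Accessors for EEG containers
#'
#' `nSamples()`, `nChannels()`, `channelLabels()`, `samplingRate()`,
#' `subjectId()` and `classLabel()` read the corresponding properties of an
#' [EEGRecord-class] (and, where meaningful, of an
#' [SWTDecomposition-class]).
#'
#' @param x an `EEGRecord` or `SWTDecomposition`.
#' @return the requested property.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname detailMatrix
#' @export
setGeneric("detailMatrix",
  function(x, level, trim = TRUE) standardGeneric("detailMatrix"))

#' @rdname detailMatrix
#' @export
setGeneric("approximationMatrix",
  function(x, trim = TRUE) standardGeneric("approximationMatrix"))
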