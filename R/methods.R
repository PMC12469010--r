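#' @describeIn accessors sample count of a record
#' @export
setMethod("nSamples", "EEGRecord", function(x) nrow(x@data))

#' @describeIn accessors channel count of a record
#' @export
setMethod("nChannels", "EEGRecord", function(x) ncol(x@data))

#' @describeIn accessors channel labels of a record
#' @export
setMethod("channelLabels", "EEGRecord", function(x) x@channelLabels)

#' @describeIn accessors sampling rate of a record
#' @export
setMethod("samplingRate", "EEGRecord", function(x) x@fs)

#' @describeIn accessors subject identifier
#' @export
setMethod("subjectId", "EEGRecord", function(x) x@subjectId)

#' @describeIn accessors diagnostic class label
#' @export
setMethod("classLabel", "EEGRecord", function(x) x@classLabel)

#' @describeIn accessors original (untrimmed) sample count of a decomposition
#' @export
setMethod("nSamples", "SWTDecomposition", function(x) x@originalLength)

#' @describeIn accessors channel count of a decomposition
#' @export
setMethod("nChannels", "SWTDecomposition",
  function(x) ncol(x@approximation))

#' @describeIn accessors channel labels of a decomposition
#' @export
setMethod("channelLabels", "SWTDecomposition", function(x) x@channelLabels)

#' @describeIn accessors source sampling rate of a decomposition
#' @export
setMethod("samplingRate", "SWTDecomposition", function(x) x@sourceFs)

#' Coefficient matrices of a stationary wavelet decomposition
#'
#' `detailMatrix()` returns the level-`level` detail coefficients and
#' `approximationMatrix()` the level-J approximation. With `trim = TRUE`
#' (default) the original-length slice is returned, i.e. padding introduced
#' by the length policy is removed.
#'
#' @param x an [SWTDecomposition-class].
#' @param level decomposition level, `1..levels`.
#' @param trim drop the zero-padding margin?
#' @return numeric matrix, samples x channels.
#' @export
#' @name detailMatrix
setMethod("detailMatrix", "SWTDecomposition",
  function(x, level, trim = TRUE) {
    level <- as.integer(level)
    if (length(level) != 1L || is.na(level) || level < 1L ||
        level > x@levels)
      stop("level must be a single integer in 1..", x@levels)
    m <- x@details[[level]]
    if (trim) m <- m[x@padLeft + seq_len(x@originalLength), , drop = FALSE]
    m
  })

#' @rdname detailMatrix
#' @export
setMethod("approximationMatrix", "SWTDecomposition",
  function(x, trim = TRUE) {
    m <- x@approximation
    if (trim) m <- m[x@padLeft + seq_len(x@originalLength), , drop = FALSE]
    m
  })

setMethod("show", "EEGRecord", function(object) {
  cat(sprintf(
    "EEGRecord '%s' [%s]: %d samples x %d channels @ %g Hz (%.2f s)\n",
    object@subjectId, object@classLabel, nrow(object@data),
    ncol(object@data), object@fs, nrow(object@data) / object@fs))
  cat("channels:", paste(object@channelLabels, collapse = " "), "\n")
})

setMethod("show", "SWTDecomposition", function(object) {
  cat(sprintf(
    "SWTDecomposition (%s, periodic): J = %d, %d samples (+%d pad) x %d channels @ %g Hz\n",
    object@wavelet, object@levels, object@originalLength,
    nrow(object@approximation) - object@originalLength,
    ncol(object@approximation), object@sourceFs))
})

setMethod("show", "ThresholdSpec", function(object) {
  cat(sprintf("ThresholdSpec: rule = %s, sigma = %s%s\n",
    object@rule, object@sigmaEstimator,
    if (length(object@lambdas))
      paste0(", fixed lambdas at levels ",
             paste(names(object@lambdas), collapse = ","))
    else ""))
})

setMethod("show", "SubbandFeatures", function(object) {
  cat(sprintf(
    "SubbandFeatures level %d (%s, %s): %d rows x %d channels, %d subjects\n",
    object@level, object@band, object@representation, nrow(object@X),
    ncol(object@X), length(unique(object@subject))))
})

setMethod("show", "FLDAModel", function(object) {
  cat(sprintf(
    "FLDAModel: %d feature(s) -> %d component(s); classes %s (positive = %s)\n",
    nrow(object@W), ncol(object@W),
    paste(object@classLevels, collapse = "/"),
    object@classOrder[["positive"]]))
  if (!is.na(object@threshold))
    cat(sprintf("decision threshold (midpoint, equal priors): %.6g\n",
                object@threshold))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d+%d subjects, %d channels, %g Hz x %.4g s (%d samples), seed %d\n",
    object@nSubjectsPerClass, object@nSubjectsPerClass, object@nChannels,
    object@fs, object@durationS, as.integer(round(object@fs * object@durationS)),
    object@seed))
  print(object@bandAmplitudes)
})
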