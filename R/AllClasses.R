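#' @import methods
NULL

EEG_CLASS_LEVELS <- c("NORMAL", "ASD")

#' EEGRecord: one subject's multi-channel EEG
#'
#' Container for a single subject's EEG matrix (rows = time samples,
#' columns = channels) together with the metadata the pipeline needs:
#' subject identifier, diagnostic class, sampling rate and 10-20 channel
#' labels.
#'
#' @slot subjectId single character, unique within a cohort.
#' @slot classLabel `"ASD"` or `"NORMAL"`.
#' @slot fs sampling rate in Hz (positive).
#' @slot channelLabels ordered, unique channel names; length equals
#'   `ncol(data)`.
#' @slot data numeric matrix, samples x channels, all values finite.
#'
#' @seealso [readSignal()], [dropChannels()], [simulateSubject()]
#' @export
setClass("EEGRecord",
  representation(
    subjectId     = "character",
    classLabel    = "character",
    fs            = "numeric",
    channelLabels = "character",
    data          = "matrix"
  )
)

setValidity("EEGRecord", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-empty string")
  if (length(object@classLabel) != 1L ||
      !object@classLabel %in% EEG_CLASS_LEVELS)
    msg <- c(msg, "classLabel must be one of 'ASD', 'NORMAL'")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (ncol(object@data) != length(object@channelLabels))
    msg <- c(msg, "length(channelLabels) must equal ncol(data)")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channelLabels must be unique")
  if (nrow(object@data) < 1L)
    msg <- c(msg, "data must have at least one sample")
  if (!is.numeric(object@data) || anyNA(object@data) ||
      any(!is.finite(object@data)))
    msg <- c(msg, "data must be numeric and finite")
  if (length(msg)) msg else TRUE
})

#' WaveletFilterBank: orthonormal two-channel filter bank
#'
#' Decomposition and reconstruction low/high-pass filters of an orthonormal
#' wavelet in the sqrt(2)-normalized convention (`sum(decLo) == sqrt(2)`).
#'
#' @slot name filter family name, e.g. `"db4"`.
#' @slot decLo,decHi decomposition low/high-pass coefficients.
#' @slot recLo,recHi reconstruction counterparts.
#' @slot nVanishingMoments number of vanishing moments of the high-pass.
#'
#' @seealso [db4Filters()]
#' @export
setClass("WaveletFilterBank",
  representation(
    name  = "character",
    decLo = "numeric",
    decHi = "numeric",
    recLo = "numeric",
    recHi = "numeric",
    nVanishingMoments = "integer"
  )
)

setValidity("WaveletFilterBank", function(object) {
  msg <- character()
  tol <- 1e-10
  if (abs(sum(object@decLo) - sqrt(2)) > tol)
    msg <- c(msg, "sum(decLo) must be sqrt(2)")
  if (abs(sum(object@decHi)) > tol)
    msg <- c(msg, "sum(decHi) must be 0")
  if (abs(sum(object@decLo^2) - 1) > tol || abs(sum(object@decHi^2) - 1) > tol)
    msg <- c(msg, "filters must be orthonormal (unit energy)")
  L <- length(object@decLo)
  qmf <- (-1)^(seq_len(L) - 1L) * rev(object@decLo)
  if (max(abs(abs(qmf) - abs(object@decHi))) > tol)
    msg <- c(msg, "decHi must be the quadrature mirror of decLo")
  if (length(msg)) msg else TRUE
})

#' SWTDecomposition: undecimated wavelet coefficients
#'
#' Result of [swtDecompose()]. Coefficient matrices are stored at the padded
#' length (a multiple of `2^levels`); accessors return the original-length
#' slice by default.
#'
#' @slot levels number of decomposition levels J.
#' @slot details list of J numeric matrices (padded samples x channels);
#'   element j holds the level-j detail coefficients (dyadic scale `2^j`).
#' @slot approximation level-J approximation matrix, same shape.
#' @slot boundaryMode boundary handling; always `"periodic"`.
#' @slot sourceFs sampling rate of the decomposed record, Hz.
#' @slot wavelet filter-bank name used.
#' @slot originalLength sample count before padding.
#' @slot padLeft number of zero samples prepended by the padding policy.
#' @slot channelLabels channel names carried from the source record.
#'
#' @seealso [swtDecompose()], [swtReconstruct()], [detailMatrix()]
#' @export
setClass("SWTDecomposition",
  representation(
    levels         = "integer",
    details        = "list",
    approximation  = "matrix",
    boundaryMode   = "character",
    sourceFs       = "numeric",
    wavelet        = "character",
    originalLength = "integer",
    padLeft        = "integer",
    channelLabels  = "character"
  )
)

setValidity("SWTDecomposition", function(object) {
  msg <- character()
  J <- object@levels
  if (J < 1L) msg <- c(msg, "levels must be >= 1")
  if (length(object@details) != J)
    msg <- c(msg, "details must hold one matrix per level")
  np <- nrow(object@approximation)
  if (np %% 2L^J != 0L)
    msg <- c(msg, "padded length must be a multiple of 2^levels")
  shapes <- vapply(object@details, function(d)
    identical(dim(d), dim(object@approximation)), logical(1))
  if (!all(shapes))
    msg <- c(msg, "all coefficient matrices must share the padded shape")
  if (!identical(object@boundaryMode, "periodic"))
    msg <- c(msg, "boundaryMode must be 'periodic'")
  if (object@originalLength < 1L || object@originalLength > np)
    msg <- c(msg, "originalLength must be in [1, padded length]")
  if (length(msg)) msg else TRUE
})

#' ThresholdSpec: wavelet-shrinkage rule and thresholds
#'
#' @slot rule `"soft"` (pipeline default) or `"hard"`.
#' @slot lambdas optional named numeric vector of fixed per-level thresholds
#'   (names are decomposition levels); empty means thresholds are derived
#'   from the data via `sigmaEstimator` and the universal rule.
#' @slot sigmaEstimator `"mad_level1"`, `"mad_per_level"` or `"fixed"`.
#' @slot fixedSigma noise scale used when `sigmaEstimator == "fixed"`.
#'
#' @seealso [thresholdSpec()], [denoise()]
#' @export
setClass("ThresholdSpec",
  representation(
    rule           = "character",
    lambdas        = "numeric",
    sigmaEstimator = "character",
    fixedSigma     = "numeric"
  )
)

setValidity("ThresholdSpec", function(object) {
  msg <- character()
  if (!object@rule %in% c("soft", "hard"))
    msg <- c(msg, "rule must be 'soft' or 'hard'")
  if (!object@sigmaEstimator %in% c("mad_level1", "mad_per_level", "fixed"))
    msg <- c(msg, "unknown sigmaEstimator")
  if (length(object@lambdas) && (is.null(names(object@lambdas)) ||
      any(object@lambdas < 0)))
    msg <- c(msg, "lambdas must be named and non-negative")
  if (object@sigmaEstimator == "fixed" &&
      (length(object@fixedSigma) != 1L || object@fixedSigma < 0))
    msg <- c(msg, "fixedSigma must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' NormalizationStats: train-fitted z-scoring statistics
#'
#' Per-column mean and population standard deviation (denominator n),
#' fitted on training rows only.
#'
#' @slot mean,sd per-column statistics; `sd` strictly positive.
#' @slot fittedOn number of rows the statistics were computed from.
#'
#' @seealso [zscoreFit()], [zscoreApply()]
#' @export
setClass("NormalizationStats",
  representation(mean = "numeric", sd = "numeric", fittedOn = "integer")
)

setValidity("NormalizationStats", function(object) {
  msg <- character()
  if (length(object@mean) != length(object@sd))
    msg <- c(msg, "mean and sd must have equal length")
  if (any(object@sd <= 0))
    msg <- c(msg, "all sd entries must be > 0")
  if (length(msg)) msg else TRUE
})

#' SubbandFeatures: per-level feature matrix
#'
#' One row per time sample; one column per channel. Rows carry the source
#' record's class label and subject identifier.
#'
#' @slot level reported decomposition level.
#' @slot band rhythm label: `"GAMMA"`, `"BETA"`, `"THETA"` or `"OTHER"`.
#' @slot X numeric feature matrix (rows x channels).
#' @slot y class label per row.
#' @slot subject subject identifier per row.
#' @slot representation `"magnitude"` (default) or `"raw"` coefficients.
#'
#' @seealso [extractFeatures()]
#' @export
setClass("SubbandFeatures",
  representation(
    level          = "integer",
    band           = "character",
    X              = "matrix",
    y              = "character",
    subject        = "character",
    representation = "character"
  )
)

setValidity("SubbandFeatures", function(object) {
  msg <- character()
  if (length(object@y) != nrow(object@X) ||
      length(object@subject) != nrow(object@X))
    msg <- c(msg, "y and subject must have one entry per row of X")
  if (!object@band %in% c("GAMMA", "BETA", "THETA", "OTHER"))
    msg <- c(msg, "invalid band label")
  if (length(msg)) msg else TRUE
})

#' FLDAModel: Fisher discriminant projection and linear decision rule
#'
#' @slot W projection matrix, features x components (<= C-1 components),
#'   unit-norm columns. Component 1 is oriented so the positive class
#'   (ASD) training mean projects at or above the negative class mean.
#' @slot classMeansProjected class means in discriminant space
#'   (classes x components).
#' @slot threshold scalar decision cut for the binary case: midpoint of the
#'   projected class means (equal priors); `NA` for more than two classes.
#' @slot classOrder named character: `negative` and `positive` class labels.
#' @slot classLevels all class labels seen at fit, in model order.
#' @slot normStats [NormalizationStats-class] applied before projection.
#' @slot ridge ridge coefficient used to stabilize the within-class scatter.
#'
#' @seealso [fldaFit()], [fldaProject()], [fldaPredict()]
#' @export
setClass("FLDAModel",
  representation(
    W                   = "matrix",
    classMeansProjected = "matrix",
    threshold           = "numeric",
    classOrder          = "character",
    classLevels         = "character",
    normStats           = "NormalizationStats",
    ridge               = "numeric"
  )
)

setValidity("FLDAModel", function(object) {
  msg <- character()
  C <- length(object@classLevels)
  if (ncol(object@W) > C - 1L)
    msg <- c(msg, "at most C-1 discriminant components are allowed")
  norms <- sqrt(colSums(object@W^2))
  if (any(abs(norms - 1) > 1e-8))
    msg <- c(msg, "columns of W must have unit Euclidean norm")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: synthetic two-class EEG cohort parameters
#'
#' Defines the simulated study conditions: cohort size, record geometry and
#' the planted class structure. Per band, each channel receives a sum of
#' `oscillatorsPerBand` sinusoids with frequencies drawn uniformly inside
#' the band and random phases, scaled so the band's total sinusoidal
#' variance is `amplitude^2 / 2`. A per-subject multiplicative gain
#' (shared across channels), a slow amplitude envelope for the ASD class
#' (emulating inconsistent fluctuations), 1/f pink noise and white noise
#' complete the signal.
#'
#' @slot nSubjectsPerClass subjects per class (default 8).
#' @slot fs sampling rate, Hz (default 256).
#' @slot durationS record duration in seconds; `fs * durationS` must be a
#'   whole number of samples (default 1000 samples at 256 Hz).
#' @slot nChannels channel count (default 15).
#' @slot channelLabels 10-20 labels for the channels.
#' @slot bandAmplitudes 3 x 2 matrix, rows `theta`, `beta`, `gamma`,
#'   columns `normal`, `asd`: sinusoidal amplitude (uV) per band and class.
#' @slot bandRanges 3 x 2 matrix of band edges in Hz (`lo`, `hi`).
#' @slot oscillatorsPerBand sinusoids summed per band per channel.
#' @slot subjectGainSd SD of the per-subject multiplicative gain.
#' @slot whiteSd white (broadband) noise SD, uV.
#' @slot pinkScale 1/f pink-noise SD, uV.
#' @slot asdEnvelopeDepth depth of the slow ASD amplitude envelope (0 = off).
#' @slot envelopeFreqRange frequency range (Hz) of the envelope oscillation.
#' @slot seed base seed; per-subject streams are derived deterministically.
#'
#' @seealso [cohortSpec()], [nullCohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nSubjectsPerClass = "integer",
    fs                = "numeric",
    durationS         = "numeric",
    nChannels         = "integer",
    channelLabels     = "character",
    bandAmplitudes    = "matrix",
    bandRanges        = "matrix",
    oscillatorsPerBand = "integer",
    subjectGainSd     = "numeric",
    whiteSd           = "numeric",
    pinkScale         = "numeric",
    asdEnvelopeDepth  = "numeric",
    envelopeFreqRange = "numeric",
    seed              = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  n <- object@fs * object@durationS
  if (abs(n - round(n)) > 1e-9 || round(n) < 64)
    msg <- c(msg, "fs * durationS must be an integer sample count >= 64")
  if (any(object@bandAmplitudes < 0))
    msg <- c(msg, "band amplitudes must be non-negative")
  if (!identical(rownames(object@bandAmplitudes), c("theta", "beta", "gamma")))
    msg <- c(msg, "bandAmplitudes rows must be theta, beta, gamma")
  if (!identical(colnames(object@bandAmplitudes), c("normal", "asd")))
    msg <- c(msg, "bandAmplitudes columns must be normal, asd")
  if (object@nSubjectsPerClass < 1L)
    msg <- c(msg, "nSubjectsPerClass must be >= 1")
  if (length(object@channelLabels) != object@nChannels)
    msg <- c(msg, "channelLabels must match nChannels")
  if (any(object@bandRanges[, 2] <= object@bandRanges[, 1]) ||
      any(object@bandRanges[, 2] > object@fs / 2))
    msg <- c(msg, "band ranges must be increasing and below fs/2")
  if (object@subjectGainSd < 0 || object@whiteSd < 0 || object@pinkScale < 0 ||
      object@asdEnvelopeDepth < 0)
    msg <- c(msg, "noise/gain/envelope parameters must be non-negative")
  if (length(msg)) msg else TRUE
})
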