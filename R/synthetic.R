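# Synthetic two-class EEG cohort with planted band-specific class effects.
# Each channel is a sum of band-limited oscillations (several sinusoids per
# band with uniform random frequencies and phases), scaled by a class- and
# band-specific amplitude and a per-subject gain, plus 1/f pink noise and
# white noise. The ASD class additionally receives a slow multiplicative
# amplitude envelope emulating inconsistent up-and-down band-power
# fluctuations; the normal class is higher and more stable by construction.

DEFAULT_CHANNELS_15 <- c("FP1", "F3", "F7", "T3", "T5", "O1", "C4", "FP2",
                         "FZ", "F4", "F8", "C3", "CZ", "PZ", "OZ")

#' Construct a synthetic cohort specification
#'
#' Defaults define the package's reference study conditions: 8 subjects per
#' class, 15 channels, 256 Hz, 1000 samples per subject (16 records x 1000
#' rows = 16,000 feature rows per level), and band amplitudes planting a
#' class effect with the largest normal/ASD gap in beta, then gamma, then
#' theta, the normal class being at least as strong in every band. See the
#' vignette for how these values were chosen and what they calibrate.
#'
#' @param nSubjectsPerClass subjects per class.
#' @param fs sampling rate, Hz.
#' @param durationS record duration, seconds (`fs * durationS` samples).
#' @param nChannels number of channels.
#' @param channelLabels channel names.
#' @param bandAmplitudes 3 x 2 numeric matrix (rows theta/beta/gamma,
#'   columns normal/asd), sinusoidal amplitudes in uV.
#' @param bandRanges 3 x 2 matrix of band edges, Hz.
#' @param oscillatorsPerBand sinusoids per band per channel.
#' @param subjectGainSd SD of the per-subject multiplicative gain.
#' @param whiteSd white-noise SD, uV.
#' @param pinkScale pink-noise SD, uV.
#' @param asdEnvelopeDepth slow ASD amplitude-envelope depth (0 disables).
#' @param envelopeFreqRange envelope frequency range, Hz.
#' @param seed base seed for the cohort.
#' @return a [CohortSpec-class].
#' @export
#' @examples
#' spec <- cohortSpec(nSubjectsPerClass = 2, durationS = 0.5)
#' cohort <- simulateCohort(spec)
cohortSpec <- function(nSubjectsPerClass = 8L,
                       fs = 256,
                       durationS = 1000 / 256,
                       nChannels = 15L,
                       channelLabels = DEFAULT_CHANNELS_15[
                         seq_len(nChannels)],
                       bandAmplitudes = rbind(theta = c(10, 8),
                                              beta  = c(20, 8),
                                              gamma = c(8, 4.5)),
                       bandRanges = rbind(theta = c(4, 8),
                                          beta  = c(16, 32),
                                          gamma = c(32, 64)),
                       oscillatorsPerBand = 6L,
                       subjectGainSd = 0.015,
                       whiteSd = 2,
                       pinkScale = 3,
                       asdEnvelopeDepth = 0.25,
                       envelopeFreqRange = c(0.1, 0.4),
                       seed = 42L) {
  colnames(bandAmplitudes) <- c("normal", "asd")
  colnames(bandRanges) <- c("lo", "hi")
  if (nChannels > length(DEFAULT_CHANNELS_15) &&
      missing(channelLabels))
    channelLabels <- paste0("CH", seq_len(nChannels))
  new("CohortSpec",
      nSubjectsPerClass = as.integer(nSubjectsPerClass),
      fs = as.numeric(fs), durationS = as.numeric(durationS),
      nChannels = as.integer(nChannels),
      channelLabels = as.character(channelLabels),
      bandAmplitudes = bandAmplitudes, bandRanges = bandRanges,
      oscillatorsPerBand = as.integer(oscillatorsPerBand),
      subjectGainSd = as.numeric(subjectGainSd),
      whiteSd = as.numeric(whiteSd), pinkScale = as.numeric(pinkScale),
      asdEnvelopeDepth = as.numeric(asdEnvelopeDepth),
      envelopeFreqRange = as.numeric(envelopeFreqRange),
      seed = as.integer(seed))
}

#' Null (no-class-effect) version of a cohort specification
#'
#' Copies the normal-class band amplitudes onto the ASD class and disables
#' the ASD envelope, so the two classes are statistically identical; used
#' to verify that end-to-end accuracy sits at chance.
#'
#' @param spec a [CohortSpec-class] (default the reference spec).
#' @return a [CohortSpec-class] with no planted class difference.
#' @export
nullCohortSpec <- function(spec = cohortSpec()) {
  amps <- spec@bandAmplitudes
  amps[, "asd"] <- amps[, "normal"]
  initialize(spec, bandAmplitudes = amps, asdEnvelopeDepth = 0)
}

# 1/f pink noise of length n with unit sd, by spectral amplitude shaping of
# white Gaussian noise (DC removed). Consumes the current RNG stream.
pinkNoise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1L)       # two-sided frequency index
  W <- W / sqrt(f)
  W[1L] <- 0
  p <- Re(stats::fft(W, inverse = TRUE)) / n
  p / stats::sd(p)
}

subjectSeed <- function(spec, subjectIndex, classLabel) {
  as.integer((as.numeric(spec@seed) + 7919 * subjectIndex +
              104729 * (classLabel == "ASD")) %% .Machine$integer.max)
}

#' Simulate one subject's EEG record
#'
#' Deterministic given `(spec@seed, subjectIndex, classLabel)`: each
#' subject has an independent derived random stream, so records do not
#' depend on simulation order. Per channel and band, `K` sinusoids with
#' stratified random frequencies inside the band and random phases are
#' summed and normalized to sample sd `a_band * (1 + g) / sqrt(2)` (the sd
#' of an amplitude-`a_band` sinusoid), multiplied by the slow ASD amplitude
#' envelope `env(t)` (identically 1 for the normal class); 1/f pink noise
#' and white noise are added last. `g` is the per-subject gain, shared
#' across channels and bands.
#'
#' @param spec a [CohortSpec-class].
#' @param subjectIndex subject number within the class (1-based).
#' @param classLabel `"ASD"` or `"NORMAL"`.
#' @return an [EEGRecord-class] with id like `"asd_03"`.
#' @export
simulateSubject <- function(spec, subjectIndex, classLabel) {
  stopifnot(is(spec, "CohortSpec"))
  classLabel <- match.arg(classLabel, EEG_CLASS_LEVELS)
  n <- as.integer(round(spec@fs * spec@durationS))
  t <- (seq_len(n) - 1L) / spec@fs
  K <- spec@oscillatorsPerBand
  col <- if (classLabel == "ASD") "asd" else "normal"

  X <- withSeed(subjectSeed(spec, subjectIndex, classLabel), {
    g <- stats::rnorm(1L, 0, spec@subjectGainSd)
    env <- if (classLabel == "ASD" && spec@asdEnvelopeDepth > 0) {
      fe <- stats::runif(1L, spec@envelopeFreqRange[1L],
                         spec@envelopeFreqRange[2L])
      1 + spec@asdEnvelopeDepth *
        sin(2 * pi * fe * t + stats::runif(1L, 0, 2 * pi))
    } else rep(1, n)
    M <- matrix(0, n, spec@nChannels)
    for (b in rownames(spec@bandAmplitudes)) {
      a <- spec@bandAmplitudes[b, col] * (1 + g)
      lo <- spec@bandRanges[b, "lo"]; hi <- spec@bandRanges[b, "hi"]
      edges <- seq(lo, hi, length.out = K + 1L)
      for (ch in seq_len(spec@nChannels)) {
        if (a == 0) next
        osc <- 0
        for (k in seq_len(K)) {
          # stratified draw: one oscillator per equal sub-interval, so the
          # band is covered evenly
          f0 <- stats::runif(1L, edges[k], edges[k + 1L])
          osc <- osc + sin(2 * pi * f0 * t + stats::runif(1L, 0, 2 * pi))
        }
        # normalize so the planted band has sample sd exactly a/sqrt(2),
        # the sd of an amplitude-a sinusoid (no band-power realization
        # noise between subjects beyond the gain and envelope)
        osc <- osc / stats::sd(osc)
        M[, ch] <- M[, ch] + a / sqrt(2) * env * osc
      }
    }
    for (ch in seq_len(spec@nChannels)) {
      if (spec@pinkScale > 0)
        M[, ch] <- M[, ch] + spec@pinkScale * pinkNoise(n)
      if (spec@whiteSd > 0)
        M[, ch] <- M[, ch] + stats::rnorm(n, 0, spec@whiteSd)
    }
    M
  })
  eegRecord(X, sprintf("%s_%02d", tolower(classLabel), subjectIndex),
            classLabel, spec@fs, spec@channelLabels)
}

#' Simulate a full two-class cohort
#'
#' `nSubjectsPerClass` records per class with unique subject identifiers.
#'
#' @param spec a [CohortSpec-class].
#' @return list of [EEGRecord-class] objects (NORMAL subjects first).
#' @seealso [writeCohort()] to materialize the cohort on disk.
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  stopifnot(is(spec, "CohortSpec"))
  recs <- list()
  for (cl in c("NORMAL", "ASD"))
    for (i in seq_len(spec@nSubjectsPerClass))
      recs[[length(recs) + 1L]] <- simulateSubject(spec, i, cl)
  recs
}
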