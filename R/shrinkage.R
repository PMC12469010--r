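# Wavelet-shrinkage denoising: hard/soft elementwise rules, a robust MAD
# noise-scale estimator, the universal threshold, and their application to
# detail coefficients (the approximation band is never thresholded).

#' Hard ("keep or kill") thresholding
#'
#' Returns `x` where `|x| > lambda` and 0 elsewhere. The boundary
#' `|x| == lambda` is killed (strict inequality).
#'
#' @param x numeric vector/matrix of coefficients.
#' @param lambda threshold, `>= 0`.
#' @return thresholded coefficients, same shape as `x`.
#' @export
#' @examples
#' hardThreshold(c(5, 2, 3, -5), 3)  # 5, 0, 0, -5
hardThreshold <- function(x, lambda) {
  stopifnotScalarNumber(lambda, "lambda")
  if (lambda < 0) stop("lambda must be >= 0")
  x * (abs(x) > lambda)
}

#' Soft thresholding (shrinkage toward zero)
#'
#' Returns `sign(x) * max(|x| - lambda, 0)`: coefficients above the
#' threshold are shrunk by `lambda`, the rest are set to zero. Continuous
#' in `x`, unlike [hardThreshold()].
#'
#' @inheritParams hardThreshold
#' @return thresholded coefficients, same shape as `x`.
#' @export
#' @examples
#' softThreshold(c(5, -5, 2), 3)  # 2, -2, 0
softThreshold <- function(x, lambda) {
  stopifnotScalarNumber(lambda, "lambda")
  if (lambda < 0) stop("lambda must be >= 0")
  sign(x) * pmax(abs(x) - lambda, 0)
}

#' Robust noise-scale estimate from detail coefficients
#'
#' The standard median-absolute-deviation estimator
#' `sigma = median(|d - median(d)|) / 0.6745`, conventionally applied to
#' the finest-level details where the signal is sparsest.
#'
#' @param d numeric vector of detail coefficients (length >= 2).
#' @return estimated noise standard deviation, `>= 0`.
#' @export
#' @examples
#' estimateSigma(c(0.6745, -0.6745, 0.6745, -0.6745))  # 1
estimateSigma <- function(d) {
  d <- as.numeric(d)
  if (length(d) < 2L) stop("at least 2 coefficients are required")
  stats::median(abs(d - stats::median(d))) / 0.6745
}

#' Universal threshold
#'
#' `lambda = sigma * sqrt(2 * log(N))`, the standard default derived from
#' the expected maximum of N Gaussian noise coefficients.
#'
#' @param sigma noise scale, `>= 0`.
#' @param N coefficient count, `>= 2`.
#' @return the threshold.
#' @export
#' @examples
#' universalThreshold(1, 1024)  # about 3.723
universalThreshold <- function(sigma, N) {
  stopifnotScalarNumber(sigma, "sigma")
  stopifnotScalarNumber(N, "N")
  if (sigma < 0) stop("sigma must be >= 0")
  if (N < 2) stop("N must be >= 2")
  sigma * sqrt(2 * log(N))
}

#' Construct a ThresholdSpec
#'
#' @param rule `"soft"` (default) or `"hard"`.
#' @param lambdas optional named numeric vector of fixed per-level
#'   thresholds; when omitted, thresholds are computed per channel with the
#'   universal rule and the chosen noise estimator.
#' @param sigmaEstimator `"mad_level1"` (default: one sigma per channel from
#'   level-1 details, applied at every level), `"mad_per_level"` (one sigma
#'   per channel and level) or `"fixed"`.
#' @param fixedSigma noise scale for `sigmaEstimator = "fixed"`.
#' @return a [ThresholdSpec-class].
#' @export
thresholdSpec <- function(rule = c("soft", "hard"), lambdas = NULL,
                          sigmaEstimator = c("mad_level1", "mad_per_level",
                                             "fixed"),
                          fixedSigma = NULL) {
  rule <- match.arg(rule)
  sigmaEstimator <- match.arg(sigmaEstimator)
  new("ThresholdSpec", rule = rule,
      lambdas = if (is.null(lambdas)) numeric() else lambdas,
      sigmaEstimator = sigmaEstimator,
      fixedSigma = if (is.null(fixedSigma)) numeric() else
        as.numeric(fixedSigma))
}

# JSON (de)serialization used by the pipeline configuration.
thresholdSpecToList <- function(spec) {
  list(rule = spec@rule,
       lambdas = if (length(spec@lambdas)) as.list(spec@lambdas) else NULL,
       sigma_estimator = spec@sigmaEstimator,
       fixed_sigma = if (length(spec@fixedSigma)) spec@fixedSigma else NULL)
}

thresholdSpecFromList <- function(x) {
  thresholdSpec(rule = x$rule %||% "soft",
                lambdas = if (length(x$lambdas)) unlist(x$lambdas) else NULL,
                sigmaEstimator = x$sigma_estimator %||% "mad_level1",
                fixedSigma = x$fixed_sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Denoise a decomposition by wavelet shrinkage
#'
#' Applies the spec's rule elementwise to every detail level, per channel
#' independently; the approximation band is never thresholded. When no
#' fixed `lambdas` are given, the threshold for channel c at level j is
#' `universalThreshold(sigma_cj, N)` with `N` the per-channel sample count
#' and `sigma_cj` from the chosen estimator.
#'
#' @param dec an [SWTDecomposition-class].
#' @param spec a [ThresholdSpec-class]; default soft rule with level-1 MAD
#'   sigma.
#' @return a new [SWTDecomposition-class] with thresholded details.
#' @export
denoise <- function(dec, spec = thresholdSpec()) {
  stopifnot(is(dec, "SWTDecomposition"), is(spec, "ThresholdSpec"))
  if (length(spec@lambdas)) {
    lv <- as.integer(names(spec@lambdas))
    if (any(is.na(lv)) || any(!lv %in% seq_len(dec@levels)))
      stop("lambdas name levels outside the decomposition (1..",
           dec@levels, ")")
  }
  thr <- switch(spec@rule, soft = softThreshold, hard = hardThreshold)
  N <- dec@originalLength
  nch <- ncol(dec@approximation)

  sigmaL1 <- if (spec@sigmaEstimator == "mad_level1") {
    d1 <- detailMatrix(dec, 1L)
    vapply(seq_len(nch), function(c) estimateSigma(d1[, c]), numeric(1))
  }

  details <- dec@details
  for (j in seq_len(dec@levels)) {
    fixed <- spec@lambdas[as.character(j)]
    dj <- details[[j]]
    trimmed <- detailMatrix(dec, j)
    for (c in seq_len(nch)) {
      lam <- if (length(fixed) && !is.na(fixed)) {
        unname(fixed)
      } else {
        sig <- switch(spec@sigmaEstimator,
          mad_level1    = sigmaL1[c],
          mad_per_level = estimateSigma(trimmed[, c]),
          fixed         = spec@fixedSigma)
        universalThreshold(sig, N)
      }
      dj[, c] <- thr(dj[, c], lam)
    }
    details[[j]] <- dj
  }
  initialize(dec, details = details)
}
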