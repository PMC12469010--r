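# Per-level sub-band feature matrices (rows = time samples, columns =
# channels) and train-fitted z-normalization.

#' Extract sub-band feature matrices from a decomposition
#'
#' For each requested level, builds a feature matrix from that level's
#' (typically denoised) detail coefficients, trimmed to the original sample
#' count, with every row labeled by the source record's class and subject.
#'
#' The default representation is the per-sample coefficient magnitude
#' `|d|`, the band-amplitude feature: class differences in band power then
#' appear as class differences in feature means, which is what a
#' mean-separating linear discriminant can use. `"raw"` keeps the signed
#' coefficients (zero-mean in each class for stationary signals; retained
#' for diagnostics). An optional epoch-averaging mode reduces each
#' non-overlapping epoch of `epochLength` samples to its column mean.
#'
#' Under the `"paper"` profile, level `j` refers to the dyadic detail level
#' `j - 1` so the conventional level/band table of this pipeline (3 = gamma
#' 32-64 Hz, 4 = beta 16-32 Hz, 6 = theta 4-8 Hz at 256 Hz) is honored
#' physically; see [bandOfLevel()].
#'
#' @param dec an [SWTDecomposition-class].
#' @param rec the source [EEGRecord-class] (class label, subject id).
#' @param levels integer vector of reported levels (default `c(3, 4, 6)`).
#' @param profile `"paper"` (default) or `"dyadic"` level numbering.
#' @param representation `"magnitude"` (default) or `"raw"`.
#' @param epochLength optional epoch size in samples for epoch averaging.
#' @return named list of [SubbandFeatures-class], one per level.
#' @export
extractFeatures <- function(dec, rec, levels = c(3L, 4L, 6L),
                            profile = c("paper", "dyadic"),
                            representation = c("magnitude", "raw"),
                            epochLength = NULL) {
  stopifnot(is(dec, "SWTDecomposition"), is(rec, "EEGRecord"))
  profile <- match.arg(profile)
  representation <- match.arg(representation)
  levels <- as.integer(levels)
  out <- vector("list", length(levels))
  names(out) <- paste0("level", levels)
  for (i in seq_along(levels)) {
    j <- levels[i]
    info <- bandOfLevel(j, dec@sourceFs, profile)
    cj <- info$coefficientLevel
    if (cj > dec@levels)
      stop(sprintf(
        "level %d (%s profile) needs coefficient level %d; decomposition has %d",
        j, profile, cj, dec@levels))
    X <- detailMatrix(dec, cj)
    if (representation == "magnitude") X <- abs(X)
    y <- rep(classLabel(rec), nrow(X))
    subj <- rep(subjectId(rec), nrow(X))
    if (!is.null(epochLength)) {
      epochLength <- as.integer(epochLength)
      if (epochLength < 1L || epochLength > nrow(X))
        stop("epochLength must be in 1..nSamples")
      nep <- nrow(X) %/% epochLength
      idx <- rep(seq_len(nep), each = epochLength)
      Xe <- apply(X[seq_along(idx), , drop = FALSE], 2L,
                  function(col) tapply(col, idx, mean))
      X <- matrix(Xe, nrow = nep, dimnames = list(NULL, colnames(X)))
      y <- rep(classLabel(rec), nep)
      subj <- rep(subjectId(rec), nep)
    }
    out[[i]] <- new("SubbandFeatures", level = j, band = info$band,
                    X = X, y = y, subject = subj,
                    representation = representation)
  }
  out
}

#' Stack per-subject feature matrices into one cohort matrix
#'
#' @param featList list of [SubbandFeatures-class] at the same level.
#' @return a single [SubbandFeatures-class] with rows concatenated in input
#'   order.
#' @export
bindFeatures <- function(featList) {
  stopifnot(length(featList) >= 1L)
  lev <- unique(vapply(featList, function(f) f@level, integer(1)))
  if (length(lev) != 1L) stop("features come from different levels")
  new("SubbandFeatures",
      level = lev,
      band = featList[[1L]]@band,
      X = do.call(rbind, lapply(featList, function(f) f@X)),
      y = unlist(lapply(featList, function(f) f@y), use.names = FALSE),
      subject = unlist(lapply(featList, function(f) f@subject),
                       use.names = FALSE),
      representation = featList[[1L]]@representation)
}

featureMatrix <- function(f) if (is(f, "SubbandFeatures")) f@X else as.matrix(f)

#' Fit z-normalization statistics on training rows
#'
#' Per-column mean and population standard deviation (denominator n). A
#' zero-variance column is a degenerate feature and raises an error naming
#' the column.
#'
#' @param train a [SubbandFeatures-class] or numeric matrix of training
#'   rows.
#' @return a [NormalizationStats-class].
#' @export
#' @examples
#' zscoreFit(matrix(c(1, 3, 2, 4), 2, 2))
zscoreFit <- function(train) {
  X <- featureMatrix(train)
  if (nrow(X) < 1L) stop("training matrix is empty")
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2))  # population sd
  if (any(sdv == 0)) {
    bad <- which(sdv == 0)
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("degenerate (zero-variance) feature column: ",
         paste(nm, collapse = ", "))
  }
  new("NormalizationStats", mean = unname(mu), sd = unname(sdv),
      fittedOn = nrow(X))
}

#' Apply fitted z-normalization statistics
#'
#' `(X - mean) / sd` columnwise, leaving labels and subjects unchanged.
#' Statistics must be fitted on training rows only so no test information
#' leaks into the transform.
#'
#' @param stats a [NormalizationStats-class].
#' @param M a [SubbandFeatures-class] or numeric matrix; column count must
#'   match the fitted statistics.
#' @return same type as `M`, normalized.
#' @export
zscoreApply <- function(stats, M) {
  stopifnot(is(stats, "NormalizationStats"))
  X <- featureMatrix(M)
  if (ncol(X) != length(stats@mean))
    stop(sprintf("shape mismatch: %d columns vs %d fitted statistics",
                 ncol(X), length(stats@mean)))
  Z <- sweep(sweep(X, 2L, stats@mean), 2L, stats@sd, "/")
  if (is(M, "SubbandFeatures")) initialize(M, X = Z) else Z
}

#' Export a feature matrix as CSV
#'
#' Channel-named columns plus `class` and `subject` columns.
#'
#' @param feat a [SubbandFeatures-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(feat, path) {
  df <- as.data.frame(feat@X)
  df$class <- feat@y
  df$subject <- feat@subject
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
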