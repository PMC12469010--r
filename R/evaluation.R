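# Subject-wise stratified splitting, confusion matrices, metric arithmetic
# and the end-to-end per-level evaluation pipeline.

#' Subject-wise stratified train/test split
#'
#' Partitions subjects (never rows) into train and test sets: within each
#' class, subjects are shuffled with the given seed and the first
#' `round(fraction * n)` (round half up) go to training, with at least one
#' train and one test subject enforced per class. Deterministic given the
#' seed; the caller's RNG state is untouched.
#'
#' @param subjects character vector of subject identifiers (unique).
#' @param labels class label per subject.
#' @param fraction target train share, in (0, 1); default 0.7.
#' @param seed integer seed; default 42.
#' @return list with `train`, `test` (subject id vectors), `fraction`,
#'   `seed`, `stratified = TRUE`.
#' @export
#' @examples
#' subjectWiseSplit(paste0("s", 1:16), rep(c("ASD", "NORMAL"), each = 8))
subjectWiseSplit <- function(subjects, labels, fraction = 0.7, seed = 42L) {
  subjects <- as.character(subjects)
  labels <- as.character(labels)
  if (length(subjects) != length(labels))
    stop("subjects and labels lengths differ")
  if (anyDuplicated(subjects)) stop("subject ids must be unique")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("stratification error: every class needs >= 2 subjects")
  train <- character()
  test <- character()
  withSeed(seed, {
    for (cl in sort(names(counts))) {
      ss <- subjects[labels == cl]
      ss <- ss[sample.int(length(ss))]
      nTrain <- floor(fraction * length(ss) + 0.5)      # round half up
      nTrain <- min(max(nTrain, 1L), length(ss) - 1L)   # >= 1 on each side
      train <- c(train, ss[seq_len(nTrain)])
      test <- c(test, ss[-seq_len(nTrain)])
    }
  })
  list(train = train, test = test, fraction = fraction,
       seed = as.integer(seed), stratified = TRUE)
}

#' Confusion matrix for binary ASD/NORMAL classification
#'
#' Counts with ASD as the positive class: `TP` (ASD predicted ASD), `FN`
#' (ASD predicted NORMAL), `FP` (NORMAL predicted ASD), `TN`.
#'
#' @param yTrue,yPred label vectors of equal length with values in
#'   `{"ASD", "NORMAL"}`.
#' @return named integer vector `c(TP, FN, FP, TN)` of class
#'   `"confusionCounts"`.
#' @export
confusion <- function(yTrue, yPred) {
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred)) stop("label vectors differ in length")
  if (!length(yTrue)) stop("empty input")
  bad <- setdiff(unique(c(yTrue, yPred)), EEG_CLASS_LEVELS)
  if (length(bad))
    stop("labels outside {ASD, NORMAL}: ", paste(bad, collapse = ", "))
  out <- c(TP = sum(yTrue == "ASD" & yPred == "ASD"),
           FN = sum(yTrue == "ASD" & yPred == "NORMAL"),
           FP = sum(yTrue == "NORMAL" & yPred == "ASD"),
           TN = sum(yTrue == "NORMAL" & yPred == "NORMAL"))
  structure(as.integer(out), names = names(out), class = "confusionCounts")
}

#' Confusion counts from explicit cells
#'
#' @param TP,FN,FP,TN non-negative integer counts (total > 0).
#' @return named integer vector of class `"confusionCounts"`.
#' @export
confusionCounts <- function(TP, FN, FP, TN) {
  v <- c(TP = unname(TP), FN = unname(FN), FP = unname(FP),
         TN = unname(TN))
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (sum(v) <= 0) stop("empty confusion matrix")
  structure(as.integer(v), names = names(v), class = "confusionCounts")
}

#' Metrics from a confusion matrix
#'
#' `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `f1 = 2PR/(P+R)`. A metric whose denominator is zero is reported as
#' `NA` (undefined), never silently 0.
#'
#' @param cm counts from [confusion()] or [confusionCounts()].
#' @return named numeric vector
#'   `c(accuracy, specificity, recall, precision, f1)`.
#' @export
#' @examples
#' metrics(confusionCounts(2280, 120, 120, 2280))  # all 0.95
metrics <- function(cm) {
  cm <- as.integer(cm[c("TP", "FN", "FP", "TN")])
  names(cm) <- c("TP", "FN", "FP", "TN")
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- sdiv(cm["TP"], cm["TP"] + cm["FP"])
  recall <- sdiv(cm["TP"], cm["TP"] + cm["FN"])
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(accuracy    = unname(sdiv(cm["TP"] + cm["TN"], total)),
    specificity = unname(sdiv(cm["TN"], cm["TN"] + cm["FP"])),
    recall      = unname(recall),
    precision   = unname(precision),
    f1          = unname(f1))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline; round-trips through
#' JSON unchanged (see [writePipelineConfig()]).
#'
#' @param J decomposition depth (default 6).
#' @param levels reported levels (default `c(3, 4, 6)`).
#' @param profile level/band numbering, `"paper"` or `"dyadic"`.
#' @param wavelet filter bank name (only `"db4"` is built in).
#' @param rule shrinkage rule, `"soft"` or `"hard"`.
#' @param sigmaEstimator noise estimator for [denoise()].
#' @param representation feature representation for [extractFeatures()].
#' @param fraction train share of the subject-wise split.
#' @param seed split seed (default 42).
#' @param exclude channels dropped before analysis (default `"O2"`).
#' @param ridge FLDA ridge coefficient.
#' @param epochLength optional epoch averaging length, samples.
#' @return a validated list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(J = 6L, levels = c(3L, 4L, 6L),
                           profile = c("paper", "dyadic"),
                           wavelet = "db4",
                           rule = c("soft", "hard"),
                           sigmaEstimator = c("mad_level1", "mad_per_level",
                                              "fixed"),
                           representation = c("magnitude", "raw"),
                           fraction = 0.7, seed = 42L,
                           exclude = "O2", ridge = 1e-6,
                           epochLength = NULL) {
  profile <- match.arg(profile)
  rule <- match.arg(rule)
  sigmaEstimator <- match.arg(sigmaEstimator)
  representation <- match.arg(representation)
  if (!identical(wavelet, "db4")) stop("unknown wavelet: ", wavelet)
  J <- as.integer(J); levels <- as.integer(levels)
  maxCoef <- if (profile == "paper") J + 1L else J
  if (any(levels < 1L) || any(levels > maxCoef))
    stop("levels must lie within 1..", maxCoef, " for the ", profile,
         " profile at J = ", J)
  if (profile == "paper" && any(levels < 2L))
    stop("the paper profile starts at level 2")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  cfg <- list(J = J, levels = levels, profile = profile, wavelet = wavelet,
              rule = rule, sigmaEstimator = sigmaEstimator,
              representation = representation, fraction = fraction,
              seed = as.integer(seed), exclude = as.character(exclude),
              ridge = ridge,
              epochLength = if (is.null(epochLength)) NULL else
                as.integer(epochLength))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Serialize / restore a pipeline configuration as JSON
#'
#' @param config a [pipelineConfig()] list.
#' @param path file path.
#' @return `path` invisibly / the configuration.
#' @export
writePipelineConfig <- function(config, path) {
  obj <- unclass(config)
  obj$format_version <- FORMAT_VERSION
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  o <- jsonlite::fromJSON(path)
  pipelineConfig(J = o$J, levels = o$levels, profile = o$profile,
                 wavelet = o$wavelet, rule = o$rule,
                 sigmaEstimator = o$sigmaEstimator,
                 representation = o$representation, fraction = o$fraction,
                 seed = o$seed, exclude = o$exclude, ridge = o$ridge,
                 epochLength = o$epochLength)
}

configHash <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           null = "null"))
}

#' Run the full sub-band FLDA pipeline on a cohort
#'
#' For every record: drop excluded channels, stationary wavelet
#' decomposition, wavelet-shrinkage denoising, sub-band feature extraction
#' at the configured levels. Subjects are then split subject-wise
#' (stratified, seeded); per level, z-normalization statistics are fitted
#' on training rows only, an FLDA model is fitted on the training features
#' and the held-out subjects' rows are classified, yielding one confusion
#' matrix and metric set per level. Fully deterministic given the cohort
#' and configuration.
#'
#' @param cohort list of [EEGRecord-class] objects, or a path accepted by
#'   [readCohort()].
#' @param config a [pipelineConfig()].
#' @return list with `report` (one data.frame row per level: level, band,
#'   band edges, confusion cells, metrics, seed, config hash), `confusions`,
#'   `models`, `split` and `config`.
#' @export
evaluatePipeline <- function(cohort, config = pipelineConfig()) {
  if (is.character(cohort)) cohort <- readCohort(cohort)
  stopifnot(inherits(config, "pipelineConfig"))
  bank <- db4Filters()
  spec <- thresholdSpec(rule = config$rule,
                        sigmaEstimator = config$sigmaEstimator)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  perLevel <- stage("features", {
    featsBySubject <- lapply(cohort, function(rec) {
      if (length(config$exclude))
        rec <- suppressWarnings(dropChannels(rec, config$exclude))
      dec <- swtDecompose(rec, J = config$J, bank = bank)
      dec <- denoise(dec, spec)
      extractFeatures(dec, rec, levels = config$levels,
                      profile = config$profile,
                      representation = config$representation,
                      epochLength = config$epochLength)
    })
    lapply(seq_along(config$levels), function(i)
      bindFeatures(lapply(featsBySubject, `[[`, i)))
  })

  subjectIds <- vapply(cohort, subjectId, character(1))
  subjectLabels <- vapply(cohort, classLabel, character(1))
  split <- stage("split",
    subjectWiseSplit(subjectIds, subjectLabels, fraction = config$fraction,
                     seed = config$seed))

  rows <- list(); confusions <- list(); models <- list()
  hash <- configHash(config)
  for (i in seq_along(config$levels)) {
    lev <- config$levels[i]
    feat <- perLevel[[i]]
    tr <- feat@subject %in% split$train
    te <- feat@subject %in% split$test
    stats <- stage("zscore", zscoreFit(feat@X[tr, , drop = FALSE]))
    Ztr <- zscoreApply(stats, feat@X[tr, , drop = FALSE])
    model <- stage("flda",
      fldaFit(Ztr, feat@y[tr], ridge = config$ridge, normStats = stats))
    pred <- stage("predict", fldaPredict(model, feat@X[te, , drop = FALSE]))
    cm <- confusion(feat@y[te], pred)
    mt <- metrics(cm)
    info <- bandOfLevel(lev, samplingRate2(cohort), config$profile)
    rows[[i]] <- data.frame(level = lev, band = feat@band,
                            f_lo = info$low, f_hi = info$high,
                            TP = cm[["TP"]], FN = cm[["FN"]],
                            FP = cm[["FP"]], TN = cm[["TN"]],
                            accuracy = mt[["accuracy"]],
                            specificity = mt[["specificity"]],
                            recall = mt[["recall"]],
                            precision = mt[["precision"]],
                            f1 = mt[["f1"]],
                            seed = config$seed, config = hash,
                            stringsAsFactors = FALSE)
    confusions[[paste0("level", lev)]] <- cm
    models[[paste0("level", lev)]] <- model
  }
  list(report = do.call(rbind, rows), confusions = confusions,
       models = models, split = split, config = config)
}

samplingRate2 <- function(cohort) {
  fs <- unique(vapply(cohort, samplingRate, numeric(1)))
  if (length(fs) != 1L) stop("records disagree on sampling rate")
  fs
}

#' Write an evaluation report
#'
#' JSON (full report incl. split and config) and CSV (one row per level).
#'
#' @param result return value of [evaluatePipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$report, file.path(dir, "report.csv"),
                   row.names = FALSE)
  obj <- list(format_version = FORMAT_VERSION,
              report = result$report,
              split = result$split,
              config = unclass(result$config))
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writePipelineConfig(result$config, file.path(dir, "config.json"))
  invisible(dir)
}
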