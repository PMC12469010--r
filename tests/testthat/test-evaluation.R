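test_that("subject-wise split is disjoint, exhaustive, stratified and seeded", {
  subj <- paste0("s", 1:16)
  lab <- rep(c("ASD", "NORMAL"), each = 8)
  sp <- subjectWiseSplit(subj, lab, 0.7, seed = 42)

  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), subj)
  # round(0.7 * 8) = 6 train / 2 test per class
  for (cl in c("ASD", "NORMAL")) {
    expect_equal(sum(sp$train %in% subj[lab == cl]), 6)
    expect_equal(sum(sp$test %in% subj[lab == cl]), 2)
  }

  # determinism and seed sensitivity
  expect_identical(sp, subjectWiseSplit(subj, lab, 0.7, seed = 42))
  sp2 <- subjectWiseSplit(subj, lab, 0.7, seed = 43)
  expect_false(identical(sp$train, sp2$train))

  # 5 + 5 at 0.7: round half up gives 4 train / 1 test per class
  sp3 <- subjectWiseSplit(paste0("t", 1:10), rep(c("ASD", "NORMAL"), 5),
                          0.7, seed = 1)
  expect_equal(length(sp3$train), 8)
  expect_equal(length(sp3$test), 2)

  expect_error(subjectWiseSplit(c("a", "b", "c"),
                                c("ASD", "ASD", "NORMAL"), 0.7, 1),
               "stratification")
  expect_error(subjectWiseSplit(c("a", "a"), c("ASD", "NORMAL"), 0.7, 1),
               "unique")
})

test_that("every class keeps at least one test subject at extreme fractions", {
  subj <- paste0("s", 1:6)
  lab <- rep(c("ASD", "NORMAL"), each = 3)
  hi <- subjectWiseSplit(subj, lab, 0.99, seed = 5)
  for (cl in c("ASD", "NORMAL"))
    expect_gte(sum(hi$test %in% subj[lab == cl]), 1)
  lo <- subjectWiseSplit(subj, lab, 0.01, seed = 5)
  for (cl in c("ASD", "NORMAL"))
    expect_gte(sum(lo$train %in% subj[lab == cl]), 1)
})

test_that("confusion counts match brute-force pairwise counting", {
  set.seed(17)
  yTrue <- sample(c("ASD", "NORMAL"), 500, replace = TRUE)
  yPred <- sample(c("ASD", "NORMAL"), 500, replace = TRUE)
  cm <- confusion(yTrue, yPred)

  counts <- c(TP = 0L, FN = 0L, FP = 0L, TN = 0L)
  for (i in seq_along(yTrue)) {
    cell <- if (yTrue[i] == "ASD" && yPred[i] == "ASD") "TP"
      else if (yTrue[i] == "ASD") "FN"
      else if (yPred[i] == "ASD") "FP" else "TN"
    counts[cell] <- counts[cell] + 1L
  }
  expect_equal(unclass(cm), counts, ignore_attr = FALSE)
  expect_equal(sum(cm), 500L)

  # perfect and fully inverted predictions
  expect_equal(unname(confusion(yTrue, yTrue)[c("FN", "FP")]), c(0L, 0L))
  inv <- ifelse(yTrue == "ASD", "NORMAL", "ASD")
  expect_equal(unname(confusion(yTrue, inv)[c("TP", "TN")]), c(0L, 0L))

  expect_error(confusion(c("ASD", "MAYBE"), c("ASD", "ASD")), "MAYBE")
  expect_error(confusion(character(), character()), "empty")
})

test_that("metric arithmetic follows the definitions, with NA for 0/0", {
  m <- metrics(confusionCounts(10, 0, 0, 0))
  expect_equal(m[["accuracy"]], 1)
  expect_equal(m[["precision"]], 1)
  expect_equal(m[["recall"]], 1)
  expect_true(is.na(m[["specificity"]]))   # TN + FP = 0: undefined, not 0

  m2 <- metrics(confusionCounts(0, 5, 0, 5))
  expect_true(is.na(m2[["precision"]]))
  expect_equal(m2[["recall"]], 0)

  m3 <- metrics(confusionCounts(3, 1, 2, 4))
  expect_equal(m3[["accuracy"]], 7 / 10)
  expect_equal(m3[["precision"]], 3 / 5)
  expect_equal(m3[["recall"]], 3 / 4)
  expect_equal(m3[["specificity"]], 4 / 6)
  expect_equal(m3[["f1"]],
               2 * (3 / 5) * (3 / 4) / ((3 / 5) + (3 / 4)))
})

test_that("pipeline produces a coherent per-level report", {
  cohort <- makeTinyCohort(nPerClass = 3, durationS = 0.5)
  cfg <- pipelineConfig(seed = 11, exclude = character())
  res <- evaluatePipeline(cohort, cfg)

  expect_equal(nrow(res$report), 3)
  expect_identical(res$report$band, c("GAMMA", "BETA", "THETA"))
  # cells sum to the number of test rows per level
  nTest <- length(res$split$test) * 128
  expect_true(all(rowSums(res$report[, c("TP", "FN", "FP", "TN")]) == nTest))
  expect_true(all(res$report$accuracy >= 0 & res$report$accuracy <= 1))

  # reruns are bitwise identical
  res2 <- evaluatePipeline(cohort, cfg)
  expect_identical(res$report, res2$report)

  # single-level config gives a single-row report
  res3 <- evaluatePipeline(cohort, pipelineConfig(levels = 4, seed = 11,
                                                  exclude = character()))
  expect_equal(nrow(res3$report), 1)
  expect_identical(res3$report$band, "BETA")
})

test_that("the fitted model is independent of test-set labels (no leakage)", {
  cohort <- makeTinyCohort(nPerClass = 3, durationS = 0.5)
  cfg <- pipelineConfig(levels = 4, seed = 11, exclude = character())
  res <- evaluatePipeline(cohort, cfg)

  # flip the class labels of all test subjects and rerun
  flipped <- lapply(cohort, function(r) {
    if (subjectId(r) %in% res$split$test)
      eegRecord(r@data, subjectId(r),
                ifelse(classLabel(r) == "ASD", "NORMAL", "ASD"),
                samplingRate(r), channelLabels(r))
    else r
  })
  res2 <- evaluatePipeline(flipped, cfg)
  m1 <- res$models$level4
  m2 <- res2$models$level4
  expect_identical(m1@W, m2@W)
  expect_identical(m1@threshold, m2@threshold)
  expect_identical(m1@normStats@mean, m2@normStats@mean)
  # but the metrics do change
  expect_false(identical(res$report$accuracy, res2$report$accuracy))
})

test_that("pipeline config validates, hashes and round-trips through JSON", {
  cfg <- pipelineConfig(J = 6, levels = c(3, 4, 6), seed = 9)
  p <- withr::local_tempfile(fileext = ".json")
  writePipelineConfig(cfg, p)
  cfg2 <- readPipelineConfig(p)
  expect_identical(unclass(cfg), unclass(cfg2))
  expect_identical(swtflda:::configHash(cfg), swtflda:::configHash(cfg2))

  expect_error(pipelineConfig(levels = 8), "levels")
  expect_error(pipelineConfig(levels = 1, profile = "paper"), "level 2")
  expect_error(pipelineConfig(fraction = 1.2), "fraction")
  expect_error(pipelineConfig(wavelet = "haar"), "wavelet")
})

test_that("stage failures carry the stage name", {
  cohort <- makeTinyCohort(nPerClass = 3, durationS = 0.5)
  # a zero-variance channel breaks z-scoring, reported at its stage
  broken <- lapply(cohort, function(r) {
    d <- r@data; d[, 1] <- 0
    eegRecord(d, subjectId(r), classLabel(r), samplingRate(r),
              channelLabels(r))
  })
  expect_error(
    evaluatePipeline(broken, pipelineConfig(levels = 4, seed = 1,
                                            exclude = character())),
    "\\[stage zscore\\]")
})

test_that("evaluation report files are written and re-readable", {
  d <- withr::local_tempdir()
  cohort <- makeTinyCohort(nPerClass = 2, durationS = 0.5)
  res <- evaluatePipeline(cohort, pipelineConfig(seed = 3,
                                                 exclude = character()))
  writeReport(res, d)
  expect_true(all(file.exists(file.path(d, c("report.csv", "report.json",
                                             "config.json")))))
  csv <- utils::read.csv(file.path(d, "report.csv"))
  expect_equal(csv$accuracy, res$report$accuracy, tolerance = 1e-12)
  cfgBack <- readPipelineConfig(file.path(d, "config.json"))
  expect_identical(unclass(cfgBack), unclass(res$config))
})
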