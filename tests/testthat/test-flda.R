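# Deterministic Gaussian toys used across the FLDA tests.
makeGaussianClasses <- function(n = 200, d = 2, shift = c(4, rep(0, d - 1)),
                                seed = 1, sdA = 1, sdB = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * d, sd = sdA), n, d),
             sweep(matrix(rnorm(n * d, sd = sdB), n, d), 2, shift, "+"))
  y <- rep(c("NORMAL", "ASD"), each = n)
  list(X = X, y = y)
}

test_that("scatter matrices match brute-force summation", {
  g <- makeGaussianClasses(n = 200, d = 2, seed = 11)
  sc <- scatterMatrices(g$X, g$y)

  # independent brute-force double loop
  d <- ncol(g$X)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  mu <- colMeans(g$X)
  for (cl in unique(g$y)) {
    Xc <- g$X[g$y == cl, ]
    mc <- colMeans(Xc)
    for (i in seq_len(nrow(Xc)))
      Sw <- Sw + (Xc[i, ] - mc) %*% t(Xc[i, ] - mc)
    Sb <- Sb + nrow(Xc) * (mc - mu) %*% t(mc - mu)
  }
  expect_equal(sc$Sw, Sw, tolerance = 1e-10)
  expect_equal(sc$Sb, Sb, tolerance = 1e-10)

  # PSD and symmetric
  expect_equal(sc$Sw, t(sc$Sw))
  expect_true(all(eigen(sc$Sw, symmetric = TRUE)$values > -1e-10))
  expect_true(all(eigen(sc$Sb, symmetric = TRUE)$values > -1e-10))
})

test_that("degenerate scatter cases behave as documented", {
  # identical class means: Sb = 0
  X <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  y <- c("A", "A", "B", "B")
  expect_equal(scatterMatrices(X, y)$Sb, matrix(0, 2, 2), tolerance = 1e-12)

  # single repeated point per class (precondition relaxed): Sw = 0
  X2 <- rbind(c(1, 1), c(2, 2))
  sc2 <- scatterMatrices(X2, c("A", "B"), allowDegenerate = TRUE)
  expect_equal(sc2$Sw, matrix(0, 2, 2))
  expect_error(scatterMatrices(X2, c("A", "B")), "degenerate class")
})

test_that("Fisher criterion is scale-invariant and zero when Sb = 0", {
  g <- makeGaussianClasses(seed = 2)
  sc <- scatterMatrices(g$X, g$y)
  set.seed(3)
  for (i in 1:5) {
    w <- rnorm(2)
    expect_equal(fisherCriterion(2 * w, sc$Sw, sc$Sb),
                 fisherCriterion(w, sc$Sw, sc$Sb), tolerance = 1e-12)
  }
  expect_equal(fisherCriterion(c(1, 1), sc$Sw, matrix(0, 2, 2)), 0)
  expect_error(fisherCriterion(c(1, 0), matrix(0, 2, 2), sc$Sb),
               "singularity")
})

test_that("binary fit matches the closed form and the eigenpair equation", {
  g <- makeGaussianClasses(n = 300, d = 5,
                           shift = c(2, -1, 0.5, 0, 1), seed = 7)
  model <- fldaFit(g$X, g$y, ridge = 0)

  # closed form in the normalized space
  Z <- zscoreApply(model@normStats, g$X)
  sc <- scatterMatrices(Z, g$y)
  dvec <- sc$classMeans["ASD", ] - sc$classMeans["NORMAL", ]
  wStar <- solve(sc$Sw, dvec)
  wStar <- wStar / sqrt(sum(wStar^2))
  cosine <- abs(sum(wStar * model@W[, 1]))
  expect_gt(cosine, 1 - 1e-10)

  # generalized eigenpair residual: Sb w = lambda Sw w
  w <- model@W[, 1]
  lam <- drop(crossprod(w, sc$Sb %*% w)) / drop(crossprod(w, sc$Sw %*% w))
  resid <- sc$Sb %*% w - lam * (sc$Sw %*% w)
  expect_lt(sqrt(sum(resid^2)) / sqrt(sum((sc$Sb %*% w)^2)), 1e-8)
})

test_that("fitted direction dominates 1e5 random unit directions", {
  g <- makeGaussianClasses(n = 150, d = 3, shift = c(1.5, -0.5, 1),
                           seed = 13)
  model <- fldaFit(g$X, g$y, ridge = 0)
  Z <- zscoreApply(model@normStats, g$X)
  sc <- scatterMatrices(Z, g$y)
  jFit <- fisherCriterion(model@W[, 1], sc$Sw, sc$Sb)

  set.seed(99)
  V <- matrix(rnorm(3 * 1e5), 3)
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  num <- colSums(V * (sc$Sb %*% V))
  den <- colSums(V * (sc$Sw %*% V))
  expect_gte(jFit, max(num / den))
})

test_that("spherical classes give a direction parallel to the mean difference", {
  g <- makeGaussianClasses(n = 3000, d = 2, shift = c(4, 0), seed = 21)
  model <- fldaFit(g$X, g$y, ridge = 0)
  # in the normalized space the planted difference stays along (1, 0)
  cosine <- abs(model@W[1, 1]) / sqrt(sum(model@W[, 1]^2))
  expect_gt(cosine, 0.99)
})

test_that("projection and prediction honor threshold, ties and orientation", {
  g <- makeGaussianClasses(n = 100, d = 2, seed = 5)
  model <- fldaFit(g$X, g$y)
  pm <- model@classMeansProjected

  # ASD mean projects above NORMAL; threshold is their midpoint
  expect_gte(pm["ASD", 1], pm["NORMAL", 1])
  expect_equal(model@threshold, mean(pm[, 1]))

  # training class means classify to their own class
  Z <- zscoreApply(model@normStats, g$X)
  mA <- colMeans(Z[g$y == "ASD", , drop = FALSE])
  mN <- colMeans(Z[g$y == "NORMAL", , drop = FALSE])
  predMeans <- fldaPredict(model, rbind(mA, mN), normalized = TRUE)
  expect_identical(predMeans, c("ASD", "NORMAL"))

  # a zero row (post-normalization) projects to zero
  expect_equal(drop(fldaProject(model, matrix(0, 1, 2), normalized = TRUE)),
               0)

  # a score exactly at the threshold is assigned to ASD (documented tie rule)
  tie <- new("FLDAModel", W = matrix(1),
             classMeansProjected = matrix(c(-1, 1), 2, 1,
               dimnames = list(c("NORMAL", "ASD"), NULL)),
             threshold = 0,
             classOrder = c(negative = "NORMAL", positive = "ASD"),
             classLevels = c("NORMAL", "ASD"),
             normStats = new("NormalizationStats", mean = 0, sd = 1,
                             fittedOn = 2L),
             ridge = 0)
  expect_identical(fldaPredict(tie, matrix(0)), "ASD")
  expect_identical(fldaPredict(tie, matrix(-1e-12)), "NORMAL")

  expect_error(fldaProject(model, matrix(0, 1, 5)), "shape mismatch")
})

test_that("predictions equal the nearest-projected-mean rule for equal covariances", {
  g <- makeGaussianClasses(n = 400, d = 3, shift = c(2, 1, -1), seed = 31)
  model <- fldaFit(g$X, g$y)
  te <- makeGaussianClasses(n = 100, d = 3, shift = c(2, 1, -1), seed = 32)
  pred <- fldaPredict(model, te$X)

  s <- drop(fldaProject(model, te$X))
  pm <- model@classMeansProjected[, 1]
  nearest <- names(pm)[apply(abs(outer(s, pm, "-")), 1, which.min)]
  # midpoint threshold = nearest projected mean for the binary case
  expect_identical(pred, nearest)
  expect_gt(mean(pred == te$y), 0.8)
})

test_that("scaling all features leaves predictions unchanged", {
  g <- makeGaussianClasses(n = 200, d = 4, shift = c(1, 0, 2, 0), seed = 41)
  m1 <- fldaFit(g$X, g$y)
  m2 <- fldaFit(g$X * 37.5, g$y)
  te <- matrix(rnorm(40), 10, 4)
  expect_identical(fldaPredict(m1, te), fldaPredict(m2, te * 37.5))
})

test_that("normalization absorbs a constant shift of all training rows", {
  g <- makeGaussianClasses(n = 150, d = 3, shift = c(2, 0, 1), seed = 51)
  shift <- c(100, -50, 7)
  Xs <- sweep(g$X, 2, shift, "+")
  m1 <- fldaFit(g$X, g$y)
  m2 <- fldaFit(Xs, g$y)
  expect_equal(fldaProject(m1, g$X), fldaProject(m2, Xs), tolerance = 1e-8)
})

test_that("planted direction is recovered increasingly well with n", {
  planted <- c(1, 0, 0, 0)
  angle <- function(n, seeds = 1:5) {
    mean(vapply(seeds, function(s) {
      g <- makeGaussianClasses(n = n, d = 4, shift = planted, seed = s)
      m <- fldaFit(g$X, g$y, ridge = 0)
      # the planted difference is axis-aligned, so normalization keeps it
      acos(min(1, abs(sum(m@W[, 1] * planted))))
    }, numeric(1)))
  }
  a <- vapply(c(50, 500, 5000), angle, numeric(1))
  expect_true(all(diff(a) < 0))
})

test_that("singular within-class scatter demands a ridge and ridge rescues it", {
  # rank-deficient features: column 3 duplicates column 1
  g <- makeGaussianClasses(n = 100, d = 2, shift = c(3, 0), seed = 61)
  X <- cbind(g$X, g$X[, 1])
  expect_error(fldaFit(X, g$y, ridge = 0), "ridge")
  m <- fldaFit(X, g$y, ridge = 1e-6)
  expect_s4_class(m, "FLDAModel")
  expect_gt(mean(fldaPredict(m, X) == g$y), 0.9)
})

test_that("three-class fit keeps C-1 components and classifies by nearest mean", {
  set.seed(71)
  n <- 150
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(4, 0), "+"),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(0, 4), "+"))
  y <- rep(c("A", "B", "C"), each = n)
  m <- fldaFit(X, y, positive = "C")
  expect_equal(ncol(m@W), 2L)
  expect_true(is.na(m@threshold))
  expect_gt(mean(fldaPredict(m, X) == y), 0.9)
})

test_that("models serialize to JSON and back without changing predictions", {
  g <- makeGaussianClasses(n = 80, d = 3, shift = c(2, -1, 1), seed = 81)
  m <- fldaFit(g$X, g$y)
  p <- withr::local_tempfile(fileext = ".json")
  writeFLDAModel(m, p)
  m2 <- readFLDAModel(p)
  te <- matrix(rnorm(30), 10, 3)
  expect_identical(fldaPredict(m, te), fldaPredict(m2, te))
  expect_equal(m2@W, m@W, tolerance = 1e-12)
  expect_equal(m2@threshold, m@threshold, tolerance = 1e-12)
})
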