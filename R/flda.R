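# Fisher Linear Discriminant: scatter matrices, the Fisher criterion, the
# projection fit (closed form for two classes, generalized eigenproblem for
# more), projection and the equal-prior linear decision rule.

#' Within- and between-class scatter matrices
#'
#' `Sw = sum_c sum_{i in c} (x_i - mu_c)(x_i - mu_c)'` and
#' `Sb = sum_c n_c (mu_c - mu)(mu_c - mu)'`; both symmetric positive
#' semidefinite.
#'
#' @param X numeric matrix, rows = observations.
#' @param y class label per row (>= 2 classes).
#' @param allowDegenerate permit classes with fewer than 2 rows (used in
#'   degenerate-case diagnostics; default `FALSE`).
#' @return list with elements `Sw`, `Sb`, `classMeans` (classes x features),
#'   `counts` and `grandMean`.
#' @export
scatterMatrices <- function(X, y, allowDegenerate = FALSE) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ")
  classes <- unique(y)
  if (length(classes) < 2L) stop("at least 2 classes are required")
  counts <- table(y)[classes]
  if (!allowDegenerate && any(counts < 2L))
    stop("degenerate class with fewer than 2 rows: ",
         paste(classes[counts < 2L], collapse = ", "))
  d <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  classMeans <- matrix(0, length(classes), d,
                       dimnames = list(classes, colnames(X)))
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    classMeans[cl, ] <- mc
    Xc <- sweep(Xc, 2L, mc)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - mu)
  }
  list(Sw = Sw, Sb = Sb, classMeans = classMeans,
       counts = as.integer(counts), grandMean = mu)
}

#' Fisher criterion
#'
#' `J(w) = (w' Sb w) / (w' Sw w)`; scale-invariant in `w`.
#'
#' @param w direction vector.
#' @param Sw,Sb scatter matrices from [scatterMatrices()].
#' @return the criterion value.
#' @export
fisherCriterion <- function(w, Sw, Sb) {
  w <- as.numeric(w)
  den <- drop(crossprod(w, Sw %*% w))
  if (den <= 0)
    stop("singularity: w' Sw w must be positive (try ridge > 0)")
  drop(crossprod(w, Sb %*% w)) / den
}

ridgedSw <- function(Sw, ridge) {
  d <- ncol(Sw)
  if (ridge > 0) Sw + ridge * sum(diag(Sw)) / d * diag(d) else Sw
}

#' Fit a Fisher Linear Discriminant model
#'
#' Maximizes `J(w) = (w' Sb w)/(w' Sw w)`. For two classes the solution is
#' the closed form `w` proportional to `Sw^-1 (mu_pos - mu_neg)`; for C > 2
#' classes the top `C - 1` eigenvectors of `Sw^-1 Sb` are retained. A ridge
#' term `ridge * tr(Sw)/d * I` stabilizes `Sw` against small-sample
#' singularity (default `1e-6`); a singular `Sw` with `ridge = 0` raises an
#' error advising a positive ridge.
#'
#' Features are z-normalized before fitting: pass raw features and the
#' statistics are fitted here, or pass already-normalized features together
#' with the [NormalizationStats-class] they were normalized with (the
#' leakage-safe pipeline path, statistics fitted on training rows only).
#' The stored statistics are re-applied by [fldaProject()] and
#' [fldaPredict()].
#'
#' The binary decision threshold is the midpoint of the projected class
#' means (the Bayes cut under equal priors and equal projected variances).
#' Component 1 is oriented so the positive class (default `"ASD"`) projects
#' at or above the negative class.
#'
#' @param X features (matrix or [SubbandFeatures-class]).
#' @param y class label per row; taken from `X` if a `SubbandFeatures`.
#' @param ridge ridge coefficient, `>= 0`.
#' @param normStats optional [NormalizationStats-class] when `X` is already
#'   normalized; when `NULL`, statistics are fitted on `X` here.
#' @param positive positive class label (default `"ASD"`).
#' @return an [FLDAModel-class].
#' @export
fldaFit <- function(X, y = NULL, ridge = 1e-6, normStats = NULL,
                    positive = "ASD") {
  if (is(X, "SubbandFeatures")) {
    if (is.null(y)) y <- X@y
    X <- X@X
  }
  X <- as.matrix(X)
  y <- as.character(y)
  if (anyNA(X) || any(!is.finite(X))) stop("X must be finite")
  if (ridge < 0) stop("ridge must be >= 0")
  if (is.null(normStats)) {
    normStats <- zscoreFit(X)
    X <- zscoreApply(normStats, X)
  }
  sc <- scatterMatrices(X, y)
  classes <- rownames(sc$classMeans)
  C <- length(classes)
  Swr <- ridgedSw(sc$Sw, ridge)

  negative <- if (positive %in% classes && C == 2L)
    setdiff(classes, positive) else classes[1L]
  if (!positive %in% classes) positive <- classes[C]

  solveSw <- function(B) {
    out <- tryCatch(solve(Swr, B), error = function(e)
      stop("singular within-class scatter; refit with ridge > 0",
           call. = FALSE))
    out
  }

  if (C == 2L) {
    d <- sc$classMeans[positive, ] - sc$classMeans[negative, ]
    w <- drop(solveSw(matrix(d, ncol = 1L)))
    W <- matrix(w / sqrt(sum(w^2)), ncol = 1L)
  } else {
    M <- solveSw(sc$Sb)
    ev <- eigen(M)
    ord <- order(Re(ev$values), decreasing = TRUE)[seq_len(C - 1L)]
    W <- Re(ev$vectors[, ord, drop = FALSE])
    W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
    # orient: positive class above the first class on every component
    pm <- sc$classMeans %*% W
    flip <- pm[positive, ] < pm[classes[1L], ]
    W[, flip] <- -W[, flip]
  }

  pm <- sc$classMeans %*% W
  threshold <- if (C == 2L)
    mean(pm[c(positive, negative), 1L]) else NA_real_

  new("FLDAModel", W = W, classMeansProjected = pm,
      threshold = threshold,
      classOrder = c(negative = negative, positive = positive),
      classLevels = classes, normStats = normStats,
      ridge = as.numeric(ridge))
}

#' Project features onto the discriminant components
#'
#' Applies the model's stored normalization statistics, then `X %*% W`.
#'
#' @param model an [FLDAModel-class].
#' @param X features (matrix or [SubbandFeatures-class]); raw scale unless
#'   `normalized = TRUE`.
#' @param normalized set `TRUE` if `X` is already normalized with the
#'   model's statistics.
#' @return score matrix, rows x components.
#' @export
fldaProject <- function(model, X, normalized = FALSE) {
  stopifnot(is(model, "FLDAModel"))
  X <- featureMatrix(X)
  if (ncol(X) != nrow(model@W))
    stop(sprintf("shape mismatch: %d features vs model with %d",
                 ncol(X), nrow(model@W)))
  if (!normalized) X <- zscoreApply(model@normStats, X)
  X %*% model@W
}

#' Classify with the linear decision rule
#'
#' Binary: label = positive class iff `score >= threshold` (ties go to the
#' positive class). More than two classes: nearest projected class mean.
#'
#' @inheritParams fldaProject
#' @return character vector of predicted labels.
#' @export
fldaPredict <- function(model, X, normalized = FALSE) {
  S <- fldaProject(model, X, normalized = normalized)
  if (length(model@classLevels) == 2L) {
    unname(ifelse(S[, 1L] >= model@threshold,
                  model@classOrder[["positive"]],
                  model@classOrder[["negative"]]))
  } else {
    pm <- model@classMeansProjected
    d2 <- vapply(rownames(pm), function(cl)
      rowSums(sweep(S, 2L, pm[cl, ])^2), numeric(nrow(S)))
    rownames(pm)[max.col(-matrix(d2, nrow(S)))]
  }
}

#' Serialize / restore an FLDA model as JSON
#'
#' @param model an [FLDAModel-class].
#' @param path output path.
#' @return `path` invisibly (`writeFLDAModel`); an [FLDAModel-class]
#'   (`readFLDAModel`).
#' @export
writeFLDAModel <- function(model, path) {
  obj <- list(format_version = FORMAT_VERSION,
              W = model@W,
              class_means_projected = model@classMeansProjected,
              class_levels = model@classLevels,
              threshold = model@threshold,
              class_order = as.list(model@classOrder),
              ridge = model@ridge,
              norm_mean = model@normStats@mean,
              norm_sd = model@normStats@sd,
              norm_fitted_on = model@normStats@fittedOn)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFLDAModel
#' @export
readFLDAModel <- function(path) {
  o <- jsonlite::fromJSON(path)
  pm <- as.matrix(o$class_means_projected)
  rownames(pm) <- o$class_levels
  new("FLDAModel", W = as.matrix(o$W), classMeansProjected = pm,
      threshold = as.numeric(o$threshold),
      classOrder = c(negative = o$class_order$negative,
                     positive = o$class_order$positive),
      classLevels = as.character(o$class_levels),
      normStats = new("NormalizationStats", mean = as.numeric(o$norm_mean),
                      sd = as.numeric(o$norm_sd),
                      fittedOn = as.integer(o$norm_fitted_on)),
      ridge = as.numeric(o$ridge))
}
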