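#' Unshrunk centroid statistics
#'
#' First stage of nearest-shrunken-centroid training on a samples x genes
#' log2 expression matrix: class centroids, overall centroid, pooled
#' within-class standard deviations \eqn{s_j}, the fudge constant
#' \eqn{s_0} (median of \eqn{s_j}), the per-class scale
#' \eqn{m_k = \sqrt{1/n_k + 1/n}} and class priors \eqn{\pi_k = n_k/n}.
#'
#' @param X numeric matrix, samples x genes (column names are gene ids).
#' @param y class labels, one per sample; every class needs >= 2 samples.
#' @param name model name carried into downstream objects.
#' @return list of statistics consumed by \code{\link{shrinkCentroids}}.
#' @export
fitCentroids <- function(X, y, name = "classifier") {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y))
    stop("X must have one row per label in y")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("at least two classes are required")
  nk <- table(factor(y, levels = classes))
  if (any(nk < 2L))
    stop("every class needs at least 2 samples; offending: ",
         paste(names(nk)[nk < 2L], collapse = ", "))
  n <- nrow(X)
  K <- length(classes)
  geneIds <- colnames(X) %||% paste0("g", seq_len(ncol(X)))
  xbar <- colMeans(X)
  xbarK <- vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                  numeric(ncol(X)))
  ssw <- Reduce(`+`, lapply(classes, function(k) {
    Xi <- X[y == k, , drop = FALSE]
    colSums(sweep(Xi, 2L, colMeans(Xi))^2)
  }))
  sj <- sqrt(ssw / (n - K))
  list(name = name, classes = classes, geneIds = geneIds,
       overallCentroid = unname(xbar),
       classCentroids = matrix(xbarK, ncol(X), K,
                               dimnames = list(geneIds, classes)),
       pooledSD = unname(sj), s0 = stats::median(sj),
       mk = stats::setNames(sqrt(1 / as.numeric(nk) + 1 / n), classes),
       priors = stats::setNames(as.numeric(nk) / n, classes))
}

#' Soft-threshold centroids at a shrinkage level
#'
#' Standardizes class-vs-overall centroid differences,
#' \eqn{d_{kj} = (\bar x_{kj} - \bar x_j)/(m_k (s_j + s_0))}, applies the
#' soft threshold \eqn{d'_{kj} = sign(d_{kj}) (|d_{kj}| - \Delta)_+} and
#' rebuilds shrunken centroids
#' \eqn{\bar x'_{kj} = \bar x_j + m_k (s_j + s_0) d'_{kj}}.
#'
#' @param stats output of \code{\link{fitCentroids}}.
#' @param delta non-negative shrinkage threshold.
#' @param cv optional cross-validation trace stored with the model.
#' @return a \linkS4class{CentroidModel}.
#' @export
shrinkCentroids <- function(stats, delta = 0, cv = list()) {
  if (delta < 0) stop("delta must be non-negative")
  se <- stats$pooledSD + stats$s0
  denom <- outer(se, stats$mk)
  diff <- stats$classCentroids - stats$overallCentroid
  d <- ifelse(denom > 0, diff / denom, 0)
  dShrunk <- sign(d) * pmax(abs(d) - delta, 0)
  shrunken <- stats$overallCentroid + denom * dShrunk
  maxAbs <- apply(abs(d), 1L, max)
  sel <- se > 0 & (maxAbs > delta | (delta == 0 & se > 0))
  methods::new("CentroidModel",
               name = stats$name, classes = stats$classes,
               geneIds = stats$geneIds,
               overallCentroid = stats$overallCentroid,
               classCentroids = stats$classCentroids,
               shrunkenCentroids = matrix(shrunken,
                                          length(stats$geneIds),
                                          length(stats$classes),
                                          dimnames = dimnames(stats$classCentroids)),
               pooledSD = stats$pooledSD, s0 = stats$s0,
               mk = stats$mk, priors = stats$priors,
               delta = delta,
               selectedGenes = stats$geneIds[sel],
               cv = cv)
}

#' Classify one expression profile
#'
#' The discriminant for class k is the prior-penalized standardized
#' distance to its shrunken centroid over the selected genes,
#' \eqn{\delta_k(x) = \sum_j (x_j - \bar x'_{kj})^2/(s_j+s_0)^2 -
#' 2\log\pi_k}; the predicted label minimizes it and probabilities are
#' \eqn{\propto \exp(-\delta_k/2)}. Genes missing from \code{x} are
#' imputed with the overall centroid value (with a warning). A fully
#' collapsed model predicts by priors alone and is flagged
#' "uninformative".
#'
#' @param object a \linkS4class{CentroidModel}.
#' @param x named numeric vector of log2 expression.
#' @return a \linkS4class{Prediction}.
#' @importFrom stats predict
#' @export
setMethod("predict", "CentroidModel", function(object, x) {
  xv <- stats::setNames(object@overallCentroid, object@geneIds)
  if (is.null(names(x))) {
    if (length(x) != length(object@geneIds))
      stop("unnamed profile must align with the model genes")
    xv[] <- x
  } else {
    have <- intersect(names(x), object@geneIds)
    missing <- setdiff(object@geneIds, names(x))
    if (length(missing))
      warning(length(missing), " model gene(s) missing from the profile; ",
              "imputed with the overall centroid")
    xv[have] <- x[have]
  }
  flags <- character()
  sel <- match(object@selectedGenes, object@geneIds)
  se <- object@pooledSD + object@s0
  disc <- -2 * log(object@priors)
  if (length(sel)) {
    z <- (xv[sel] - object@shrunkenCentroids[sel, , drop = FALSE])^2 /
      se[sel]^2
    disc <- colSums(z) + disc
  } else {
    flags <- "uninformative"
  }
  pr <- exp(-(disc - min(disc)) / 2)
  pr <- pr / sum(pr)
  methods::new("Prediction",
               label = names(which.max(pr)),
               probabilities = pr,
               discriminants = disc,
               flags = flags)
})

stratifiedFolds <- function(y, kFolds, seed) {
  y <- as.character(y)
  nk <- table(y)
  # every training split must keep >= 2 samples of every class
  feasible <- function(k) all(nk - ceiling(nk / k) >= 2L)
  if (!feasible(kFolds)) {
    k <- kFolds
    while (k > 2L && !feasible(k)) k <- k - 1L
    if (!feasible(k))
      stop("cross-validation impossible: a class is too small to keep ",
           "2 training samples in every fold")
    warning("reducing folds from ", kFolds, " to ", k,
            " so every training split keeps every class")
    kFolds <- k
  }
  fold <- integer(length(y))
  set.seed(seed)
  for (k in unique(y)) {
    idx <- sample(which(y == k))
    fold[idx] <- rep_len(seq_len(kFolds), length(idx))
  }
  fold
}

#' Cross-validated error over a shrinkage grid
#'
#' Stratified k-fold cross-validation: for each fold, centroids are
#' refit on the remaining samples and the held-out samples are classified
#' at every shrinkage level.
#'
#' @param X samples x genes log2 expression.
#' @param y class labels.
#' @param deltaGrid non-negative thresholds; default 30 points from 0 to
#'   the largest absolute standardized difference in the full fit.
#' @param kFolds number of folds (default 10, reduced if a class is small).
#' @param seed RNG seed for fold assignment.
#' @param name model name.
#' @return list(deltaGrid, error, nSelected, seed, kFolds).
#' @export
nscCrossValidate <- function(X, y, deltaGrid = NULL, kFolds = 10,
                             seed = 1, name = "classifier") {
  X <- as.matrix(X)
  y <- as.character(y)
  full <- fitCentroids(X, y, name = name)
  if (is.null(deltaGrid)) {
    se <- full$pooledSD + full$s0
    denom <- outer(se, full$mk)
    d <- ifelse(denom > 0,
                (full$classCentroids - full$overallCentroid) / denom, 0)
    deltaGrid <- seq(0, max(abs(d)), length.out = 30)
  }
  fold <- stratifiedFolds(y, kFolds, seed)
  nFolds <- max(fold)
  wrong <- matrix(0, nFolds, length(deltaGrid))
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    st <- fitCentroids(X[tr, , drop = FALSE], y[tr], name = name)
    te <- which(!tr)
    for (di in seq_along(deltaGrid)) {
      m <- shrinkCentroids(st, deltaGrid[di])
      pred <- vapply(te, function(i)
        suppressWarnings(predictedLabel(predict(m, X[i, ]))), character(1))
      wrong[f, di] <- sum(pred != y[te])
    }
  }
  err <- colSums(wrong) / length(y)
  nSel <- vapply(deltaGrid, function(d)
    length(shrinkCentroids(full, d)@selectedGenes), integer(1))
  list(deltaGrid = deltaGrid, error = err, nSelected = nSel,
       seed = seed, kFolds = nFolds)
}

#' Train a nearest-shrunken-centroid classifier
#'
#' Fits centroid statistics, selects the shrinkage level minimizing the
#' cross-validated error (ties broken toward the largest threshold, i.e.
#' the fewest genes) and returns the model refit on all samples.
#'
#' @inheritParams nscCrossValidate
#' @return a \linkS4class{CentroidModel} with the CV trace in \code{@cv}.
#' @export
trainCentroidModel <- function(X, y, deltaGrid = NULL, kFolds = 10,
                               seed = 1, name = "classifier") {
  cv <- nscCrossValidate(X, y, deltaGrid = deltaGrid, kFolds = kFolds,
                         seed = seed, name = name)
  best <- max(which(cv$error == min(cv$error)))
  full <- fitCentroids(X, y, name = name)
  shrinkCentroids(full, cv$deltaGrid[best], cv = cv)
}
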