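test_that("centroid statistics match hand computation on the 1-gene toy", {
  X <- matrix(c(1, 1, 3, 3), 4, 1, dimnames = list(NULL, "g1"))
  y <- c("A", "A", "B", "B")
  st <- fitCentroids(X, y)
  expect_equal(st$overallCentroid, 2)
  expect_equal(unname(st$classCentroids[1, ]), c(1, 3))
  expect_equal(st$pooledSD, 0)
  expect_equal(unname(st$priors), c(0.5, 0.5))
  expect_equal(unname(st$mk), rep(sqrt(1 / 2 + 1 / 4), 2))
  expect_error(fitCentroids(X, c("A", "B", "B", "B")), "at least 2")
})

test_that("identical per-class data gives zero standardized differences", {
  X <- matrix(rep(c(5, 2, 7), each = 6), 6, 3)
  colnames(X) <- paste0("g", 1:3)
  st <- fitCentroids(X, rep(c("A", "B"), each = 3))
  m <- shrinkCentroids(st, 0)
  expect_equal(m@shrunkenCentroids[, "A"], m@shrunkenCentroids[, "B"])
  expect_equal(unname(m@shrunkenCentroids[, "A"]), st$overallCentroid)
})

test_that("soft thresholding shrinks standardized differences correctly", {
  st <- list(name = "t", classes = c("A", "B"), geneIds = "g1",
             overallCentroid = 0,
             classCentroids = matrix(c(2.5, -2.5), 1, 2,
                                     dimnames = list("g1", c("A", "B"))),
             pooledSD = 1, s0 = 0, mk = c(A = 1, B = 1),
             priors = c(A = 0.5, B = 0.5))
  # d_A = 2.5; at delta 1 the shrunken difference is 1.5
  m1 <- shrinkCentroids(st, 1)
  expect_equal(unname(m1@shrunkenCentroids["g1", ]), c(1.5, -1.5))
  # delta 0 is the identity
  m0 <- shrinkCentroids(st, 0)
  expect_identical(m0@shrunkenCentroids, st$classCentroids)
  # delta beyond max |d| collapses everything
  mBig <- shrinkCentroids(st, 3)
  expect_equal(unname(mBig@shrunkenCentroids["g1", ]), c(0, 0))
  expect_length(mBig@selectedGenes, 0)
})

test_that("predictions match centroids, priors and the degenerate toy", {
  sim <- simulateClassCohort(nGenes = 40, classes = c("A", "B", "C"),
                             nPerClass = 10, nShifted = 9, shiftSD = 3,
                             seed = 6)
  m <- shrinkCentroids(fitCentroids(sim$X, sim$y), 0)
  for (k in m@classes) {
    pred <- predict(m, setNames(m@shrunkenCentroids[, k], m@geneIds))
    expect_identical(predictedLabel(pred), k)
    expect_equal(sum(classProbabilities(pred)), 1, tolerance = 1e-9)
  }
  # fully collapsed model falls back to priors
  stp <- list(name = "t", classes = c("A", "B"), geneIds = "g1",
              overallCentroid = 0,
              classCentroids = matrix(c(1, -1), 1, 2,
                                      dimnames = list("g1", c("A", "B"))),
              pooledSD = 1, s0 = 0, mk = c(A = 1, B = 1),
              priors = c(A = 0.7, B = 0.3))
  mc <- shrinkCentroids(stp, 10)
  pred <- predict(mc, c(g1 = 5))
  expect_identical(predictedLabel(pred), "A")
  expect_equal(unname(classProbabilities(pred)), c(0.7, 0.3),
               tolerance = 1e-9)
  expect_identical(pred@flags, "uninformative")
  # 1-gene toy with zero pooled SD: call by priors, first class on ties
  X <- matrix(c(1, 1, 3, 3), 4, 1, dimnames = list(NULL, "g1"))
  mt <- shrinkCentroids(fitCentroids(X, c("A", "A", "B", "B")), 0)
  expect_identical(predictedLabel(predict(mt, c(g1 = 1))), "A")
})

test_that("delta = 0 predictions equal a diagonal Gaussian classifier", {
  set.seed(13)
  for (i in 1:25) {
    K <- sample(2:4, 1)
    n <- K * 8
    X <- matrix(rnorm(n * 12), n, 12,
                dimnames = list(NULL, paste0("g", 1:12)))
    y <- rep(LETTERS[1:K], each = 8)
    X[, 1:3] <- X[, 1:3] + outer(as.integer(factor(y)), rep(1, 3))
    st <- fitCentroids(X, y)
    m <- shrinkCentroids(st, 0)
    x <- rnorm(12)
    names(x) <- colnames(X)
    expect_identical(predictedLabel(predict(m, x)),
                     gaussianOracleLabel(st, unname(x)))
  }
})

test_that("selected-gene count is non-increasing in delta", {
  sim <- simulateClassCohort(nGenes = 200, nPerClass = 15, nShifted = 20,
                             seed = 8)
  st <- fitCentroids(sim$X, sim$y)
  grid <- seq(0, 6, length.out = 30)
  nSel <- vapply(grid, function(d)
    length(shrinkCentroids(st, d)@selectedGenes), integer(1))
  expect_true(all(diff(nSel) <= 0))
  expect_equal(nSel[1], sum(st$pooledSD + st$s0 > 0))
})

test_that("cross-validation selects sensible shrinkage", {
  sim <- simulateClassCohort(nGenes = 60, classes = c("A", "B"),
                             nPerClass = 12, nShifted = 10, shiftSD = 6,
                             seed = 15)
  cv <- nscCrossValidate(sim$X, sim$y, kFolds = 4, seed = 2)
  expect_equal(min(cv$error), 0)
  one <- trainCentroidModel(sim$X, sim$y, deltaGrid = 1.25, kFolds = 4,
                            seed = 2)
  expect_equal(one@delta, 1.25)
})

test_that("permuted labels give chance-level cross-validated error", {
  simBig <- simulateClassCohort(nGenes = 50, classes = c("A", "B"),
                                nPerClass = 40, nShifted = 0, seed = 19)
  set.seed(77)
  yPerm <- sample(simBig$y)
  cvNull <- nscCrossValidate(simBig$X, yPerm, kFolds = 5, seed = 3)
  expect_true(abs(cvNull$error[1] - 0.5) <= 0.1)
})

test_that("ties in CV error resolve to the largest delta", {
  sim <- simulateClassCohort(nGenes = 30, classes = c("A", "B"),
                             nPerClass = 10, nShifted = 6, shiftSD = 8,
                             seed = 23)
  m <- trainCentroidModel(sim$X, sim$y, kFolds = 5, seed = 4)
  err <- m@cv$error
  expect_equal(m@delta, max(m@cv$deltaGrid[err == min(err)]))
})
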