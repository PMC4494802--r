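test_that("geometric means follow the zero-forcing log-mean convention", {
  expect_equal(unname(computeGeometricMeans(rbind(c(4, 9)))), 6)
  expect_equal(unname(computeGeometricMeans(rbind(c(0, 50)))), 0)
  m <- rbind(a = c(2, 4, 8), b = c(1, 1, 1), c = c(0, 10, 10))
  expect_equal(computeGeometricMeans(m), c(a = 4, b = 1, c = 0))
  expect_error(computeGeometricMeans(matrix(numeric(), 0, 0)),
               "non-empty")
  expect_error(computeGeometricMeans(rbind(c(-1, 2))), "non-negative")
})

test_that("geometric means are permutation-invariant over samples", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rpois(60, 20), 10, 6)
    m[sample(60, 5)] <- 0
    perm <- sample(ncol(m))
    expect_equal(computeGeometricMeans(m),
                 computeGeometricMeans(m[, perm]))
  }
})

test_that("size factors reproduce worked examples and scale equivariance", {
  gm <- c(10, 20, 5, 0, 8)
  expect_identical(computeSizeFactors(cbind(c(20, 40, 10, 3, 16)), gm), 2)
  counts <- rbind(c(10), c(20), c(5), c(0), c(8))
  expect_equal(computeSizeFactors(counts, gm), 1)
  expect_equal(computeSizeFactors(counts * 2, gm), 2)
  set.seed(7)
  m <- matrix(rpois(50, 30) + 1, 10, 5)
  gm2 <- computeGeometricMeans(m)
  sf <- computeSizeFactors(m, gm2)
  for (cc in c(0.5, 3, 11)) {
    m2 <- m
    m2[, 2] <- m2[, 2] * cc
    expect_equal(computeSizeFactors(m2, gm2)[2], sf[2] * cc,
                 tolerance = 1e-12)
  }
  expect_error(computeSizeFactors(cbind(c(0, 0)), c(5, 5)), "undefined")
})

test_that("size factors match the brute-force median-of-ratios oracle", {
  set.seed(11)
  for (i in 1:30) {
    m <- matrix(rpois(8 * 4, 15), 8, 4)
    m[sample(length(m), 4)] <- 0
    gm <- computeGeometricMeans(m)
    if (any(vapply(seq_len(4), function(s) !any(gm > 0 & m[, s] > 0),
                   logical(1)))) next
    expect_equal(computeSizeFactors(m, gm), bruteSizeFactors(m, gm),
                 tolerance = 1e-12)
    expect_equal(unname(gm), bruteGeoMeans(m), tolerance = 1e-12)
  }
})

test_that("size factors agree with the DESeq2 estimator on odd gene counts", {
  skip_if_not_installed("DESeq2")
  set.seed(3)
  m <- matrix(rpois(31 * 6, 40) + 1, 31, 6)  # all-positive, odd rows
  sf <- computeSizeFactors(m, computeGeometricMeans(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(sf, unname(ref), tolerance = 1e-12)
})

test_that("background genes are exactly the all-zero rows", {
  m <- matrix(5, 3, 2, dimnames = list(paste0("g", 1:3), NULL))
  expect_identical(identifyBackgroundGenes(m), character(0))
  m[2, ] <- 0
  expect_identical(identifyBackgroundGenes(m), "g2")
  m4 <- rbind(g1 = c(0, 0), g2 = c(0, 1), g3 = c(0, 0), g4 = c(5, 5))
  expect_identical(identifyBackgroundGenes(m4), c("g1", "g3"))
})

test_that("normal NB parameters use the method of moments with a floor", {
  counts <- rbind(g1 = c(5, 15), g2 = c(10, 10), g3 = c(20, 20))
  gm <- computeGeometricMeans(counts)
  np <- fitNormalParams(counts, gm, c("normal", "normal"))
  expect_equal(unname(np$mean[1]), 10)
  expect_equal(unname(np$dispersion[1]), 0.4)  # (50 - 10) / 100
  # constant gene: zero excess variance -> floor
  expect_equal(unname(np$dispersion[2]), 1e-8)
  cz <- rbind(g1 = c(5, 15), g2 = c(10, 10), gz = c(0, 0))
  npz <- fitNormalParams(cz, computeGeometricMeans(cz),
                         c("normal", "normal"))
  expect_equal(unname(npz$mean[3]), 0)
  expect_equal(unname(npz$dispersion[3]), 1e-8)
  expect_error(fitNormalParams(counts, gm, c("tumor", "normal")),
               "at least 2 normal")
})

test_that("frozen reference round-trips through freeze/thaw exactly", {
  ref <- tinyReference()
  sim <- simulateClassCohort(nGenes = 5, nPerClass = 6, nShifted = 2,
                             classes = c("A", "B"), seed = 4)
  ref@classifiers <- list(toy = trainCentroidModel(
    sim$X, sim$y, deltaGrid = c(0, 0.5), kFolds = 2, seed = 1,
    name = "toy"))
  path <- file.path(withr::local_tempdir(), "ref.frz.json")
  freezeReference(ref, path)
  back <- thawReference(path)
  expect_identical(geneIds(back), geneIds(ref))
  expect_identical(unname(geoMeans(back)), unname(geoMeans(ref)))
  expect_identical(backgroundGenes(back), backgroundGenes(ref))
  expect_identical(unname(normalMeans(back)), unname(normalMeans(ref)))
  expect_identical(unname(normalDispersions(back)),
                   unname(normalDispersions(ref)))
  m1 <- classifiers(ref)$toy; m2 <- classifiers(back)$toy
  expect_identical(m2@shrunkenCentroids, m1@shrunkenCentroids)
  expect_identical(m2@priors, m1@priors)
  expect_identical(m2@delta, m1@delta)
  expect_identical(m2@selectedGenes, m1@selectedGenes)
})

test_that("thaw rejects truncated and mis-versioned archives", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ref.frz.json")
  freezeReference(tinyReference(), path)
  txt <- readLines(path)
  writeLines(substr(txt, 1, nchar(txt) %/% 2), file.path(dir, "trunc.json"))
  expect_error(thawReference(file.path(dir, "trunc.json")), "cannot load")
  writeLines(sub("\"format_version\":\"1.0\"",
                 "\"format_version\":\"99.0\"", txt, fixed = TRUE),
             file.path(dir, "badver.json"))
  expect_error(thawReference(file.path(dir, "badver.json")), "version")
  writeLines("{\"format\": \"something-else\"}",
             file.path(dir, "badfmt.json"))
  expect_error(thawReference(file.path(dir, "badfmt.json")),
               "not a frozen reference")
})

test_that("background set and geometric means stay consistent", {
  ref <- tinyReference()
  expect_true(all(geoMeans(ref)[backgroundGenes(ref)] == 0))
  expect_identical(backgroundGenes(ref), "gD")
})
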