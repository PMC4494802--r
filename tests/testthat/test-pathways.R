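chainTopology <- function(sign = "activation") {
  pathwayTopology("chain", data.frame(source_gene = "A",
                                      target_gene = "B",
                                      interaction = sign,
                                      stringsAsFactors = FALSE),
                  genes = c("A", "B"))
}

starTopology <- function() {
  pathwayTopology("star", data.frame(source_gene = rep("H", 4),
                                     target_gene = paste0("L", 1:4),
                                     interaction = "activation",
                                     stringsAsFactors = FALSE),
                  genes = c("H", paste0("L", 1:4)))
}

randomDag <- function(p, seed) {
  set.seed(seed)
  genes <- paste0("g", seq_len(p))
  src <- tgt <- character(0)
  for (j in 2:p) {
    up <- which(runif(j - 1) < 0.4)
    src <- c(src, genes[up])
    tgt <- c(tgt, rep(genes[j], length(up)))
  }
  if (!length(src)) { src <- genes[1]; tgt <- genes[2] }
  pathwayTopology("dag", data.frame(
    source_gene = src, target_gene = tgt,
    interaction = sample(c("activation", "inhibition"), length(src),
                         replace = TRUE), stringsAsFactors = FALSE),
    genes = genes)
}

test_that("topology construction validates edges and counts targets", {
  tp <- starTopology()
  expect_equal(unname(tp@nDownstream), c(4, 0, 0, 0, 0))
  expect_equal(tp@beta["L1", "H"], 1)
  expect_error(pathwayTopology("x", data.frame(source_gene = "A")),
               "missing column")
  # unknown interaction types get weight 0 and are ignored
  tp2 <- pathwayTopology("y", data.frame(
    source_gene = c("A", "A"), target_gene = c("B", "C"),
    interaction = c("activation", "binding"), stringsAsFactors = FALSE),
    genes = c("A", "B", "C"))
  expect_equal(sum(tp2@beta != 0), 1)
})

test_that("the two-gene chain gives the derived PF, Acc and tA", {
  act <- chainTopology("activation")
  PF <- netPerturbation(c(1, 0), act)
  expect_equal(PF, c(1, 1))
  acc <- perturbationAccumulation(PF, c(1, 0))
  expect_equal(acc$acc, c(0, 1))
  expect_equal(acc$tA, 1)
  inh <- chainTopology("inhibition")
  PFi <- netPerturbation(c(1, 0), inh)
  expect_equal(PFi, c(1, -1))
  expect_equal(perturbationAccumulation(PFi, c(1, 0))$tA, -1)
  expect_equal(netPerturbation(c(0, 0), act), c(0, 0))
})

test_that("singular propagation systems are rejected", {
  cyc <- pathwayTopology("cycle", data.frame(
    source_gene = c("A", "B"), target_gene = c("B", "A"),
    interaction = "activation", stringsAsFactors = FALSE))
  expect_error(netPerturbation(c(1, 0), cyc), "unsolvable")
})

test_that("matrix solve equals fixed-point iteration on random DAGs", {
  for (i in 1:25) {
    tp <- randomDag(sample(4:10, 1), seed = 100 + i)
    dE <- numeric(length(tp@genes))
    dE[sample(length(dE), 2)] <- rnorm(2, 0, 2)
    expect_equal(netPerturbation(dE, tp), fixedPointPF(tp, dE),
                 tolerance = 1e-9)
  }
})

test_that("tA is invariant under gene relabeling", {
  tp <- randomDag(6, seed = 55)
  dE <- c(2, 0, -1, 0, 0, 0.5)
  tA <- perturbationAccumulation(netPerturbation(dE, tp), dE)$tA
  perm <- c(3, 1, 6, 2, 5, 4)
  tpPerm <- methods::new("PathwayTopology", pathwayId = "perm",
                         name = "perm", genes = tp@genes[perm],
                         beta = tp@beta[perm, perm],
                         nDownstream = tp@nDownstream[perm])
  tAPerm <- perturbationAccumulation(netPerturbation(dE[perm], tpPerm),
                                     dE[perm])$tA
  expect_equal(tA, tAPerm, tolerance = 1e-12)
})

test_that("bootstrap pPERT matches degenerate cases and the enumeration oracle", {
  star <- starTopology()
  # no DE gene in the pathway
  expect_equal(pathwayPerturbationP(star, rep(0, 5))$pPERT, 1)
  # single isolated node: tA is identically zero
  iso <- methods::new("PathwayTopology", pathwayId = "iso", name = "iso",
                      genes = "A", beta = matrix(0, 1, 1),
                      nDownstream = 0L)
  expect_equal(pathwayPerturbationP(iso, 3)$pPERT, 1)
  # star with the DE gene on the hub: exact enumeration gives 1/5
  dE <- c(2, 0, 0, 0, 0)
  exact <- enumPPert(star, dE)
  expect_equal(exact, 0.2)
  boot <- pathwayPerturbationP(star, dE, nBoot = 2000, seed = 4)
  tol <- 3 * sqrt(exact * (1 - exact) / 2000) + 1 / 2000
  expect_lt(abs(boot$pPERT - exact), tol)
  # determinism under a fixed seed
  boot2 <- pathwayPerturbationP(star, dE, nBoot = 2000, seed = 4)
  expect_identical(boot$pPERT, boot2$pPERT)
  expect_error(pathwayPerturbationP(star, dE, nBoot = 10), "at least 100")
})

test_that("enrichment p-values are exact hypergeometric upper tails", {
  expect_equal(pathwayEnrichmentP(0, 5, 5, 10), 1)
  expect_equal(pathwayEnrichmentP(5, 5, 5, 10), 1 / choose(10, 5))
  for (case in list(c(2, 6, 10, 40), c(4, 8, 12, 100), c(1, 3, 3, 30))) {
    expect_equal(pathwayEnrichmentP(case[1], case[2], case[3], case[4]),
                 bruteHyperUpper(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  expect_error(pathwayEnrichmentP(6, 5, 5, 10), "inconsistent")
})

test_that("the Fisher-product combination matches its closed form", {
  expect_equal(combinePG(1, 1), 1)
  expect_equal(combinePG(0.1, 0.1), 0.01 - 0.01 * log(0.01),
               tolerance = 1e-10)
  for (p in c(0.001, 0.2, 0.7))
    expect_gte(combinePG(p, 1), p)
  expect_error(combinePG(0, 0.5), "must lie")
})

test_that("analyzePathways ranks a constructed positive control first", {
  set.seed(123)
  universe <- paste0("g", 1:300)
  deGenes <- paste0("g", 1:30)
  de <- data.frame(gene = deGenes,
                   log2_fold_change = c(rep(3, 10), rnorm(20, 0, 2)),
                   significant = TRUE, stringsAsFactors = FALSE)
  hub <- pathwayTopology("hub", data.frame(
    source_gene = rep("g1", 9), target_gene = paste0("g", 2:10),
    interaction = "activation", stringsAsFactors = FALSE))
  rnd <- lapply(1:5, function(i) {
    genes <- sample(universe[31:300], 15)
    pathwayTopology(paste0("rnd", i), data.frame(
      source_gene = genes[1:14], target_gene = genes[2:15],
      interaction = "activation", stringsAsFactors = FALSE))
  })
  res <- analyzePathways(c(list(hub), rnd), de, universe, seed = 5)
  expect_identical(res$pathway_id[1], "hub")
  expect_identical(res$status[1], "activated")
  expect_true(all(res$pNDE[res$pathway_id != "hub"] == 1))
  # empty DE table: both component p-values are 1 everywhere
  deEmpty <- de[0, ]
  resEmpty <- analyzePathways(c(list(hub), rnd), deEmpty, universe,
                              seed = 5)
  expect_true(all(resEmpty$pNDE == 1))
  expect_true(all(resEmpty$pPERT == 1))
  expect_true(all(resEmpty$pG == 1))
})
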