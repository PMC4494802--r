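#' Construct a pathway topology
#'
#' @param pathwayId identifier.
#' @param edges data.frame with columns source_gene, target_gene,
#'   interaction ("activation", "inhibition" or other types).
#' @param genes optional full gene list (isolated genes allowed); defaults
#'   to the genes seen in the edge list.
#' @param name display name (defaults to the id).
#' @param edgeWeights named numeric, weight per interaction type; types
#'   absent from the map get weight 0 (ignored).
#' @return a \linkS4class{PathwayTopology}.
#' @export
pathwayTopology <- function(pathwayId, edges, genes = NULL,
                            name = pathwayId,
                            edgeWeights = c(activation = 1,
                                            inhibition = -1)) {
  need <- c("source_gene", "target_gene", "interaction")
  miss <- setdiff(need, names(edges))
  if (length(miss))
    stop("edge table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(genes))
    genes <- sort(unique(c(edges$source_gene, edges$target_gene)))
  genes <- as.character(genes)
  beta <- matrix(0, length(genes), length(genes),
                 dimnames = list(genes, genes))
  w <- edgeWeights[as.character(edges$interaction)]
  w[is.na(w)] <- 0
  keep <- w != 0
  if (any(keep)) {
    src <- as.character(edges$source_gene[keep])
    tgt <- as.character(edges$target_gene[keep])
    bad <- !(src %in% genes) | !(tgt %in% genes)
    if (any(bad)) stop("edge references a gene outside the gene list")
    # beta[i, j]: effect of source j on target i
    beta[cbind(match(tgt, genes), match(src, genes))] <- w[keep]
  }
  methods::new("PathwayTopology",
               pathwayId = as.character(pathwayId),
               name = as.character(name),
               genes = genes, beta = beta,
               nDownstream = as.integer(colSums(beta != 0)))
}

#' Read pathway topologies from an edge-list TSV
#'
#' Expects columns pathway_id, source_gene, target_gene, interaction.
#'
#' @param path TSV file.
#' @param edgeWeights see \code{\link{pathwayTopology}}.
#' @return named list of \linkS4class{PathwayTopology} objects.
#' @export
readPathwayTopologies <- function(path,
                                  edgeWeights = c(activation = 1,
                                                  inhibition = -1)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway_id", "source_gene", "target_gene", "interaction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pathway edge list is missing column(s): ",
         paste(miss, collapse = ", "))
  ids <- unique(df$pathway_id)
  out <- lapply(ids, function(id)
    pathwayTopology(id, df[df$pathway_id == id, , drop = FALSE],
                    edgeWeights = edgeWeights))
  stats::setNames(out, ids)
}

#' Net perturbation factors of a pathway
#'
#' Solves the propagation system \eqn{PF = \Delta E + B \cdot PF} with
#' \eqn{B_{ij} = \beta_{ij} / n_{ds}(j)} (downstream counts floored at 1),
#' i.e. \eqn{PF = (I - B)^{-1} \Delta E}: each gene's perturbation is its
#' own log2 fold change plus the normalized, signed perturbation inherited
#' from its upstream regulators.
#'
#' @param deltaE per-gene log2 fold changes aligned to the topology genes
#'   (0 for genes that are not differentially expressed).
#' @param topology a \linkS4class{PathwayTopology}.
#' @return numeric vector of perturbation factors, or an error when
#'   \eqn{I - B} is numerically singular (reciprocal condition number
#'   below 1e-10); callers flag such pathways "unsolvable".
#' @export
netPerturbation <- function(deltaE, topology) {
  p <- length(topology@genes)
  if (length(deltaE) != p)
    stop("deltaE must have one value per pathway gene")
  B <- sweep(topology@beta, 2L, pmax(topology@nDownstream, 1L), "/")
  A <- diag(p) - B
  if (rcond(A) < 1e-10)
    stop("pathway '", topology@pathwayId,
         "' is unsolvable: I - B is numerically singular")
  as.numeric(solve(A, deltaE))
}

#' Perturbation accumulation and total accumulated perturbation
#'
#' @param PF perturbation factors from \code{\link{netPerturbation}}.
#' @param deltaE the fold changes the factors were computed from.
#' @return list(acc = PF - deltaE, tA = sum(acc)).
#' @export
perturbationAccumulation <- function(PF, deltaE) {
  if (length(PF) != length(deltaE))
    stop("PF and deltaE must be aligned")
  acc <- PF - deltaE
  list(acc = acc, tA = sum(acc))
}

#' Bootstrap p-value for the total accumulated perturbation
#'
#' Builds the null by placing the observed nonzero fold changes on
#' uniformly random gene positions of the pathway and recomputing tA; the
#' p-value is the fraction of null draws at least as far from the null
#' median as the observed tA, floored at 1/nBoot.
#'
#' @param topology a \linkS4class{PathwayTopology}.
#' @param deltaE observed per-gene fold changes aligned to the topology.
#' @param nBoot number of bootstrap draws (default 2000, minimum 100).
#' @param seed RNG seed.
#' @return list(pPERT, tA, nullMedian).
#' @export
pathwayPerturbationP <- function(topology, deltaE, nBoot = 2000,
                                 seed = 1) {
  if (nBoot < 100) stop("nBoot must be at least 100")
  obsVals <- deltaE[deltaE != 0]
  PF <- netPerturbation(deltaE, topology)
  tA <- perturbationAccumulation(PF, deltaE)$tA
  if (!length(obsVals))
    return(list(pPERT = 1, tA = tA, nullMedian = 0))
  p <- length(topology@genes)
  B <- sweep(topology@beta, 2L, pmax(topology@nDownstream, 1L), "/")
  A <- diag(p) - B
  # tA is linear in deltaE: tA = w' deltaE with w = colSums(inv(A)) - 1
  w <- colSums(solve(A)) - 1
  set.seed(seed)
  nullTA <- vapply(seq_len(nBoot), function(b) {
    pos <- sample.int(p, length(obsVals))
    sum(w[pos] * obsVals)
  }, numeric(1))
  med <- stats::median(nullTA)
  pPERT <- max(mean(abs(nullTA - med) >= abs(tA - med)), 1 / nBoot)
  list(pPERT = pPERT, tA = tA, nullMedian = med)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least \code{nDEInPath}
#' differentially expressed genes in a pathway of \code{pathSize} genes,
#' given \code{nDETotal} DE genes in a universe of \code{universeSize}
#' (the reliably expressed genes).
#'
#' @param nDEInPath observed DE genes in the pathway.
#' @param pathSize pathway genes present in the universe.
#' @param nDETotal DE genes in the universe.
#' @param universeSize universe size.
#' @return P[X >= nDEInPath] under the hypergeometric null.
#' @export
pathwayEnrichmentP <- function(nDEInPath, pathSize, nDETotal,
                               universeSize) {
  if (nDEInPath > min(pathSize, nDETotal) || pathSize > universeSize ||
      nDETotal > universeSize || nDEInPath < 0)
    stop("inconsistent enrichment counts")
  if (nDEInPath == 0) return(1)
  stats::phyper(nDEInPath - 1, pathSize, universeSize - pathSize,
                nDETotal, lower.tail = FALSE)
}

#' Combine enrichment and perturbation p-values
#'
#' Fisher-product combination: with \eqn{c = pNDE \cdot pPERT},
#' \eqn{pG = c - c \log c} (the probability that a product of two
#' independent uniforms falls below c).
#'
#' @param pNDE,pPERT p-values in (0, 1].
#' @return combined p-value pG in (0, 1].
#' @export
combinePG <- function(pNDE, pPERT) {
  if (any(pNDE <= 0 | pNDE > 1) || any(pPERT <= 0 | pPERT > 1))
    stop("p-values must lie in (0, 1]")
  cc <- pNDE * pPERT
  cc - cc * log(cc)
}

#' Topological pathway impact analysis over a DE table
#'
#' For every pathway: restricts to genes in the expressed universe, builds
#' the DE fold-change vector, solves the perturbation system, bootstraps
#' pPERT, computes hypergeometric pNDE, combines them into pG and
#' BH-adjusts across pathways. Pathways with a numerically singular
#' propagation system are excluded with a warning and flagged.
#'
#' @param pathways list of \linkS4class{PathwayTopology}.
#' @param deTable output of \code{\link{callDE}}.
#' @param universe character vector, the reliably expressed genes.
#' @param fdrAlpha significance level on BH-adjusted pG (default 0.05).
#' @param nBoot bootstrap draws for pPERT.
#' @param seed RNG seed (recorded in report provenance).
#' @return data.frame sorted by ascending pG with columns pathway_id,
#'   name, path_size, n_de, tA, pNDE, pPERT, pG, pG_fdr, status.
#' @export
analyzePathways <- function(pathways, deTable, universe,
                            fdrAlpha = 0.05, nBoot = 2000, seed = 1) {
  deGenes <- deTable$gene[deTable$significant]
  deLfc <- stats::setNames(deTable$log2_fold_change[deTable$significant],
                           deGenes)
  deGenes <- intersect(deGenes, universe)
  rows <- list()
  for (i in seq_along(pathways)) {
    pw <- pathways[[i]]
    inUni <- intersect(pw@genes, universe)
    if (!length(inUni)) {
      warning("pathway '", pw@pathwayId,
              "' shares no gene with the universe; skipped")
      next
    }
    deltaE <- stats::setNames(numeric(length(pw@genes)), pw@genes)
    hit <- intersect(pw@genes, deGenes)
    deltaE[hit] <- deLfc[hit]
    res <- tryCatch(
      pathwayPerturbationP(pw, unname(deltaE), nBoot = nBoot,
                           seed = childSeed(seed, i)),
      error = function(e) {
        warning("pathway '", pw@pathwayId, "' excluded: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    pNDE <- pathwayEnrichmentP(length(hit), length(inUni),
                               length(deGenes), length(universe))
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = pw@pathwayId, name = pw@name,
      path_size = length(inUni), n_de = length(hit),
      tA = res$tA, pNDE = pNDE, pPERT = res$pPERT,
      pG = combinePG(pNDE, res$pPERT),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pathway_id = character(), name = character(),
                      path_size = integer(), n_de = integer(),
                      tA = numeric(), pNDE = numeric(), pPERT = numeric(),
                      pG = numeric(), pG_fdr = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$pG_fdr <- stats::p.adjust(out$pG, method = "BH")
  out$status <- ifelse(out$pG_fdr < fdrAlpha,
                       ifelse(out$tA > 0, "activated",
                              ifelse(out$tA < 0, "inhibited", "none")),
                       "none")
  out[order(out$pG), , drop = FALSE]
}
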