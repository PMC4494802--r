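#' Default simulation conditions
#'
#' One place for the synthetic-cohort conditions used across the package:
#' a desk-scale breast-cancer-like cohort with lognormal gene abundances
#' (median 100 counts), gamma-distributed NB dispersions (mean 0.05),
#' lognormal sequencing-depth multipliers, 5% background genes, 50 spiked
#' genes at |log2 fold change| 3 restricted to expressed genes
#' (normal mean >= 50), a 4-class subtype structure and 20 random
#' pathway topologies.
#'
#' @param ... overrides for any listed field.
#' @return named list of simulation parameters.
#' @export
simulationConfig <- function(...) {
  utils::modifyList(list(
    nGenes = 6000L, nTumor = 40L, nNormal = 20L,
    backgroundFraction = 0.05,
    depthSdLog = 0.25,
    meanLog = log(100), sdLog = 1,
    dispShape = 2, dispScale = 0.025,
    nSpikes = 50L, spikeLfc = 3, spikeUpFraction = 0.6,
    spikeMinMean = 50,
    classes = c("Basal", "Her2", "LumA", "LumB"),
    nClassMarkers = 30L, classShift = 2,
    nPathways = 20L, pathwaySizeRange = c(10L, 40L),
    edgeDensity = 0.08, activationProb = 0.8,
    seed = 1L), list(...))
}

#' Simulate a reference cohort with known ground truth
#'
#' Counts are negative binomial (variance mu + alpha mu^2) around
#' per-gene means scaled by per-sample depth multipliers (the true size
#' factors). A fixed fraction of genes is forced to zero in every sample
#' (background). Optionally, tumor samples carry a class structure: class
#' marker genes have their mean multiplied by 2^classShift in the marker's
#' class.
#'
#' @param config list from \code{\link{simulationConfig}}.
#' @param depthMultipliers optional explicit per-sample depth multipliers.
#' @param withClasses simulate subtype labels and marker shifts on tumor
#'   samples.
#' @param geneIds optional gene identifiers (default g0001...).
#' @return list(counts, sampleGroup, classLabels, truth) where truth holds
#'   depthMultipliers, backgroundGenes, geneMeans, geneDispersions and
#'   markerGenes.
#' @export
simulateReference <- function(config = simulationConfig(),
                              depthMultipliers = NULL,
                              withClasses = FALSE, geneIds = NULL) {
  cf <- config
  nS <- cf$nTumor + cf$nNormal
  if (cf$nNormal < 2L) stop("need at least 2 normal samples")
  if (cf$backgroundFraction < 0 || cf$backgroundFraction >= 1)
    stop("backgroundFraction must lie in [0, 1)")
  if (!is.null(depthMultipliers) && length(depthMultipliers) != nS)
    stop("depthMultipliers must have one entry per sample")
  set.seed(cf$seed)
  genes <- geneIds %||% sprintf("g%04d", seq_len(cf$nGenes))
  if (length(genes) != cf$nGenes) stop("geneIds must match nGenes")
  samples <- c(sprintf("tumor%03d", seq_len(cf$nTumor)),
               sprintf("normal%03d", seq_len(cf$nNormal)))
  group <- rep(c("tumor", "normal"), c(cf$nTumor, cf$nNormal))
  mu <- stats::rlnorm(cf$nGenes, cf$meanLog, cf$sdLog)
  alpha <- stats::rgamma(cf$nGenes, shape = cf$dispShape,
                         scale = cf$dispScale)
  nBg <- floor(cf$backgroundFraction * cf$nGenes)
  bgIdx <- sample.int(cf$nGenes, nBg)
  mu[bgIdx] <- 0
  if (is.null(depthMultipliers))
    depthMultipliers <- stats::rlnorm(nS, 0, cf$depthSdLog)
  labels <- rep(NA_character_, nS)
  markers <- data.frame(gene = character(), class = character(),
                        stringsAsFactors = FALSE)
  muMat <- outer(mu, depthMultipliers)
  if (withClasses) {
    labels[group == "tumor"] <-
      rep_len(cf$classes, cf$nTumor)[sample.int(cf$nTumor)]
    eligible <- setdiff(order(-mu), bgIdx)[seq_len(cf$nClassMarkers)]
    markers <- data.frame(gene = genes[eligible],
                          class = rep_len(cf$classes, cf$nClassMarkers),
                          stringsAsFactors = FALSE)
    for (i in seq_len(cf$nClassMarkers)) {
      inClass <- which(!is.na(labels) & labels == markers$class[i])
      muMat[eligible[i], inClass] <-
        muMat[eligible[i], inClass] * 2^cf$classShift
    }
  }
  counts <- matrix(stats::rnbinom(cf$nGenes * nS, mu = muMat,
                                  size = rep(1 / alpha, nS)),
                   cf$nGenes, nS, dimnames = list(genes, samples))
  counts[bgIdx, ] <- 0
  list(counts = counts, sampleGroup = group, classLabels = labels,
       truth = list(depthMultipliers = depthMultipliers,
                    backgroundGenes = genes[bgIdx],
                    geneMeans = stats::setNames(mu, genes),
                    geneDispersions = stats::setNames(alpha, genes),
                    markerGenes = markers))
}

#' Simulate one patient sample from a normal model
#'
#' Draws NB counts around \code{means * depth}, with spiked genes shifted
#' by their stated log2 fold change; all other genes behave as null.
#'
#' @param means named per-gene means (ground-truth or frozen normal means).
#' @param dispersions named per-gene dispersions, aligned to means.
#' @param spikes data.frame(gene, lfc) or NULL.
#' @param depth patient depth multiplier (true size factor).
#' @param seed RNG seed.
#' @return list(counts = named integer vector, spikes).
#' @export
simulatePatient <- function(means, dispersions, spikes = NULL,
                            depth = 1, seed = 1) {
  if (length(means) != length(dispersions))
    stop("means and dispersions must be aligned")
  mu <- means * depth
  if (!is.null(spikes) && nrow(spikes)) {
    bad <- setdiff(spikes$gene, names(means))
    if (length(bad)) stop("spiked gene not in the model: ", bad[1L])
    mu[spikes$gene] <- mu[spikes$gene] * 2^spikes$lfc
  }
  set.seed(seed)
  cnt <- stats::rnbinom(length(mu), mu = mu,
                        size = 1 / pmax(dispersions, 1e-12))
  cnt[mu == 0] <- 0L
  list(counts = stats::setNames(as.numeric(cnt), names(means)),
       spikes = spikes)
}

#' Pick spiked genes for a patient simulation
#'
#' Spikes are restricted to expressed genes (normal mean at or above
#' \code{spikeMinMean}), reflecting that recurrently dysregulated cancer
#' genes are expressed genes.
#'
#' @param means named per-gene normal means.
#' @param config simulation config (nSpikes, spikeLfc, spikeUpFraction,
#'   spikeMinMean).
#' @param seed RNG seed.
#' @return data.frame(gene, lfc).
#' @export
pickSpikes <- function(means, config = simulationConfig(), seed = 1) {
  eligible <- names(means)[means >= config$spikeMinMean]
  if (length(eligible) < config$nSpikes)
    stop("not enough expressed genes to spike")
  set.seed(seed)
  genes <- sample(eligible, config$nSpikes)
  nUp <- round(config$spikeUpFraction * config$nSpikes)
  data.frame(gene = genes,
             lfc = rep(c(config$spikeLfc, -config$spikeLfc),
                       c(nUp, config$nSpikes - nUp)),
             stringsAsFactors = FALSE)
}

#' Simulate a labeled log-expression cohort for classifier tests
#'
#' Gaussian log2 expression with unit within-class SD; each of
#' \code{nShifted} marker genes is assigned one class (round-robin) whose
#' mean is shifted by \code{shiftSD} pooled standard deviations.
#'
#' @param nGenes,nPerClass,nShifted,shiftSD design parameters.
#' @param classes class labels.
#' @param seed RNG seed.
#' @param baseline optional per-gene baseline means; pass the
#'   \code{baseline} of a training cohort to draw held-out samples from
#'   the same population (otherwise a new baseline is drawn).
#' @return list(X = samples x genes matrix, y = labels, markers,
#'   baseline).
#' @export
simulateClassCohort <- function(nGenes = 500, classes = c("A", "B", "C",
                                                          "D"),
                                nPerClass = 40, nShifted = 30,
                                shiftSD = 2, seed = 1,
                                baseline = NULL) {
  set.seed(seed)
  K <- length(classes)
  n <- K * nPerClass
  y <- rep(classes, each = nPerClass)
  base <- baseline %||% stats::rnorm(nGenes, 7, 1.5)
  if (length(base) != nGenes)
    stop("baseline must have one mean per gene")
  X <- matrix(stats::rnorm(n * nGenes), n, nGenes) +
    matrix(base, n, nGenes, byrow = TRUE)
  colnames(X) <- sprintf("g%04d", seq_len(nGenes))
  rownames(X) <- sprintf("s%03d", seq_len(n))
  markerClass <- rep_len(classes, nShifted)
  for (j in seq_len(nShifted))
    X[y == markerClass[j], j] <- X[y == markerClass[j], j] + shiftSD
  list(X = X, y = y,
       markers = data.frame(gene = colnames(X)[seq_len(nShifted)],
                            class = markerClass,
                            stringsAsFactors = FALSE),
       baseline = base)
}

#' Simulate pathway topologies, optionally with a planted signal pathway
#'
#' Random pathways draw genes from the universe and directed signed edges
#' at the configured density (activation with probability
#' \code{activationProb}). When \code{plantedGenes} is given, an extra
#' pathway "PW_PLANTED" is built over those genes with an upstream hub
#' (the first gene) activating every other member plus a forward
#' activation chain, so coordinated positive fold changes on its members
#' propagate into a large positive net perturbation.
#'
#' @param universe character vector of gene identifiers to draw from.
#' @param config simulation config (nPathways, pathwaySizeRange,
#'   edgeDensity, activationProb).
#' @param plantedGenes optional character vector of genes for the planted
#'   pathway.
#' @param seed RNG seed.
#' @return list(edges = data.frame(pathway_id, source_gene, target_gene,
#'   interaction), plantedId).
#' @export
simulatePathways <- function(universe, config = simulationConfig(),
                             plantedGenes = NULL, seed = 1) {
  set.seed(seed)
  edges <- list()
  addEdges <- function(id, src, tgt, act) {
    edges[[length(edges) + 1L]] <<- data.frame(
      pathway_id = id, source_gene = src, target_gene = tgt,
      interaction = ifelse(act, "activation", "inhibition"),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(config$nPathways)) {
    size <- sample(config$pathwaySizeRange[1L]:config$pathwaySizeRange[2L],
                   1L)
    genes <- sample(universe, size)
    nEdges <- max(size - 1L,
                  round(config$edgeDensity * size * (size - 1L)))
    src <- sample(genes, nEdges, replace = TRUE)
    tgt <- sample(genes, nEdges, replace = TRUE)
    keep <- src != tgt
    dup <- duplicated(paste(src, tgt))
    keep <- keep & !dup
    if (!any(keep)) { keep[1L] <- src[1L] != tgt[1L] }
    addEdges(sprintf("PW%03d", i), src[keep], tgt[keep],
             stats::runif(sum(keep)) < config$activationProb)
  }
  plantedId <- NULL
  if (!is.null(plantedGenes) && length(plantedGenes) >= 3L) {
    plantedId <- "PW_PLANTED"
    hub <- plantedGenes[1L]
    rest <- plantedGenes[-1L]
    addEdges(plantedId, rep(hub, length(rest)), rest, TRUE)
    addEdges(plantedId, rest[-length(rest)], rest[-1L], TRUE)
  }
  list(edges = do.call(rbind, edges), plantedId = plantedId)
}

# The fixed toy clinical fixture: 6 SNVs whose filtering, annotation and
# drug-rule outcomes are hand-enumerable. Returned alongside the files so
# tests can assert the expected outcomes without re-deriving them.
toyClinicalSpec <- function() {
  variants <- data.frame(
    chrom = c("chr7", "chr17", "chr3", "chr13", "chr17", "chr12"),
    pos = c(55259515L, 7577120L, 178936091L, 32914438L, 41245466L,
            25398284L),
    ref = c("T", "C", "G", "T", "G", "C"),
    alt = c("G", "T", "A", "C", "A", "A"),
    gene = c("EGFR", "TP53", "PIK3CA", "BRCA2", "BRCA1", "KRAS"),
    effect = c("missense", "missense", "missense", "synonymous",
               "missense", "missense"),
    maf = c(0.01, 0.2, 0.5, NA, 0.09, 0.01),
    common = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  variants$key <- variantKey(variants$chrom, variants$pos, variants$ref,
                             variants$alt)
  retained <- variants$key[c(1L, 4L, 5L)]
  removed <- stats::setNames(c("maf", "maf", "common-flag"),
                             variants$key[c(2L, 3L, 6L)])
  # exactly 3 attachments on the retained variants:
  # cosmic hits v1, clinvar hits v4, cadd hits v5; allele mismatches and
  # entries on removed variants must never attach
  cosmic <- data.frame(
    chrom = c("7", "17", "17"), pos = c(55259515L, 41245466L, 7577120L),
    ref = c("T", "G", "C"), alt = c("G", "C", "T"),
    cosmic_id = c("COSM6224", "COSM0001", "COSM10704"),
    histology = c("carcinoma", "carcinoma", "carcinoma"),
    stringsAsFactors = FALSE)
  clinvar <- data.frame(
    chrom = c("13", "7"), pos = c(32914438L, 55259515L),
    ref = c("T", "A"), alt = c("C", "G"),
    significance = c("Pathogenic", "Benign"),
    stringsAsFactors = FALSE)
  cadd <- data.frame(
    chrom = c("17", "2"), pos = c(41245466L, 1000L),
    ref = c("G", "C"), alt = c("A", "T"),
    cadd_phred = c(25.1, 3.2), stringsAsFactors = FALSE)
  rules <- data.frame(
    chrom = c("7", "17"), pos = c(55259515L, 7577120L),
    ref = c("T", "C"), alt = c("G", "T"),
    drug_id = c("DB010", "DB011"),
    drug_name = c("Afatinib", "Adavosertib"),
    stringsAsFactors = FALSE)
  list(variants = variants, retainedKeys = retained,
       removedReasons = removed,
       tables = list(cosmic = cosmic, clinvar = clinvar, cadd = cadd,
                     drug_variant_rules = rules),
       expectedAttachments = data.frame(
         key = c(variants$key[1L], variants$key[4L], variants$key[5L]),
         table = c("cosmic", "clinvar", "cadd"),
         stringsAsFactors = FALSE),
       expectedVariantMatches = data.frame(
         drug_id = "DB010", key = variants$key[1L],
         stringsAsFactors = FALSE))
}

toyDrugTable <- function() {
  data.frame(
    drug_id = c("DB001", "DB002", "DB003", "DB004", "DB005", "DB010"),
    name = c("Trastuzumab", "Tamoxifen", "Dexamethasone", "Alpelisib",
             "Investigationib", "Afatinib"),
    approved = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    targets = c("ERBB2:antibody", "ESR1:antagonist", "NR3C1:agonist",
                "PTEN:inhibitor", "ERBB2:antibody", "EGFR:inhibitor"),
    pathway_ids = c("PW_PLANTED", "", "", "", "PW_PLANTED", ""),
    source = rep("synthetic-fixture", 6L),
    stringsAsFactors = FALSE)
}

toyFusionTable <- function() {
  data.frame(
    gene_5p = c("BCAS4", "TMPRSS2", "NOTCH1", "EML4"),
    gene_3p = c("BCAS3", "ERG", "NUP214", "ALK"),
    description = c("known in breast cancer lines", "read-through-like",
                    NA, "kinase fusion"),
    oncogenic_p = c(0.02, 0.6, NA, 0.001),
    expression_gain_loss = c(1.4, -0.2, NA, 2.1),
    stringsAsFactors = FALSE)
}

writeToyVCF <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=nof1seq-synthetic-fixture",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Predicted effect\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%.0f\tPASS\tGENE=%s;EFFECT=%s",
                  variants$chrom, variants$pos, variants$ref,
                  variants$alt, 60 + seq_len(nrow(variants)),
                  variants$gene, variants$effect)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the toy annotation bundle, VCF, drug and fusion tables
#'
#' Emits the hand-enumerable clinical fixture (synthetic throughout): a
#' 6-variant VCF, the annotation bundle TSVs (common flags, population
#' MAF, COSMIC-like, ClinVar-like, CADD-like, variant-drug rules), a drug
#' metadata table and a fusion candidate table. Of the 6 variants exactly
#' 3 survive the filter and exactly 3 clinical annotations attach.
#'
#' @param dir output directory.
#' @return the fixture description from the internal spec (variant table,
#'   expected retained keys, removal reasons, expected attachments and
#'   variant-drug matches), invisibly.
#' @export
makeAnnotationTables <- function(dir) {
  spec <- toyClinicalSpec()
  bundleDir <- file.path(dir, "annotation_bundle")
  dir.create(bundleDir, recursive = TRUE, showWarnings = FALSE)
  v <- spec$variants
  writeTSV(v[v$common, c("chrom", "pos", "ref", "alt")],
           file.path(bundleDir, "common_variants.tsv"))
  m <- v[!is.na(v$maf), c("chrom", "pos", "ref", "alt", "maf")]
  writeTSV(m, file.path(bundleDir, "population_maf.tsv"))
  for (nm in names(spec$tables))
    writeTSV(spec$tables[[nm]], file.path(bundleDir, paste0(nm, ".tsv")))
  writeToyVCF(v, file.path(dir, "patient.vcf"))
  writeTSV(toyDrugTable(), file.path(dir, "drugs.tsv"))
  writeTSV(toyFusionTable(), file.path(dir, "fusions.tsv"))
  invisible(spec)
}

#' Generate a complete demo input directory
#'
#' Simulates the reference cohort (with subtype structure on the tumor
#' samples), a patient sample with 50 spiked genes (a handful renamed to
#' real drug-target symbols so the drug-matching demo is meaningful), the
#' pathway edge list with a planted activated pathway over up-spiked
#' genes, and the toy clinical fixture. Everything a
#' \code{build-ref} + \code{analyze} run needs, with ground truth in
#' \code{truth.json}.
#'
#' @param dir output directory.
#' @param seed master RNG seed; every draw derives from it.
#' @param config simulation config overrides (see
#'   \code{\link{simulationConfig}}).
#' @return invisible list of ground truth (spikes, planted pathway id,
#'   marker genes, depth multipliers).
#' @export
makeFixtures <- function(dir, seed = 1, config = simulationConfig()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cf <- utils::modifyList(config, list(seed = childSeed(seed, 1L)))
  sim <- simulateReference(cf, withClasses = TRUE)
  genes <- rownames(sim$counts)
  means <- sim$truth$geneMeans
  # rename a few eligible genes to the fixture drug-target symbols
  symbols <- c("ERBB2", "ESR1", "EGFR", "NR3C1", "PTEN")
  eligible <- setdiff(names(means)[means >= cf$spikeMinMean],
                      sim$truth$markerGenes$gene)
  stopifnot(length(eligible) >= length(symbols))
  renamed <- eligible[seq_along(symbols)]
  genes[match(renamed, genes)] <- symbols
  rownames(sim$counts) <- genes
  names(means) <- genes
  names(sim$truth$geneDispersions) <- genes
  sim$truth$backgroundGenes <- genes[match(sim$truth$backgroundGenes,
                                           names(sim$truth$geneMeans))]
  sim$truth$geneMeans <- means
  # spikes: named symbols first (up: ERBB2, ESR1, EGFR; down: NR3C1,
  # PTEN), the rest drawn from eligible genes
  auto <- pickSpikes(means[setdiff(names(means), symbols)],
                     utils::modifyList(cf, list(nSpikes = cf$nSpikes - 5L)),
                     seed = childSeed(seed, 2L))
  spikes <- rbind(data.frame(gene = symbols,
                             lfc = c(3, 3, 3, -3, -3),
                             stringsAsFactors = FALSE), auto)
  patient <- simulatePatient(means, sim$truth$geneDispersions, spikes,
                             depth = 1.3, seed = childSeed(seed, 3L))
  upSpiked <- spikes$gene[spikes$lfc > 0]
  planted <- c("ERBB2", setdiff(utils::head(upSpiked, 10L), "ERBB2"))
  pw <- simulatePathways(setdiff(genes, sim$truth$backgroundGenes), cf,
                         plantedGenes = planted,
                         seed = childSeed(seed, 4L))
  writeTSV(data.frame(gene_id = genes, sim$counts,
                      check.names = FALSE),
           file.path(dir, "cohort_counts.tsv"))
  writeTSV(data.frame(sample_id = colnames(sim$counts),
                      group = sim$sampleGroup,
                      subtype = sim$classLabels,
                      stringsAsFactors = FALSE),
           file.path(dir, "sample_metadata.tsv"))
  writeTSV(data.frame(gene_id = genes,
                      patient01 = patient$counts[genes],
                      stringsAsFactors = FALSE),
           file.path(dir, "patient_counts.tsv"))
  writeTSV(pw$edges, file.path(dir, "pathways.tsv"))
  clin <- makeAnnotationTables(dir)
  truth <- list(seed = seed, spikes = spikes,
                planted_pathway = pw$plantedId,
                patient_depth = 1.3,
                depth_multipliers = sim$truth$depthMultipliers,
                background_genes = sim$truth$backgroundGenes,
                marker_genes = sim$truth$markerGenes,
                retained_variant_keys = clin$retainedKeys)
  writeLines(jsonlite::toJSON(truth, digits = NA, auto_unbox = TRUE,
                              null = "null"),
             file.path(dir, "truth.json"))
  invisible(truth)
}
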