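#' Per-gene geometric means of a count matrix
#'
#' Computes the median-of-ratios pseudo-reference: for each gene the
#' geometric mean of its counts across all cohort samples,
#' \code{exp(mean(log(counts)))}. Any zero count forces the geometric mean
#' to 0 (the standard convention, so such genes are excluded from ratio
#' medians downstream).
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return numeric vector, one non-negative value per gene (named when
#'   \code{counts} has rownames).
#' @examples
#' computeGeometricMeans(rbind(a = c(4, 9), b = c(0, 50)))
#' @export
computeGeometricMeans <- function(counts) {
  counts <- as.matrix(counts)
  if (!length(counts) || ncol(counts) < 1L)
    stop("counts must be a non-empty genes x samples matrix")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative")
  gm <- exp(rowMeans(log(counts)))
  gm[apply(counts == 0, 1L, any)] <- 0
  gm
}

#' Median-of-ratios size factors for cohort samples
#'
#' For each sample, the size factor is the median of
#' \code{count / geoMean} over genes with positive geometric mean and
#' positive count in that sample.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @param geoMeans per-gene geometric means aligned to \code{counts} rows.
#' @return numeric vector of positive size factors, one per sample.
#' @export
computeSizeFactors <- function(counts, geoMeans) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(geoMeans))
    stop("geoMeans must align with the rows of counts")
  vapply(seq_len(ncol(counts)), function(s) {
    cnt <- counts[, s]
    ok <- geoMeans > 0 & cnt > 0
    if (!any(ok))
      stop("size factor undefined for sample '",
           colnames(counts)[s] %||% s,
           "': no gene with positive count and positive geometric mean")
    stats::median(cnt[ok] / geoMeans[ok])
  }, numeric(1))
}

#' Background genes: zero raw counts in every cohort sample
#'
#' Genes never observed in the reference cohort define the noise floor of
#' expression; the patient's values on these genes set the reliability
#' cutoff.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return character vector of gene identifiers (or integer indices when
#'   the matrix has no rownames).
#' @export
identifyBackgroundGenes <- function(counts) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative")
  idx <- rowSums(counts != 0) == 0L
  if (is.null(rownames(counts))) which(idx) else rownames(counts)[idx]
}

#' Negative-binomial parameters of the normal-tissue samples
#'
#' Size-factor-normalizes the cohort and, over the normal samples,
#' estimates a per-gene mean and a method-of-moments dispersion
#' \code{max((var - mean) / mean^2, dispersionFloor)} (variance
#' parameterization \code{mu + alpha * mu^2}). Genes with zero normal mean
#' get mean 0 and the floor dispersion.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @param geoMeans per-gene geometric means.
#' @param sampleGroup character per sample, "tumor" or "normal".
#' @param dispersionFloor smallest dispersion retained; keeps the NB
#'   well-defined and approximates Poisson when data are underdispersed.
#' @return list with numeric vectors \code{mean} and \code{dispersion}.
#' @export
fitNormalParams <- function(counts, geoMeans, sampleGroup,
                            dispersionFloor = 1e-8) {
  counts <- as.matrix(counts)
  if (length(sampleGroup) != ncol(counts))
    stop("sampleGroup must have one entry per sample")
  normIdx <- sampleGroup == "normal"
  if (sum(normIdx) < 2L)
    stop("at least 2 normal samples are required to fit normal parameters")
  sf <- computeSizeFactors(counts, geoMeans)
  norm <- sweep(counts[, normIdx, drop = FALSE], 2L, sf[normIdx], "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  disp <- ifelse(mu > 0, pmax((v - mu) / mu^2, dispersionFloor),
                 dispersionFloor)
  mu[mu < 0] <- 0
  list(mean = mu, dispersion = disp)
}

#' Build a frozen reference from a cohort count matrix
#'
#' Runs the full "documentation by value" reduction: geometric means,
#' background gene set, joint size-factor normalization, normal-tissue NB
#' parameters, and packaging of any trained classifiers.
#'
#' @param counts non-negative matrix, genes x samples, with rownames.
#' @param sampleGroup character per sample, "tumor" or "normal".
#' @param classifiers optional named list of \linkS4class{CentroidModel}.
#' @param provenance optional list of extra metadata to record.
#' @param dispersionFloor see \code{\link{fitNormalParams}}.
#' @return a \linkS4class{FrozenReference}.
#' @export
buildFrozenReference <- function(counts, sampleGroup,
                                 classifiers = list(),
                                 provenance = list(),
                                 dispersionFloor = 1e-8) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have gene identifiers as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers")
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers")
  if (length(sampleGroup) != ncol(counts))
    stop("sampleGroup must have one entry per sample")
  gm <- computeGeometricMeans(counts)
  bg <- identifyBackgroundGenes(counts)
  np <- fitNormalParams(counts, gm, sampleGroup,
                        dispersionFloor = dispersionFloor)
  prov <- utils::modifyList(list(
    format_version = "1.0",
    n_samples = ncol(counts),
    n_tumor = sum(sampleGroup == "tumor"),
    n_normal = sum(sampleGroup == "normal"),
    n_genes = nrow(counts),
    n_background = length(bg),
    dispersion_floor = dispersionFloor,
    built = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), provenance)
  methods::new("FrozenReference",
               geneIds = rownames(counts),
               geoMeans = unname(gm),
               backgroundGenes = bg,
               normalMeans = unname(np$mean),
               normalDispersions = unname(np$dispersion),
               classifiers = classifiers,
               provenance = prov)
}

FROZEN_FORMAT_VERSION <- "1.0"

centroidModelToList <- function(m) {
  list(name = m@name, classes = m@classes, gene_ids = m@geneIds,
       overall_centroid = m@overallCentroid,
       class_centroids = as.vector(m@classCentroids),
       shrunken_centroids = as.vector(m@shrunkenCentroids),
       pooled_sd = m@pooledSD, s0 = m@s0, mk = m@mk,
       priors = m@priors, delta = m@delta,
       selected_genes = m@selectedGenes, cv = m@cv)
}

centroidModelFromList <- function(l) {
  p <- length(l$gene_ids); K <- length(l$classes)
  mk <- function(v, nr, nc) matrix(as.numeric(v), nr, nc,
                                   dimnames = list(l$gene_ids, l$classes))
  methods::new("CentroidModel",
               name = l$name, classes = as.character(l$classes),
               geneIds = as.character(l$gene_ids),
               overallCentroid = as.numeric(l$overall_centroid),
               classCentroids = mk(l$class_centroids, p, K),
               shrunkenCentroids = mk(l$shrunken_centroids, p, K),
               pooledSD = as.numeric(l$pooled_sd),
               s0 = as.numeric(l$s0),
               mk = stats::setNames(as.numeric(l$mk), l$classes),
               priors = stats::setNames(as.numeric(l$priors), l$classes),
               delta = as.numeric(l$delta),
               selectedGenes = as.character(l$selected_genes %||% character()),
               cv = as.list(l$cv %||% list()))
}

#' Serialize a frozen reference to a versioned archive
#'
#' Writes a single self-describing JSON document with an explicit format
#' version so the clinical artifact is stable across releases. Doubles are
#' written at full precision; \code{thawReference(freezeReference(x))}
#' reproduces every field exactly.
#'
#' @param ref a \linkS4class{FrozenReference}.
#' @param path output file path (conventionally \code{.frz.json}).
#' @return \code{path}, invisibly.
#' @export
freezeReference <- function(ref, path) {
  stopifnot(methods::is(ref, "FrozenReference"))
  doc <- list(
    format = "nof1seq-frozen-reference",
    format_version = FROZEN_FORMAT_VERSION,
    gene_ids = ref@geneIds,
    geo_means = ref@geoMeans,
    background_genes = ref@backgroundGenes,
    normal_means = ref@normalMeans,
    normal_dispersions = ref@normalDispersions,
    classifiers = lapply(ref@classifiers, centroidModelToList),
    provenance = ref@provenance
  )
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Load a frozen reference from disk
#'
#' @param path file written by \code{\link{freezeReference}}.
#' @return a \linkS4class{FrozenReference}.
#' @export
thawReference <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e)
                    stop("cannot load frozen reference from '", path,
                         "': ", conditionMessage(e)))
  if (!identical(doc$format, "nof1seq-frozen-reference"))
    stop("'", path, "' is not a frozen reference archive")
  if (!identical(doc$format_version, FROZEN_FORMAT_VERSION))
    stop("frozen reference format version '", doc$format_version,
         "' does not match supported version '", FROZEN_FORMAT_VERSION, "'")
  need <- c("gene_ids", "geo_means", "background_genes", "normal_means",
            "normal_dispersions")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("frozen reference is missing field(s): ",
         paste(miss, collapse = ", "))
  methods::new("FrozenReference",
               geneIds = as.character(doc$gene_ids),
               geoMeans = as.numeric(doc$geo_means),
               backgroundGenes = as.character(unlist(doc$background_genes) %||%
                                              character()),
               normalMeans = as.numeric(doc$normal_means),
               normalDispersions = as.numeric(doc$normal_dispersions),
               classifiers = lapply(doc$classifiers %||% list(),
                                    centroidModelFromList),
               provenance = as.list(doc$provenance %||% list()))
}
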