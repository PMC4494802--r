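#' @import methods
NULL

#' Frozen reference for n-of-1 add-on processing
#'
#' A \code{FrozenReference} captures, by value, everything later pipeline
#' stages need from a reference cohort: per-gene geometric means of raw
#' counts (the median-of-ratios pseudo-reference), the background gene set
#' (genes with zero raw counts in every cohort sample, used as a noise
#' floor), per-gene negative-binomial parameters of the normal-tissue
#' samples, and any trained \linkS4class{CentroidModel} classifiers.
#' Once frozen, a new patient sample can be processed identically at any
#' later time without access to the cohort itself.
#'
#' @slot geneIds character, ordered gene identifiers (no duplicates).
#' @slot geoMeans numeric, per-gene geometric mean of raw cohort counts;
#'   genes with any zero count in the cohort have geometric mean 0.
#' @slot backgroundGenes character, genes with zero raw count in every
#'   cohort sample.
#' @slot normalMeans numeric, per-gene mean of size-factor-normalized
#'   counts over the normal-tissue samples.
#' @slot normalDispersions numeric, per-gene negative-binomial dispersion
#'   (variance = mu + alpha * mu^2), floored at a small positive value.
#' @slot classifiers list of \linkS4class{CentroidModel} objects, named.
#' @slot provenance list of free-form metadata (cohort size, build date,
#'   format version).
#'
#' @seealso \code{\link{buildFrozenReference}}, \code{\link{freezeReference}}
#' @export
setClass("FrozenReference",
  representation(
    geneIds = "character",
    geoMeans = "numeric",
    backgroundGenes = "character",
    normalMeans = "numeric",
    normalDispersions = "numeric",
    classifiers = "list",
    provenance = "list"
  )
)

setValidity("FrozenReference", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "duplicate gene identifiers")
  if (length(object@geoMeans) != n)
    msg <- c(msg, "geoMeans length does not match geneIds")
  if (length(object@normalMeans) != n)
    msg <- c(msg, "normalMeans length does not match geneIds")
  if (length(object@normalDispersions) != n)
    msg <- c(msg, "normalDispersions length does not match geneIds")
  if (any(object@geoMeans < 0, na.rm = TRUE))
    msg <- c(msg, "geoMeans must be non-negative")
  if (any(object@normalMeans < 0, na.rm = TRUE))
    msg <- c(msg, "normalMeans must be non-negative")
  if (any(object@normalDispersions < 0, na.rm = TRUE))
    msg <- c(msg, "normalDispersions must be non-negative")
  if (!all(object@backgroundGenes %in% object@geneIds))
    msg <- c(msg, "backgroundGenes must be a subset of geneIds")
  bg <- match(object@backgroundGenes, object@geneIds)
  if (length(bg) && any(object@geoMeans[bg] != 0))
    msg <- c(msg, "background genes must have geometric mean 0")
  if (length(object@classifiers) &&
      !all(vapply(object@classifiers, is, logical(1), "CentroidModel")))
    msg <- c(msg, "classifiers must all be CentroidModel objects")
  if (length(msg)) msg else TRUE
})

#' Normalized expression profile of one patient sample
#'
#' Holds the raw counts of a single new sample together with its add-on
#' size factor relative to a \linkS4class{FrozenReference}, the normalized
#' and log2(x + 1) expression values, the background-derived expression
#' reliability cutoff, and the set of reliably expressed genes (strictly
#' above the cutoff).
#'
#' @slot patientId character(1).
#' @slot geneIds character, the reference gene universe.
#' @slot rawCounts numeric, per-gene raw counts aligned to \code{geneIds}.
#' @slot sizeFactor numeric(1), median-of-ratios scaling factor.
#' @slot normCounts numeric, \code{rawCounts / sizeFactor}.
#' @slot logExpr numeric, \code{log2(normCounts + 1)}.
#' @slot expressionCutoff numeric(1), reliability cutoff on the log2 scale.
#' @slot reliableGenes character, genes with \code{logExpr > expressionCutoff}.
#'
#' @seealso \code{\link{buildPatientProfile}}
#' @export
setClass("PatientProfile",
  representation(
    patientId = "character",
    geneIds = "character",
    rawCounts = "numeric",
    sizeFactor = "numeric",
    normCounts = "numeric",
    logExpr = "numeric",
    expressionCutoff = "numeric",
    reliableGenes = "character"
  )
)

setValidity("PatientProfile", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (length(object@patientId) != 1L)
    msg <- c(msg, "patientId must be a single string")
  if (length(object@rawCounts) != n || length(object@normCounts) != n ||
      length(object@logExpr) != n)
    msg <- c(msg, "count/expression vectors must match geneIds")
  if (length(object@sizeFactor) != 1L || !is.finite(object@sizeFactor) ||
      object@sizeFactor <= 0)
    msg <- c(msg, "sizeFactor must be a single positive number")
  if (n && max(abs(object@logExpr - log2(object@normCounts + 1))) > 1e-8)
    msg <- c(msg, "logExpr must equal log2(normCounts + 1)")
  above <- object@geneIds[object@logExpr > object@expressionCutoff]
  if (!all(object@reliableGenes %in% above))
    msg <- c(msg, "reliableGenes must all lie strictly above the cutoff")
  if (length(msg)) msg else TRUE
})

#' Nearest-shrunken-centroid classifier
#'
#' A trained nearest-shrunken-centroid (PAM-style) model on log2
#' expression. Class centroids are shrunk towards the overall centroid by
#' soft-thresholding the standardized differences
#' \eqn{d_{kj} = (\bar x_{kj} - \bar x_j) / (m_k (s_j + s_0))} at
#' threshold \eqn{\Delta}; genes whose shrunken difference is nonzero in
#' any class are the selected genes.
#'
#' @slot name character(1), e.g. "ER" or "subtype".
#' @slot classes character, ordered class labels.
#' @slot geneIds character.
#' @slot overallCentroid numeric per gene.
#' @slot classCentroids matrix genes x classes (unshrunk).
#' @slot shrunkenCentroids matrix genes x classes at \code{delta}.
#' @slot pooledSD numeric per gene, pooled within-class SD.
#' @slot s0 numeric(1), median of pooledSD (fudge constant).
#' @slot mk numeric per class, sqrt(1/n_k + 1/n).
#' @slot priors numeric per class, summing to 1.
#' @slot delta numeric(1), shrinkage threshold.
#' @slot selectedGenes character.
#' @slot cv list, cross-validation trace (deltaGrid, error, seed) or empty.
#'
#' @seealso \code{\link{trainCentroidModel}}, \code{\link{shrinkCentroids}}
#' @export
setClass("CentroidModel",
  representation(
    name = "character",
    classes = "character",
    geneIds = "character",
    overallCentroid = "numeric",
    classCentroids = "matrix",
    shrunkenCentroids = "matrix",
    pooledSD = "numeric",
    s0 = "numeric",
    mk = "numeric",
    priors = "numeric",
    delta = "numeric",
    selectedGenes = "character",
    cv = "list"
  )
)

setValidity("CentroidModel", function(object) {
  msg <- character()
  p <- length(object@geneIds)
  K <- length(object@classes)
  if (K < 2L) msg <- c(msg, "at least two classes required")
  if (length(object@priors) != K || abs(sum(object@priors) - 1) > 1e-12)
    msg <- c(msg, "priors must sum to 1")
  if (!identical(dim(object@classCentroids), c(p, K)) ||
      !identical(dim(object@shrunkenCentroids), c(p, K)))
    msg <- c(msg, "centroid matrices must be genes x classes")
  if (length(object@pooledSD) != p || any(object@pooledSD < 0))
    msg <- c(msg, "pooledSD must be non-negative, one per gene")
  if (length(object@delta) != 1L || object@delta < 0)
    msg <- c(msg, "delta must be a single non-negative number")
  if (!all(object@selectedGenes %in% object@geneIds))
    msg <- c(msg, "selectedGenes must be a subset of geneIds")
  if (length(msg)) msg else TRUE
})

#' Class prediction with probabilities
#'
#' @slot label character(1), the predicted class.
#' @slot probabilities numeric per class, summing to 1.
#' @slot discriminants numeric per class, the penalized distances
#'   \eqn{\delta_k(x)} (smaller is closer).
#' @slot flags character, e.g. "uninformative" when no genes survived
#'   shrinkage and the call is by priors alone.
#'
#' @export
setClass("Prediction",
  representation(
    label = "character",
    probabilities = "numeric",
    discriminants = "numeric",
    flags = "character"
  )
)

setValidity("Prediction", function(object) {
  msg <- character()
  if (abs(sum(object@probabilities) - 1) > 1e-9)
    msg <- c(msg, "probabilities must sum to 1")
  if (length(object@label) != 1L ||
      !identical(names(which.max(object@probabilities)), object@label))
    msg <- c(msg, "label must attain the maximum probability")
  if (length(msg)) msg else TRUE
})

#' Signed, weighted pathway topology
#'
#' The gene-gene influence structure of one pathway: \code{beta[i, j]} is
#' the signed weight of the effect of gene j on gene i (+1 activation, -1
#' inhibition by default). \code{nDownstream[j]} counts the targets of
#' gene j and is floored at 1 when propagating so leaf genes do not divide
#' by zero.
#'
#' @slot pathwayId character(1).
#' @slot name character(1).
#' @slot genes character.
#' @slot beta matrix, genes x genes signed weights.
#' @slot nDownstream integer per gene (raw target counts, may be 0).
#'
#' @seealso \code{\link{readPathwayTopologies}}, \code{\link{netPerturbation}}
#' @export
setClass("PathwayTopology",
  representation(
    pathwayId = "character",
    name = "character",
    genes = "character",
    beta = "matrix",
    nDownstream = "integer"
  )
)

setValidity("PathwayTopology", function(object) {
  msg <- character()
  p <- length(object@genes)
  if (!identical(dim(object@beta), c(p, p)))
    msg <- c(msg, "beta must be a square genes x genes matrix")
  if (length(object@nDownstream) != p)
    msg <- c(msg, "nDownstream must have one entry per gene")
  nds <- colSums(object@beta != 0)
  if (p && any(object@nDownstream != nds))
    msg <- c(msg, "nDownstream must equal the number of nonzero beta targets")
  if (length(msg)) msg else TRUE
})

#' Integrated report model
#'
#' The single structured document all rendering works from. Sections that
#' were not run are NULL slots and are rendered as explicit "not run"
#' blocks, never silently dropped. The provenance block (seeds,
#' thresholds, reference provenance, package version) is always present.
#'
#' @slot patient list of patient metadata (id at minimum).
#' @slot provenance list: thresholds, seeds, reference provenance.
#' @slot profileSummary list: size factor, cutoff, reliable gene count.
#' @slot predictions list of \linkS4class{Prediction} objects or NULL.
#' @slot deTable data.frame or NULL.
#' @slot pathways data.frame or NULL.
#' @slot variants data.frame or NULL.
#' @slot fusions data.frame or NULL.
#' @slot drugs list(table=, evidence=) or NULL.
#' @slot qc data.frame or NULL, pass-through quality-control table.
#'
#' @seealso \code{\link{buildReportModel}}, \code{\link{renderReport}}
#' @export
setClass("ReportModel",
  representation(
    patient = "list",
    provenance = "list",
    profileSummary = "list",
    predictions = "ANY",
    deTable = "ANY",
    pathways = "ANY",
    variants = "ANY",
    fusions = "ANY",
    drugs = "ANY",
    qc = "ANY"
  )
)

setValidity("ReportModel", function(object) {
  msg <- character()
  if (is.null(object@patient$patient_id))
    msg <- c(msg, "patient metadata must include patient_id")
  if (!length(object@provenance))
    msg <- c(msg, "provenance block must be present")
  if (length(msg)) msg else TRUE
})
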