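#' Add-on size factor of one patient sample
#'
#' Scales a new sample against the frozen reference exactly as the cohort
#' samples were scaled: the size factor is the median of
#' \code{patientCount / geoMean} over genes with positive geometric mean
#' and positive patient count. By construction, a sample that was part of
#' the cohort recovers its cohort size factor.
#'
#' @param patientCounts named numeric vector of raw counts, or a vector
#'   already aligned to \code{geneIds(ref)}.
#' @param ref a \linkS4class{FrozenReference}.
#' @return a single positive size factor.
#' @export
addonSizeFactor <- function(patientCounts, ref) {
  cnt <- alignToReference(patientCounts, ref)
  gm <- ref@geoMeans
  ok <- gm > 0 & cnt > 0
  if (!any(ok))
    stop("size factor undefined: patient shares no expressed gene ",
         "with the reference")
  stats::median(cnt[ok] / gm[ok])
}

# Match patient genes to the reference universe. Patient genes absent from
# the reference are dropped with a warning; reference genes absent from
# the patient are counted as 0.
alignToReference <- function(patientCounts, ref) {
  if (anyNA(patientCounts) || any(patientCounts < 0))
    stop("patient counts must be non-negative")
  if (is.null(names(patientCounts))) {
    if (length(patientCounts) != length(ref@geneIds))
      stop("unnamed patient counts must align with the reference genes")
    return(as.numeric(patientCounts))
  }
  extra <- setdiff(names(patientCounts), ref@geneIds)
  if (length(extra))
    warning(length(extra), " patient gene(s) absent from the reference ",
            "were dropped (e.g. ", extra[1L], ")")
  out <- stats::setNames(numeric(length(ref@geneIds)), ref@geneIds)
  keep <- intersect(names(patientCounts), ref@geneIds)
  out[keep] <- patientCounts[keep]
  unname(out)
}

#' Log2 transform with pseudocount 1
#'
#' @param x non-negative numeric vector of normalized counts.
#' @return \code{log2(x + 1)} elementwise.
#' @export
log2p1 <- function(x) {
  if (anyNA(x) || any(x < 0)) stop("normalized counts must be non-negative")
  log2(x + 1)
}

#' Expression-reliability cutoff from background genes
#'
#' The noise floor of the patient profile: a quantile (default 0.95,
#' linear interpolation) of the patient's log2 expression restricted to
#' the reference background genes (genes never observed in the cohort).
#'
#' @param patientLogExpr named numeric vector of log2(norm + 1) values.
#' @param background character vector of background gene identifiers.
#' @param probs quantile level in [0, 1].
#' @return the cutoff on the log2 scale.
#' @export
expressionCutoff <- function(patientLogExpr, background, probs = 0.95) {
  if (!length(background))
    stop("cutoff undefined: the background gene set is empty")
  miss <- setdiff(background, names(patientLogExpr))
  if (length(miss))
    stop("background gene(s) missing from the patient profile: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  unname(stats::quantile(patientLogExpr[background], probs = probs,
                         type = 7, names = FALSE))
}

#' Reliably expressed genes
#'
#' Genes whose log2 expression lies strictly above the cutoff; strict
#' inequality guarantees background genes themselves do not pass when the
#' cutoff equals their maximum.
#'
#' @param patientLogExpr named numeric vector.
#' @param cutoff finite cutoff on the log2 scale.
#' @return character vector of gene identifiers.
#' @export
reliabilityFilter <- function(patientLogExpr, cutoff) {
  if (!is.finite(cutoff) && !identical(cutoff, -Inf))
    stop("cutoff must be finite (or -Inf to keep all genes)")
  names(patientLogExpr)[patientLogExpr > cutoff]
}

#' Normalize one patient sample against a frozen reference
#'
#' Computes the add-on size factor, normalized and log2 expression, the
#' background-derived reliability cutoff and the reliable gene set, and
#' returns them as a \linkS4class{PatientProfile}.
#'
#' @param patientId sample identifier.
#' @param patientCounts named numeric vector of raw counts.
#' @param ref a \linkS4class{FrozenReference}.
#' @param bgQuantile quantile for \code{\link{expressionCutoff}}.
#' @return a \linkS4class{PatientProfile}.
#' @export
buildPatientProfile <- function(patientId, patientCounts, ref,
                                bgQuantile = 0.95) {
  cnt <- alignToReference(patientCounts, ref)
  names(cnt) <- ref@geneIds
  sf <- addonSizeFactor(cnt, ref)
  norm <- cnt / sf
  le <- log2p1(norm)
  cut <- expressionCutoff(le, ref@backgroundGenes, probs = bgQuantile)
  rel <- reliabilityFilter(le, cut)
  methods::new("PatientProfile",
               patientId = as.character(patientId),
               geneIds = ref@geneIds,
               rawCounts = unname(cnt),
               sizeFactor = sf,
               normCounts = unname(norm),
               logExpr = unname(le),
               expressionCutoff = cut,
               reliableGenes = rel)
}
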