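#' Two-sided negative-binomial tail probability for one count
#'
#' The single-sample test at the heart of the n-of-1 contrast: under
#' NB(mean = expected, dispersion alpha; variance mu + alpha mu^2) the
#' two-sided p-value is the doubled smaller tail,
#' \code{min(1, 2 * min(P[X <= obs], P[X >= obs]))}. Dispersion 0 is the
#' Poisson limit. Vectorized over genes.
#'
#' @param observed non-negative integer count(s).
#' @param expected positive expected count(s) (normal mean times the
#'   patient size factor).
#' @param dispersion non-negative dispersion(s); 0 gives exact Poisson.
#' @return p-value(s) in (0, 1]; genes with \code{expected <= 0} get NA
#'   (callers record p = 1 with a degenerate flag).
#' @export
nbTwoSidedP <- function(observed, expected, dispersion) {
  n <- max(length(observed), length(expected), length(dispersion))
  observed <- rep_len(observed, n)
  expected <- rep_len(expected, n)
  dispersion <- rep_len(dispersion, n)
  if (any(observed < 0, na.rm = TRUE))
    stop("observed counts must be non-negative")
  if (any(dispersion < 0, na.rm = TRUE))
    stop("dispersion must be non-negative")
  p <- rep(NA_real_, n)
  ok <- is.finite(expected) & expected > 0
  pois <- ok & dispersion == 0
  nb <- ok & dispersion > 0
  lower <- upper <- numeric(n)
  if (any(pois)) {
    lower[pois] <- stats::ppois(observed[pois], lambda = expected[pois])
    upper[pois] <- stats::ppois(observed[pois] - 1, lambda = expected[pois],
                                lower.tail = FALSE)
  }
  if (any(nb)) {
    size <- 1 / dispersion[nb]
    lower[nb] <- stats::pnbinom(observed[nb], size = size, mu = expected[nb])
    upper[nb] <- stats::pnbinom(observed[nb] - 1, size = size,
                                mu = expected[nb], lower.tail = FALSE)
  }
  p[ok] <- pmin(1, 2 * pmin(lower[ok], upper[ok]))
  p
}

#' Log2 fold change with pseudocount
#'
#' @param patientNorm patient normalized count(s).
#' @param normalMean frozen normal mean(s).
#' @param pseudocount added to both numerator and denominator (default 1).
#' @return \code{log2((patientNorm + pc) / (normalMean + pc))}.
#' @export
log2FoldChange <- function(patientNorm, normalMean, pseudocount = 1) {
  if (any(patientNorm < 0, na.rm = TRUE) || any(normalMean < 0,
                                                na.rm = TRUE))
    stop("inputs must be non-negative")
  log2((patientNorm + pseudocount) / (normalMean + pseudocount))
}

#' Single-sample differential expression against frozen normal parameters
#'
#' Tests every reliably expressed gene of the patient against the frozen
#' normal-tissue NB parameters. The expected count is the frozen normal
#' mean scaled by the patient size factor; p-values are two-sided doubled
#' NB tails, adjusted by Benjamini-Hochberg over the tested genes. A gene
#' is called significant when \code{adj_p < alpha} and
#' \code{|log2 fold change| >= lfcMin}.
#'
#' @param profile a \linkS4class{PatientProfile}.
#' @param ref the \linkS4class{FrozenReference} the profile was built on.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param lfcMin minimum absolute log2 fold change (default 1).
#' @param pseudocount for \code{\link{log2FoldChange}}.
#' @return data.frame with columns gene, normal_mean, patient_norm,
#'   log2_fold_change, p_value, adj_p, significant, direction
#'   ("up"/"down"/"none") and degenerate (TRUE when the frozen mean was 0
#'   and p was recorded as 1).
#' @export
callDE <- function(profile, ref, alpha = 0.05, lfcMin = 1,
                   pseudocount = 1) {
  stopifnot(methods::is(profile, "PatientProfile"),
            methods::is(ref, "FrozenReference"))
  if (!identical(profile@geneIds, ref@geneIds))
    stop("profile and reference gene universes differ")
  genes <- profile@reliableGenes
  cols <- c("gene", "normal_mean", "patient_norm", "log2_fold_change",
            "p_value", "adj_p", "significant", "direction", "degenerate")
  if (!length(genes)) {
    warning("no reliably expressed genes: empty DE table")
    out <- data.frame(gene = character(), normal_mean = numeric(),
                      patient_norm = numeric(),
                      log2_fold_change = numeric(), p_value = numeric(),
                      adj_p = numeric(), significant = logical(),
                      direction = character(), degenerate = logical(),
                      stringsAsFactors = FALSE)
    return(out[, cols])
  }
  idx <- match(genes, ref@geneIds)
  mu <- ref@normalMeans[idx]
  disp <- ref@normalDispersions[idx]
  obs <- profile@rawCounts[idx]
  expected <- mu * profile@sizeFactor
  p <- nbTwoSidedP(obs, expected, disp)
  degenerate <- is.na(p)
  p[degenerate] <- 1
  lfc <- log2FoldChange(profile@normCounts[idx], mu,
                        pseudocount = pseudocount)
  adj <- stats::p.adjust(p, method = "BH")
  sig <- !degenerate & adj < alpha & abs(lfc) >= lfcMin
  dir <- ifelse(sig, ifelse(lfc > 0, "up", "down"), "none")
  data.frame(gene = genes, normal_mean = mu,
             patient_norm = profile@normCounts[idx],
             log2_fold_change = lfc, p_value = p, adj_p = adj,
             significant = sig, direction = dir, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}
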