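`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gene-by-sample count matrix from TSV
#'
#' First column holds gene identifiers, the header row holds sample
#' identifiers, cells are non-negative integer counts.
#'
#' @param path path to a TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("count matrix needs a gene column plus at least one sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0))
    stop("counts must be non-negative numbers")
  rownames(m) <- genes
  m
}

#' Read per-sample metadata from TSV
#'
#' Expects columns \code{sample_id} and \code{group} (values "tumor" or
#' "normal"); any further columns are treated as class labels for
#' classifier training.
#'
#' @param path path to a TSV file.
#' @return data.frame with rownames set to sample_id.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample metadata is missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample identifiers")
  rownames(df) <- df$sample_id
  df
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Deterministic child seeds below 2^31, derived from one user seed.
childSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k) %% 2147483L
}
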