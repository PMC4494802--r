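#' Canonical variant key
#'
#' All cross-table joins use the exact-allele key
#' (chromosome, 1-based position, reference allele, alternate allele)
#' with any "chr" prefix stripped from the chromosome name.
#'
#' @param chrom,pos,ref,alt key fields (vectorized).
#' @return character key "chrom:pos:ref:alt".
#' @export
variantKey <- function(chrom, pos, ref, alt) {
  paste(sub("^chr", "", as.character(chrom)), as.integer(pos),
        toupper(as.character(ref)), toupper(as.character(alt)), sep = ":")
}

#' Read variants from a VCF file
#'
#' Parses a VCF (v4.x) with \pkg{vcfR}, splits multi-allelic rows into one
#' record per alternate allele (the exact-allele rules are per-allele) and
#' extracts GENE/EFFECT INFO keys when present. Indels are kept and
#' flagged: the exact-allele annotation rule was stated for single
#' nucleotide variants.
#'
#' @param path VCF file.
#' @return data.frame with columns chrom, pos, ref, alt, gene, effect,
#'   qual, filter, key, is_indel.
#' @export
readVariants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- if ("INFO" %in% colnames(v@fix)) v@fix[, "INFO"] else
    rep(NA_character_, nrow(fix))
  gene <- vapply(info, function(s) {
    m <- regmatches(s, regexpr("(?:^|;)GENE=([^;]*)", s, perl = TRUE))
    if (length(m)) sub(".*GENE=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  effect <- vapply(info, function(s) {
    m <- regmatches(s, regexpr("(?:^|;)EFFECT=([^;]*)", s, perl = TRUE))
    if (length(m)) sub(".*EFFECT=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts, gene = gene[i],
               effect = effect[i], qual = fix$QUAL[i],
               filter = fix$FILTER[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$ref == out$alt))
    stop("malformed variant: reference allele equals alternate allele")
  out$key <- variantKey(out$chrom, out$pos, out$ref, out$alt)
  out$is_indel <- nchar(out$ref) != 1L | nchar(out$alt) != 1L
  out
}

#' Read an annotation bundle from a directory of TSVs
#'
#' Expected files: \code{common_variants.tsv} (keys flagged common or of
#' no known medical impact), \code{population_maf.tsv} (keys plus a
#' \code{maf} column in [0, 1]); every other \code{*.tsv} with the four
#' key columns becomes a named clinical table (COSMIC-like, ClinVar-like,
#' CADD-like, variant-drug rules, ...).
#'
#' @param dir directory path.
#' @return list(common_flags = character keys, maf = named numeric,
#'   clinical_tables = named list of data.frames with a \code{key} column).
#' @export
readAnnotationBundle <- function(dir) {
  keyed <- function(df, what) {
    need <- c("chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(what, " is missing key column(s): ",
           paste(miss, collapse = ", "))
    df$key <- variantKey(df$chrom, df$pos, df$ref, df$alt)
    df
  }
  bundle <- list(common_flags = character(), maf = numeric(),
                 clinical_tables = list())
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  for (f in files) {
    nm <- sub("\\.tsv$", "", basename(f))
    df <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (nm == "common_variants") {
      bundle$common_flags <- keyed(df, nm)$key
    } else if (nm == "population_maf") {
      df <- keyed(df, nm)
      if (!"maf" %in% names(df)) stop("population_maf needs a maf column")
      if (any(df$maf < 0 | df$maf > 1, na.rm = TRUE))
        stop("MAF values must lie in [0, 1]")
      bundle$maf <- stats::setNames(df$maf, df$key)
    } else {
      bundle$clinical_tables[[nm]] <- keyed(df, nm)
    }
  }
  bundle
}

#' Filter variants on common flags and population frequency
#'
#' A variant is removed iff its key is flagged common/no-known-medical
#' impact OR its minor allele frequency is present and strictly above the
#' threshold. A missing MAF retains the variant: absent population data
#' must not suppress a potentially actionable call. The operation is
#' idempotent and every removed variant carries exactly one reason.
#'
#' @param variants data.frame from \code{\link{readVariants}}.
#' @param bundle annotation bundle from \code{\link{readAnnotationBundle}}.
#' @param mafThreshold removal threshold, default 0.1.
#' @return the input data.frame plus columns \code{retained} (logical) and
#'   \code{removal_reason} ("common-flag", "maf" or NA).
#' @export
filterVariants <- function(variants, bundle, mafThreshold = 0.1) {
  v <- variants
  malformed <- is.na(v$pos) | is.na(v$ref) | is.na(v$alt) |
    v$ref == "" | v$alt == ""
  if (any(malformed))
    warning(sum(malformed), " variant(s) with malformed keys were ",
            "retained and flagged")
  common <- v$key %in% bundle$common_flags
  maf <- unname(bundle$maf[v$key])
  highMaf <- !is.na(maf) & maf > mafThreshold
  reason <- rep(NA_character_, nrow(v))
  reason[highMaf] <- "maf"
  reason[common] <- "common-flag"
  reason[malformed] <- NA_character_
  v$retained <- is.na(reason)
  v$removal_reason <- reason
  v$malformed_key <- malformed
  v
}

#' Attach clinical annotations by exact allele match
#'
#' For every clinical table in the bundle, entries whose
#' (chrom, pos, ref, alt) key equals a variant's key exactly are attached
#' as evidence; a positional match with a different allele is never
#' attached. The variant set itself is unchanged.
#'
#' @param variants data.frame with a \code{key} column (typically the
#'   retained output of \code{\link{filterVariants}}).
#' @param bundle annotation bundle.
#' @return data.frame of attachments with columns key, table and detail
#'   (the entry's non-key columns collapsed to "name=value" pairs); zero
#'   rows when nothing matches.
#' @export
annotateVariants <- function(variants, bundle) {
  out <- list()
  for (nm in names(bundle$clinical_tables)) {
    tab <- bundle$clinical_tables[[nm]]
    hit <- tab[tab$key %in% variants$key, , drop = FALSE]
    if (!nrow(hit)) next
    extraCols <- setdiff(names(hit), c("chrom", "pos", "ref", "alt", "key"))
    detail <- apply(hit[, extraCols, drop = FALSE], 1L, function(r)
      paste(paste0(extraCols, "=", r), collapse = "; "))
    out[[nm]] <- data.frame(key = hit$key, table = nm,
                            detail = unname(detail),
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(key = character(), table = character(),
                      detail = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ingest a fusion candidate table
#'
#' Reads a FusionCatcher-like TSV of fusion candidates (5' and 3' partner
#' genes, optional description, oncogenic-potential p-value and expression
#' gain/loss) and orders candidates by ascending oncogenic p-value with
#' missing p-values last; the sort is stable so ties preserve input order.
#' Duplicate rows are kept and flagged.
#'
#' @param path TSV file, or a data.frame with the same columns.
#' @return data.frame with columns gene_5p, gene_3p, description,
#'   oncogenic_p, expression_gain_loss, duplicate.
#' @export
ingestFusions <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_5p", "gene_3p")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fusion table is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (opt in c("description", "oncogenic_p", "expression_gain_loss"))
    if (!opt %in% names(df))
      df[[opt]] <- rep(if (opt == "description") NA_character_ else
        NA_real_, nrow(df))
  df <- df[, c("gene_5p", "gene_3p", "description", "oncogenic_p",
               "expression_gain_loss")]
  if (!nrow(df)) {
    df$duplicate <- logical()
    return(df)
  }
  sig <- paste(df$gene_5p, df$gene_3p, df$description, df$oncogenic_p,
               df$expression_gain_loss, sep = "\r")
  df$duplicate <- duplicated(sig) | duplicated(sig, fromLast = TRUE)
  ord <- order(is.na(df$oncogenic_p), df$oncogenic_p)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
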