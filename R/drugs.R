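#' Read a drug metadata table
#'
#' TSV shaped like an export of DrugBank/KEGG-style drug metadata:
#' columns drug_id, name, approved (TRUE/FALSE), targets
#' ("GENE1:inhibitor,GENE2:agonist" pairs), pathway_ids (comma separated)
#' and optional source link columns.
#'
#' @param path TSV file or equivalent data.frame.
#' @return data.frame with list-columns \code{target_genes},
#'   \code{target_actions} and \code{pathways}.
#' @export
readDrugTable <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "name", "approved", "targets", "pathway_ids")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("drug table is missing column(s): ", paste(miss, collapse = ", "))
  parsePairs <- function(s) {
    if (is.na(s) || !nzchar(s)) return(list(genes = character(),
                                            actions = character()))
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], ":",
                      fixed = TRUE)
    list(genes = vapply(parts, `[`, character(1), 1L),
         actions = vapply(parts, function(p)
           if (length(p) > 1L) p[2L] else "other", character(1)))
  }
  pp <- lapply(df$targets, parsePairs)
  df$target_genes <- lapply(pp, `[[`, "genes")
  df$target_actions <- lapply(pp, `[[`, "actions")
  df$pathways <- lapply(df$pathway_ids, function(s)
    if (is.na(s) || !nzchar(s)) character() else
      strsplit(s, ",", fixed = TRUE)[[1L]])
  df$approved <- as.logical(df$approved)
  df
}

emptyMatches <- function() {
  data.frame(drug_id = character(), drug_name = character(),
             evidence_type = character(), matched_entity = character(),
             direction_concordant = character(), rationale = character(),
             stringsAsFactors = FALSE)
}

drugMatchRow <- function(drug, type, entity, concordant, rationale) {
  data.frame(drug_id = drug$drug_id, drug_name = drug$name,
             evidence_type = type, matched_entity = entity,
             direction_concordant = concordant, rationale = rationale,
             stringsAsFactors = FALSE)
}

#' Match drugs to differentially expressed genes
#'
#' The action/direction rule applied (and printed in the report so
#' clinicians see it): inhibitor, antagonist and antibody actions match
#' up-regulated targets; agonist actions match down-regulated targets;
#' action "other" matches either direction with concordance
#' not-applicable. Only approved drugs and significant DE genes enter.
#'
#' @param deTable output of \code{\link{callDE}}.
#' @param drugs drug table from \code{\link{readDrugTable}}.
#' @param requireConcordance when FALSE, every action type matches either
#'   direction (concordance still reported).
#' @return data.frame of matches, one row per (drug, gene) pair.
#' @export
matchExpressionDrugs <- function(deTable, drugs,
                                 requireConcordance = TRUE) {
  sig <- deTable[deTable$significant, , drop = FALSE]
  if (!nrow(sig)) return(emptyMatches())
  dir <- stats::setNames(sig$direction, sig$gene)
  out <- list()
  for (i in seq_len(nrow(drugs))) {
    d <- drugs[i, ]
    if (!isTRUE(d$approved)) next
    genes <- d$target_genes[[1L]]
    actions <- d$target_actions[[1L]]
    for (j in seq_along(genes)) {
      g <- genes[j]
      if (!g %in% names(dir)) next
      act <- actions[j]
      wanted <- switch(act,
                       inhibitor = "up", antagonist = "up",
                       antibody = "up", agonist = "down", NA_character_)
      conc <- if (is.na(wanted)) "not-applicable" else
        if (dir[[g]] == wanted) "yes" else "no"
      if (requireConcordance && identical(conc, "no")) next
      out[[length(out) + 1L]] <- drugMatchRow(
        d, "expression", g, conc,
        paste0(d$name, " (", act, ") targets ", g, ", ", dir[[g]],
               "-regulated in the patient"))
    }
  }
  if (!length(out)) return(emptyMatches())
  do.call(rbind, out)
}

#' Match drugs to retained variants by exact allele key
#'
#' @param variants retained variants (data.frame with a \code{key} column).
#' @param rules variant-drug rule table with key columns plus drug_id,
#'   drug_name (e.g. the \code{drug_variant_rules} clinical table of the
#'   annotation bundle).
#' @return data.frame of matches, one row per (variant, rule) pair.
#' @export
matchVariantDrugs <- function(variants, rules) {
  if (is.null(rules) || !nrow(rules)) return(emptyMatches())
  if (!"key" %in% names(rules))
    rules$key <- variantKey(rules$chrom, rules$pos, rules$ref, rules$alt)
  hit <- rules[rules$key %in% variants$key, , drop = FALSE]
  if (!nrow(hit)) return(emptyMatches())
  out <- lapply(seq_len(nrow(hit)), function(i)
    drugMatchRow(list(drug_id = hit$drug_id[i], name = hit$drug_name[i]),
                 "variant", hit$key[i], "not-applicable",
                 paste0(hit$drug_name[i], " linked to variant ",
                        hit$key[i])))
  do.call(rbind, out)
}

#' Match drugs to significantly dysregulated pathways
#'
#' @param pathwayResults output of \code{\link{analyzePathways}}.
#' @param drugs drug table from \code{\link{readDrugTable}}.
#' @param fdrAlpha significance level on pG_fdr (default 0.05).
#' @return data.frame of matches, one row per (drug, pathway) pair.
#' @export
matchPathwayDrugs <- function(pathwayResults, drugs, fdrAlpha = 0.05) {
  sig <- pathwayResults$pathway_id[pathwayResults$pG_fdr < fdrAlpha]
  if (!length(sig)) return(emptyMatches())
  out <- list()
  for (i in seq_len(nrow(drugs))) {
    d <- drugs[i, ]
    if (!isTRUE(d$approved)) next
    for (pw in intersect(d$pathways[[1L]], sig))
      out[[length(out) + 1L]] <- drugMatchRow(
        d, "pathway", pw, "not-applicable",
        paste0(d$name, " acts on dysregulated pathway ", pw))
  }
  if (!length(out)) return(emptyMatches())
  do.call(rbind, out)
}

#' Consolidate drug matches into a ranked table
#'
#' One row per drug, ranked by number of distinct evidence types
#' (descending), then total evidence count (descending), then drug name
#' (ascending) - a deterministic total order. All evidence rows are
#' retained alongside.
#'
#' @param matches data.frame rbind of the match_* outputs.
#' @return list(table = ranked one-row-per-drug data.frame with columns
#'   rank, drug_id, drug_name, n_evidence_types, n_evidence,
#'   evidence_types; evidence = the full match rows ordered the same way).
#' @export
consolidateDrugMatches <- function(matches) {
  if (is.null(matches) || !nrow(matches))
    return(list(table = data.frame(rank = integer(), drug_id = character(),
                                   drug_name = character(),
                                   n_evidence_types = integer(),
                                   n_evidence = integer(),
                                   evidence_types = character(),
                                   stringsAsFactors = FALSE),
                evidence = emptyMatches()))
  sp <- split(matches, matches$drug_id)
  rows <- lapply(sp, function(m)
    data.frame(drug_id = m$drug_id[1L], drug_name = m$drug_name[1L],
               n_evidence_types = length(unique(m$evidence_type)),
               n_evidence = nrow(m),
               evidence_types = paste(sort(unique(m$evidence_type)),
                                      collapse = "+"),
               stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  ord <- order(-tab$n_evidence_types, -tab$n_evidence, tab$drug_name,
               tab$drug_id, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  ev <- matches[order(match(matches$drug_id, tab$drug_id),
                      matches$evidence_type, matches$matched_entity,
                      method = "radix"), , drop = FALSE]
  rownames(ev) <- NULL
  list(table = tab, evidence = ev)
}
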