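#' Assemble the integrated report model
#'
#' Collects all stage outputs into one structured document. A patient
#' profile and DE table are required; every other section is optional and
#' is rendered as an explicit "not run" block when absent. All inputs that
#' carry a patient identifier must agree on it.
#'
#' @param profile a \linkS4class{PatientProfile}.
#' @param ref the \linkS4class{FrozenReference} used.
#' @param deTable output of \code{\link{callDE}}.
#' @param predictions named list of \linkS4class{Prediction} objects.
#' @param pathways output of \code{\link{analyzePathways}}.
#' @param variants filtered variant data.frame (\code{\link{filterVariants}}).
#' @param annotations attachment table (\code{\link{annotateVariants}}).
#' @param fusions output of \code{\link{ingestFusions}}.
#' @param drugs output of \code{\link{consolidateDrugMatches}}.
#' @param qc optional pass-through QC table.
#' @param patientMeta named list of extra patient metadata.
#' @param thresholds named list recorded in provenance (alpha, lfc_min,
#'   bg_quantile, maf_threshold, fdr_alpha, ...).
#' @param seeds named list of RNG seeds recorded in provenance.
#' @return a \linkS4class{ReportModel}.
#' @export
buildReportModel <- function(profile, ref, deTable,
                             predictions = NULL, pathways = NULL,
                             variants = NULL, annotations = NULL,
                             fusions = NULL, drugs = NULL, qc = NULL,
                             patientMeta = list(),
                             thresholds = list(), seeds = list()) {
  stopifnot(methods::is(profile, "PatientProfile"))
  pid <- patientId(profile)
  metaId <- patientMeta$patient_id
  if (!is.null(metaId) && !identical(as.character(metaId), pid))
    stop("patient_id mismatch between profile ('", pid,
         "') and metadata ('", metaId, "')")
  patientMeta$patient_id <- pid
  prov <- list(
    package = "nof1seq",
    package_version = as.character(utils::packageVersion("nof1seq")),
    thresholds = thresholds,
    seeds = seeds,
    reference = refProvenance(ref),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  variantSection <- if (is.null(variants)) NULL else
    list(table = variants,
         annotations = annotations %||%
           data.frame(key = character(), table = character(),
                      detail = character(), stringsAsFactors = FALSE))
  methods::new("ReportModel",
               patient = patientMeta,
               provenance = prov,
               profileSummary = list(
                 size_factor = sizeFactor(profile),
                 expression_cutoff = cutoffValue(profile),
                 n_genes = length(geneIds(profile)),
                 n_reliable = length(reliableGenes(profile))),
               predictions = predictions,
               deTable = deTable,
               pathways = pathways,
               variants = variantSection,
               fusions = fusions,
               drugs = drugs,
               qc = qc)
}

htmlEscape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmtCell <- function(x) {
  if (is.numeric(x)) vapply(x, function(v)
    if (is.na(v)) "" else format(v, digits = 5), character(1))
  else ifelse(is.na(x), "", htmlEscape(x))
}

lfcColor <- function(lfc) {
  # blue for down, red for up, intensity by magnitude (saturates at |4|)
  a <- pmin(abs(lfc) / 4, 1)
  ifelse(is.na(lfc) | lfc == 0, "",
         sprintf("background:rgba(%s,%.2f)",
                 ifelse(lfc > 0, "214,69,65", "31,119,180"), 0.15 + 0.5 * a))
}

tableToHtml <- function(df, id, caption = NULL, linkCols = list(),
                        colorCol = NULL) {
  if (!nrow(df))
    return(paste0("<p class=\"empty\" id=\"", id,
                  "\">no entries</p>"))
  head <- paste0("<th onclick=\"sortBy('", id, "',", seq_along(df) - 1L,
                 ")\">", htmlEscape(names(df)), "</th>", collapse = "")
  cells <- lapply(names(df), function(cn) {
    v <- fmtCell(df[[cn]])
    if (!is.null(linkCols[[cn]]))
      v <- ifelse(nzchar(v),
                  paste0("<a href=\"",
                         vapply(df[[cn]], function(u)
                           sub("{id}", utils::URLencode(as.character(u)),
                               linkCols[[cn]], fixed = TRUE), character(1)),
                         "\">", v, "</a>"), v)
    v
  })
  styles <- if (!is.null(colorCol) && colorCol %in% names(df))
    lfcColor(df[[colorCol]]) else NULL
  rows <- vapply(seq_len(nrow(df)), function(i) {
    tds <- vapply(seq_along(cells), function(j) {
      st <- if (!is.null(styles) && names(df)[j] == colorCol &&
                nzchar(styles[i]))
        paste0(" style=\"", styles[i], "\"") else ""
      paste0("<td", st, ">", cells[[j]][i], "</td>")
    }, character(1))
    paste0("<tr>", paste0(tds, collapse = ""), "</tr>")
  }, character(1))
  paste0(if (!is.null(caption)) paste0("<p class=\"tblmeta\">", caption,
                                       "</p>") else "",
         "<input class=\"search\" type=\"text\" placeholder=\"filter...\"",
         " onkeyup=\"filterTable('", id, "', this.value)\"/>",
         "<table id=\"", id, "\"><thead><tr>", head,
         "</tr></thead><tbody>",
         paste0(rows, collapse = "\n"), "</tbody></table>")
}

reportJS <- "
function sortBy(id, col) {
  var tb = document.getElementById(id).tBodies[0];
  var rows = Array.prototype.slice.call(tb.rows);
  var dir = tb.getAttribute('data-dir') === 'asc' ? -1 : 1;
  tb.setAttribute('data-dir', dir === 1 ? 'asc' : 'desc');
  rows.sort(function(a, b) {
    var x = a.cells[col].textContent, y = b.cells[col].textContent;
    var nx = parseFloat(x), ny = parseFloat(y);
    if (!isNaN(nx) && !isNaN(ny)) return dir * (nx - ny);
    return dir * x.localeCompare(y);
  });
  rows.forEach(function(r) { tb.appendChild(r); });
}
function filterTable(id, q) {
  q = q.toLowerCase();
  var rows = document.getElementById(id).tBodies[0].rows;
  for (var i = 0; i < rows.length; i++) {
    rows[i].style.display =
      rows[i].textContent.toLowerCase().indexOf(q) >= 0 ? '' : 'none';
  }
}
"

reportCSS <- "
body { font-family: sans-serif; margin: 2em; color: #222; }
h1 { border-bottom: 2px solid #444; }
h2 { margin-top: 2em; color: #234; }
table { border-collapse: collapse; margin: 0.5em 0; width: 100%; }
th, td { border: 1px solid #bbb; padding: 3px 8px; font-size: 0.9em; }
th { background: #eef; cursor: pointer; }
.search { margin: 4px 0; padding: 2px 6px; }
.notrun { color: #777; font-style: italic; }
.empty { color: #777; }
.tblmeta { color: #555; font-size: 0.9em; }
pre.prov { background: #f6f6f6; padding: 1em; font-size: 0.85em; }
@media print { .search { display: none; } }
"

sectionOrNotRun <- function(present, title, body) {
  paste0("<h2>", title, "</h2>",
         if (present) body else
           "<p class=\"notrun\">not run for this sample</p>")
}

provHtml <- function(prov) {
  paste0("<pre class=\"prov\">",
         htmlEscape(jsonlite::toJSON(prov, auto_unbox = TRUE,
                                     pretty = TRUE, digits = NA)),
         "</pre>")
}

predictionsDf <- function(preds) {
  do.call(rbind, lapply(names(preds), function(nm) {
    p <- preds[[nm]]
    data.frame(predictor = nm, call = predictedLabel(p),
               probability = unname(classProbabilities(p)[predictedLabel(p)]),
               classes = paste(names(classProbabilities(p)), collapse = "/"),
               probabilities = paste(
                 format(unname(classProbabilities(p)), digits = 4),
                 collapse = "/"),
               flags = paste(p@flags, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Render the interactive HTML report and CSV exports
#'
#' Writes a self-contained HTML report (inline CSS/JS, no network assets)
#' with sortable, searchable tables, gene/drug identifiers linked through
#' configurable URL templates and fold-change-colored DE cells; every
#' populated table is also written under \code{tables/*.csv}, and the full
#' model is serialized to \code{report_model.json}.
#'
#' @param model a \linkS4class{ReportModel}.
#' @param outDir output directory (created if needed).
#' @param urlTemplates named list of templates with an \code{{id}}
#'   placeholder for columns gene and drug_id.
#' @return invisible list of written paths.
#' @export
renderReport <- function(model, outDir,
                         urlTemplates = list(
                           gene = "https://www.genecards.org/cgi-bin/carddisp.pl?gene={id}",
                           drug_id = "https://go.drugbank.com/drugs/{id}")) {
  dir.create(file.path(outDir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)
  written <- character()
  csv <- function(df, nm) {
    p <- file.path(outDir, "tables", paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  geneLink <- list(gene = urlTemplates$gene)
  drugLink <- list(drug_id = urlTemplates$drug_id)
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    paste0("<title>nof1seq report: ",
           htmlEscape(model@patient$patient_id), "</title>"),
    paste0("<style>", reportCSS, "</style>"),
    paste0("<script>", reportJS, "</script></head><body>"),
    paste0("<h1>Molecular profile of patient ",
           htmlEscape(model@patient$patient_id), "</h1>"))
  ps <- model@profileSummary
  sampDf <- data.frame(size_factor = ps$size_factor,
                       expression_cutoff_log2 = ps$expression_cutoff,
                       genes = ps$n_genes, reliable_genes = ps$n_reliable)
  csv(sampDf, "sample_processing")
  parts <- c(parts, "<h2>Sample processing</h2>",
             tableToHtml(sampDf, "tbl-sample"))
  if (!is.null(model@qc)) csv(model@qc, "qc")
  parts <- c(parts, sectionOrNotRun(
    !is.null(model@qc), "Quality control (pass-through)",
    if (!is.null(model@qc)) tableToHtml(model@qc, "tbl-qc")))
  if (!is.null(model@predictions)) {
    pdf <- predictionsDf(model@predictions)
    csv(pdf, "predictions")
    parts <- c(parts, sectionOrNotRun(TRUE,
      "Receptor status and molecular subtype",
      tableToHtml(pdf, "tbl-pred")))
  } else {
    parts <- c(parts, sectionOrNotRun(FALSE,
      "Receptor status and molecular subtype", ""))
  }
  if (!is.null(model@deTable)) {
    csv(model@deTable, "differential_expression")
    sig <- model@deTable[model@deTable$significant, , drop = FALSE]
    parts <- c(parts, sectionOrNotRun(TRUE, "Differential expression",
      paste0(tableToHtml(sig, "tbl-de",
                         caption = paste0(nrow(sig),
                           " significant of ", nrow(model@deTable),
                           " tested genes (full table in CSV export)"),
                         linkCols = geneLink,
                         colorCol = "log2_fold_change"))))
  } else {
    parts <- c(parts, sectionOrNotRun(FALSE, "Differential expression", ""))
  }
  if (!is.null(model@pathways)) {
    csv(model@pathways, "pathways")
    parts <- c(parts, sectionOrNotRun(TRUE, "Pathway impact analysis",
      tableToHtml(model@pathways, "tbl-pw")))
  } else {
    parts <- c(parts, sectionOrNotRun(FALSE, "Pathway impact analysis", ""))
  }
  if (!is.null(model@variants)) {
    csv(model@variants$table, "variants")
    csv(model@variants$annotations, "variant_annotations")
    parts <- c(parts, sectionOrNotRun(TRUE, "Variants",
      paste0(tableToHtml(model@variants$table, "tbl-var"),
             "<h3>Clinical annotations (exact allele match)</h3>",
             tableToHtml(model@variants$annotations, "tbl-var-ann"))))
  } else {
    parts <- c(parts, sectionOrNotRun(FALSE, "Variants", ""))
  }
  if (!is.null(model@fusions)) {
    csv(model@fusions, "fusions")
    parts <- c(parts, sectionOrNotRun(TRUE, "Fusion candidates",
      tableToHtml(model@fusions, "tbl-fus")))
  } else {
    parts <- c(parts, sectionOrNotRun(FALSE, "Fusion candidates", ""))
  }
  if (!is.null(model@drugs)) {
    csv(model@drugs$table, "drug_candidates")
    csv(model@drugs$evidence, "drug_evidence")
    body <- if (nrow(model@drugs$table))
      paste0(tableToHtml(model@drugs$table, "tbl-drug",
                         linkCols = drugLink),
             "<h3>Evidence</h3>",
             tableToHtml(model@drugs$evidence, "tbl-drug-ev",
                         linkCols = drugLink))
    else "<p class=\"empty\">no candidates</p>"
    parts <- c(parts, sectionOrNotRun(TRUE, "Drug candidates", body))
  } else {
    parts <- c(parts, sectionOrNotRun(FALSE, "Drug candidates", ""))
  }
  parts <- c(parts, "<h2>Provenance</h2>", provHtml(model@provenance),
             "</body></html>")
  htmlPath <- file.path(outDir, "report.html")
  writeLines(paste0(parts, collapse = "\n"), htmlPath)
  modelPath <- file.path(outDir, "report_model.json")
  writeReportModel(model, modelPath)
  invisible(c(htmlPath, modelPath, written))
}

#' Serialize a report model to JSON
#'
#' @param model a \linkS4class{ReportModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReportModel <- function(model, path) {
  preds <- if (is.null(model@predictions)) NULL else
    lapply(model@predictions, function(p)
      list(label = p@label, probabilities = as.list(p@probabilities),
           discriminants = as.list(p@discriminants),
           flags = p@flags))
  doc <- list(format = "nof1seq-report-model", format_version = "1.0",
              patient = model@patient, provenance = model@provenance,
              profile_summary = model@profileSummary,
              predictions = preds, de_table = model@deTable,
              pathways = model@pathways,
              variants = model@variants$table,
              variant_annotations = model@variants$annotations,
              fusions = model@fusions,
              drug_table = model@drugs$table,
              drug_evidence = model@drugs$evidence,
              qc = model@qc)
  writeLines(jsonlite::toJSON(doc, dataframe = "columns", digits = NA,
                              auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

#' Render the print-ready clinical summary
#'
#' A one-page-style document for dissemination to treating physicians:
#' patient information, sample processing information, the recommended
#' approved drugs in consolidated rank order with their evidence types,
#' and appendix tables; states "no actionable findings" when nothing is
#' significant.
#'
#' @param model a \linkS4class{ReportModel}.
#' @param outPath output HTML file.
#' @return \code{outPath}, invisibly.
#' @export
renderSummary <- function(model, outPath) {
  nSig <- if (!is.null(model@deTable)) sum(model@deTable$significant) else 0L
  drugTab <- if (!is.null(model@drugs)) model@drugs$table else NULL
  actionable <- (!is.null(drugTab) && nrow(drugTab) > 0)
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    paste0("<title>Clinical summary: ",
           htmlEscape(model@patient$patient_id), "</title>"),
    paste0("<style>", reportCSS, "</style></head><body>"),
    paste0("<h1>Clinical summary - patient ",
           htmlEscape(model@patient$patient_id), "</h1>"),
    "<h2>Patient information</h2>",
    tableToHtml(data.frame(field = names(model@patient),
                           value = vapply(model@patient, function(v)
                             paste(as.character(v), collapse = ", "),
                             character(1)),
                           stringsAsFactors = FALSE), "sum-pat"),
    "<h2>Sample processing</h2>",
    tableToHtml(data.frame(
      size_factor = model@profileSummary$size_factor,
      expression_cutoff_log2 = model@profileSummary$expression_cutoff,
      reliable_genes = model@profileSummary$n_reliable,
      significant_genes = nSig), "sum-proc"),
    "<h2>Recommended approved drugs</h2>",
    if (actionable)
      tableToHtml(drugTab[, c("rank", "drug_name", "evidence_types",
                              "n_evidence")], "sum-drug")
    else "<p class=\"empty\">no actionable findings</p>")
  if (!is.null(model@predictions)) {
    parts <- c(parts, "<h2>Molecular classification</h2>",
               tableToHtml(predictionsDf(model@predictions), "sum-pred"))
  }
  parts <- c(parts, "<h2>Appendix</h2>")
  if (!is.null(model@deTable)) {
    sig <- model@deTable[model@deTable$significant, , drop = FALSE]
    parts <- c(parts, "<h3>Significant differential expression</h3>",
               tableToHtml(sig, "sum-de"))
  }
  if (!is.null(model@pathways))
    parts <- c(parts, "<h3>Pathway impact</h3>",
               tableToHtml(model@pathways, "sum-pw"))
  if (!is.null(model@variants))
    parts <- c(parts, "<h3>Retained variants</h3>",
               tableToHtml(model@variants$table[
                 model@variants$table$retained, , drop = FALSE], "sum-var"))
  if (!is.null(model@fusions))
    parts <- c(parts, "<h3>Fusion candidates</h3>",
               tableToHtml(model@fusions, "sum-fus"))
  parts <- c(parts, "<h2>Provenance</h2>", provHtml(model@provenance),
             "</body></html>")
  writeLines(paste0(parts, collapse = "\n"), outPath)
  invisible(outPath)
}
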