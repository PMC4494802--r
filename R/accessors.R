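#' @rdname FrozenReference-class
#' @export
setMethod("geneIds", "FrozenReference", function(x) x@geneIds)

#' @rdname FrozenReference-class
#' @export
setMethod("geoMeans", "FrozenReference", function(x) {
  stats::setNames(x@geoMeans, x@geneIds)
})

#' @rdname FrozenReference-class
#' @export
setMethod("backgroundGenes", "FrozenReference", function(x) x@backgroundGenes)

#' @rdname FrozenReference-class
#' @export
setMethod("normalMeans", "FrozenReference", function(x) {
  stats::setNames(x@normalMeans, x@geneIds)
})

#' @rdname FrozenReference-class
#' @export
setMethod("normalDispersions", "FrozenReference", function(x) {
  stats::setNames(x@normalDispersions, x@geneIds)
})

#' @rdname FrozenReference-class
#' @export
setMethod("classifiers", "FrozenReference", function(x) x@classifiers)

#' @rdname FrozenReference-class
#' @export
setMethod("refProvenance", "FrozenReference", function(x) x@provenance)

setMethod("show", "FrozenReference", function(object) {
  cat("FrozenReference (format ",
      as.character(object@provenance$format_version %||% "?"), ")\n",
      "  genes: ", length(object@geneIds),
      " (", length(object@backgroundGenes), " background)\n",
      "  classifiers: ",
      if (length(object@classifiers))
        paste(names(object@classifiers), collapse = ", ") else "none",
      "\n", sep = "")
})

#' @rdname PatientProfile-class
#' @export
setMethod("patientId", "PatientProfile", function(x) x@patientId)

#' @rdname PatientProfile-class
#' @export
setMethod("geneIds", "PatientProfile", function(x) x@geneIds)

#' @rdname PatientProfile-class
#' @export
setMethod("rawCounts", "PatientProfile", function(x) {
  stats::setNames(x@rawCounts, x@geneIds)
})

#' @rdname PatientProfile-class
#' @export
setMethod("sizeFactor", "PatientProfile", function(x) x@sizeFactor)

#' @rdname PatientProfile-class
#' @export
setMethod("normCounts", "PatientProfile", function(x) {
  stats::setNames(x@normCounts, x@geneIds)
})

#' @rdname PatientProfile-class
#' @export
setMethod("logExpr", "PatientProfile", function(x) {
  stats::setNames(x@logExpr, x@geneIds)
})

#' @rdname PatientProfile-class
#' @export
setMethod("cutoffValue", "PatientProfile", function(x) x@expressionCutoff)

#' @rdname PatientProfile-class
#' @export
setMethod("reliableGenes", "PatientProfile", function(x) x@reliableGenes)

setMethod("show", "PatientProfile", function(object) {
  cat("PatientProfile '", object@patientId, "'\n",
      "  genes: ", length(object@geneIds),
      ", size factor: ", format(object@sizeFactor, digits = 6), "\n",
      "  expression cutoff (log2): ",
      format(object@expressionCutoff, digits = 6),
      ", reliable genes: ", length(object@reliableGenes), "\n", sep = "")
})

#' @rdname CentroidModel-class
#' @export
setMethod("geneIds", "CentroidModel", function(x) x@geneIds)

#' @rdname CentroidModel-class
#' @export
setMethod("selectedGenes", "CentroidModel", function(x) x@selectedGenes)

setMethod("show", "CentroidModel", function(object) {
  cat("CentroidModel '", object@name, "': ",
      paste(object@classes, collapse = "/"), "\n",
      "  genes: ", length(object@geneIds),
      ", selected at delta=", format(object@delta, digits = 4), ": ",
      length(object@selectedGenes), "\n", sep = "")
})

#' @rdname Prediction-class
#' @export
setMethod("predictedLabel", "Prediction", function(x) x@label)

#' @rdname Prediction-class
#' @export
setMethod("classProbabilities", "Prediction", function(x) x@probabilities)

setMethod("show", "Prediction", function(object) {
  cat("Prediction: ", object@label, " (p = ",
      format(object@probabilities[object@label], digits = 4), ")",
      if (length(object@flags)) paste0(" [", paste(object@flags,
                                                   collapse = ", "), "]"),
      "\n", sep = "")
})

setMethod("show", "PathwayTopology", function(object) {
  cat("PathwayTopology '", object@pathwayId, "' (", object@name, ")\n",
      "  genes: ", length(object@genes),
      ", edges: ", sum(object@beta != 0), "\n", sep = "")
})

setMethod("show", "ReportModel", function(object) {
  secs <- c(expression = !is.null(object@deTable),
            pathways = !is.null(object@pathways),
            variants = !is.null(object@variants),
            fusions = !is.null(object@fusions),
            drugs = !is.null(object@drugs),
            predictions = !is.null(object@predictions),
            qc = !is.null(object@qc))
  cat("ReportModel for patient '", object@patient$patient_id, "'\n",
      "  sections: ",
      paste(names(secs)[secs], collapse = ", "), "\n",
      "  not run: ",
      if (any(!secs)) paste(names(secs)[!secs], collapse = ", ") else "none",
      "\n", sep = "")
})
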