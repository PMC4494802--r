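#' @rdname FrozenReference-class
#' @param x,object a \linkS4class{FrozenReference}, \linkS4class{PatientProfile}
#'   or \linkS4class{CentroidModel} as appropriate.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname FrozenReference-class
#' @export
setGeneric("geoMeans", function(x) standardGeneric("geoMeans"))

#' @rdname FrozenReference-class
#' @export
setGeneric("backgroundGenes", function(x) standardGeneric("backgroundGenes"))

#' @rdname FrozenReference-class
#' @export
setGeneric("normalMeans", function(x) standardGeneric("normalMeans"))

#' @rdname FrozenReference-class
#' @export
setGeneric("normalDispersions",
           function(x) standardGeneric("normalDispersions"))

#' @rdname FrozenReference-class
#' @export
setGeneric("classifiers", function(x) standardGeneric("classifiers"))

#' @rdname FrozenReference-class
#' @export
setGeneric("refProvenance", function(x) standardGeneric("refProvenance"))

#' @rdname PatientProfile-class
#' @param x a \linkS4class{PatientProfile}.
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname PatientProfile-class
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname PatientProfile-class
#' @export
setGeneric("sizeFactor", function(x) standardGeneric("sizeFactor"))

#' @rdname PatientProfile-class
#' @export
setGeneric("normCounts", function(x) standardGeneric("normCounts"))

#' @rdname PatientProfile-class
#' @export
setGeneric("logExpr", function(x) standardGeneric("logExpr"))

#' @rdname PatientProfile-class
#' @export
setGeneric("cutoffValue", function(x) standardGeneric("cutoffValue"))

#' @rdname PatientProfile-class
#' @export
setGeneric("reliableGenes", function(x) standardGeneric("reliableGenes"))

#' @rdname CentroidModel-class
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname Prediction-class
#' @param x a \linkS4class{Prediction}.
#' @export
setGeneric("predictedLabel", function(x) standardGeneric("predictedLabel"))

#' @rdname Prediction-class
#' @export
setGeneric("classProbabilities",
           function(x) standardGeneric("classProbabilities"))
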