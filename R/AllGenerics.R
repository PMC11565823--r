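#' Accessors for polysomeFate classes
#'
#' Small accessor layer over the S4 containers: raw counts and stage axis of
#' a [FractionExperiment-class]; values/name/scale of a
#' [LayerMatrix-class]; centers, memberships and objective trace of a
#' [FuzzyModel-class]; core sets and peak stages of a
#' [ClusterCores-class].
#'
#' @param x An object of the documented class.
#' @return The extracted component (see the individual generics).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fractionCounts", function(x) standardGeneric("fractionCounts"))

#' @rdname accessors
#' @export
setMethod("fractionCounts", "FractionExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @rdname accessors
#' @export
setMethod("stageLabels", "FractionExperiment", function(x)
  S4Vectors::metadata(x)$stageAxis)

#' @rdname accessors
#' @export
setMethod("stageLabels", "LayerMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))

#' @rdname accessors
#' @export
setMethod("layerValues", "LayerMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("layerName", function(x) standardGeneric("layerName"))

#' @rdname accessors
#' @export
setMethod("layerName", "LayerMatrix", function(x) x@layer)

#' @rdname accessors
#' @export
setGeneric("isLogScale", function(x) standardGeneric("isLogScale"))

#' @rdname accessors
#' @export
setMethod("isLogScale", "LayerMatrix", function(x) x@logScale)

#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @rdname accessors
#' @export
setMethod("clusterCenters", "FuzzyModel", function(x) x@centers)

#' @rdname accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname accessors
#' @export
setMethod("memberships", "FuzzyModel", function(x) x@memberships)

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setMethod("objectiveTrace", "FuzzyModel", function(x) x@objective)

#' @rdname accessors
#' @export
setGeneric("coreSets", function(x) standardGeneric("coreSets"))

#' @rdname accessors
#' @export
setMethod("coreSets", "ClusterCores", function(x) x@coreSets)

#' @rdname accessors
#' @export
setGeneric("peakStages", function(x) standardGeneric("peakStages"))

#' @rdname accessors
#' @export
setMethod("peakStages", "ClusterCores", function(x) x@peakStage)

#' @rdname accessors
#' @export
setGeneric("unassignedGenes", function(x) standardGeneric("unassignedGenes"))

#' @rdname accessors
#' @export
setMethod("unassignedGenes", "ClusterCores", function(x) x@unassigned)
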