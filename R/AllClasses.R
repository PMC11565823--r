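#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' FractionExperiment: fraction-resolved counts with sample annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container for raw
#' integer read counts of genes across gradient-fraction and
#' whole-transcriptome libraries. Each sample (column) is annotated with a
#' developmental stage, a compartment (one of F1-F10 or "total") and a
#' replicate id; the ordered stage axis is stored in the metadata.
#'
#' Validity requires: a single integer "counts" assay with no negative and
#' no missing entries; unique gene ids; `colData` columns `stage`,
#' `compartment`, `replicate`; every stage present on the stored stage axis;
#' every compartment one of F1-F10/total; positive integer replicates; and
#' unique (stage, compartment, replicate) triples.
#'
#' @seealso [FractionExperiment()], [readFractionCounts()],
#'   [aggregateLayers()]
#' @export
setClass("FractionExperiment", contains = "SummarizedExperiment")

setValidity("FractionExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(cnt))
    msg <- c(msg, "counts contain missing values")
  else {
    if (any(cnt < 0)) {
      bad <- which(cnt < 0, arr.ind = TRUE)[1L, ]
      msg <- c(msg, sprintf("negative count for gene '%s' in sample '%s'",
                            rownames(cnt)[bad[1L]], colnames(cnt)[bad[2L]]))
    }
    if (any(cnt != round(cnt))) {
      bad <- which(cnt != round(cnt), arr.ind = TRUE)[1L, ]
      msg <- c(msg, sprintf("non-integer count for gene '%s' in sample '%s'",
                            rownames(cnt)[bad[1L]], colnames(cnt)[bad[2L]]))
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("stage", "compartment", "replicate")
  if (!all(need %in% colnames(cd)))
    return(c(msg, paste("colData must contain columns:",
                        paste(need, collapse = ", "))))
  axis <- S4Vectors::metadata(object)$stageAxis
  if (is.null(axis))
    msg <- c(msg, "metadata()$stageAxis is missing")
  else if (!all(cd$stage %in% axis))
    msg <- c(msg, paste("unknown stage label:",
                        paste(unique(cd$stage[!cd$stage %in% axis]),
                              collapse = ", ")))
  if (!all(cd$compartment %in% compartmentLabels()))
    msg <- c(msg, paste("unknown compartment:",
                        paste(unique(
                          cd$compartment[!cd$compartment %in%
                                           compartmentLabels()]),
                          collapse = ", ")))
  rep <- cd$replicate
  if (anyNA(rep) || any(rep != round(rep)) || any(rep < 1))
    msg <- c(msg, "replicate ids must be positive integers")
  key <- paste(cd$stage, cd$compartment, cd$replicate)
  if (anyDuplicated(key))
    msg <- c(msg, paste("duplicated (stage, compartment, replicate) triple:",
                        key[duplicated(key)][1L]))
  if (length(msg)) msg else TRUE
})

#' Construct a FractionExperiment
#'
#' @param counts Integer matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames.
#' @param sampleData A `data.frame` or [S4Vectors::DataFrame] with one row
#'   per sample (rownames or a `sample_id` column matching `colnames(counts)`)
#'   and columns `stage`, `compartment`, `replicate`.
#' @param stages Ordered stage axis, see [stageAxis()].
#' @return A validated [FractionExperiment-class] object.
#' @examples
#' cnt <- matrix(0:5, nrow = 3,
#'               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' sd <- data.frame(sample_id = c("s1", "s2"), stage = "GV",
#'                  compartment = c("F1", "F2"), replicate = 1L)
#' fe <- FractionExperiment(cnt, sd)
#' @export
FractionExperiment <- function(counts, sampleData, stages = stageAxis()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "numeric"
  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% colnames(sampleData)) {
    rownames(sampleData) <- as.character(sampleData$sample_id)
    sampleData$sample_id <- NULL
  }
  if (is.null(colnames(counts)))
    stop("'counts' must have sample ids as colnames")
  missing_in_sheet <- setdiff(colnames(counts), rownames(sampleData))
  if (length(missing_in_sheet))
    stop("samples absent from the sample sheet: ",
         paste(missing_in_sheet, collapse = ", "))
  missing_in_counts <- setdiff(rownames(sampleData), colnames(counts))
  if (length(missing_in_counts))
    stop("sheet samples absent from the counts table: ",
         paste(missing_in_counts, collapse = ", "))
  sampleData <- sampleData[colnames(counts), , drop = FALSE]
  sampleData$stage <- as.character(sampleData$stage)
  sampleData$compartment <- as.character(sampleData$compartment)
  sampleData$replicate <- as.integer(sampleData$replicate)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sampleData))
  S4Vectors::metadata(se)$stageAxis <- stageAxis(stages)
  methods::validObject(obj <- methods::new("FractionExperiment", se))
  obj
}

#' LayerMatrix: per-layer gene-by-stage expression
#'
#' One translational layer (free, monosome, polysome or transcriptome)
#' summarised as a genes x stages matrix, either in CPM or (the default
#' output of [aggregateLayers()]) replicate-averaged log2(CPM + 1).
#'
#' @slot layer Layer name, one of free/monosome/polysome/transcriptome.
#' @slot values Non-negative numeric matrix, genes x stages.
#' @slot logScale Logical; `TRUE` when values are log2(CPM + 1).
#' @export
setClass("LayerMatrix",
         representation(layer = "character", values = "matrix",
                        logScale = "logical"))

setValidity("LayerMatrix", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% layerNames())
    msg <- c(msg, paste("layer must be one of:",
                        paste(layerNames(), collapse = ", ")))
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry gene ids (rownames) and stage labels (colnames)")
  if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (length(object@logScale) != 1L || is.na(object@logScale))
    msg <- c(msg, "logScale must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' @rdname LayerMatrix-class
#' @param layer Layer name.
#' @param values Numeric genes x stages matrix with dimnames.
#' @param logScale Whether `values` are on log2(CPM + 1) scale.
#' @export
LayerMatrix <- function(layer, values, logScale = TRUE) {
  methods::new("LayerMatrix", layer = layer, values = as.matrix(values),
               logScale = logScale)
}

#' FuzzyModel: fitted fuzzy c-means model
#'
#' Result of [fuzzyCMeans()]: cluster centers, the soft membership matrix,
#' the fuzzifier, the per-iteration objective trace and convergence state.
#'
#' @slot centers Numeric c x p matrix of cluster centers.
#' @slot memberships Numeric n x c matrix; each row sums to 1.
#' @slot m Fuzzifier (> 1).
#' @slot objective Numeric vector of the objective J_m per iteration
#'   (non-increasing).
#' @slot seed Integer seed used for initialization.
#' @slot nIter Iterations to convergence of the selected restart.
#' @slot converged Logical; `FALSE` when `maxIter` was hit.
#' @export
setClass("FuzzyModel",
         representation(centers = "matrix", memberships = "matrix",
                        m = "numeric", objective = "numeric",
                        seed = "integer", nIter = "integer",
                        converged = "logical"))

setValidity("FuzzyModel", function(object) {
  msg <- character()
  if (any(!is.finite(object@centers)))
    msg <- c(msg, "centers must be finite")
  u <- object@memberships
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (any(abs(rowSums(u) - 1) > 1e-9))
    msg <- c(msg, "membership rows must sum to 1")
  if (ncol(u) != nrow(object@centers))
    msg <- c(msg, "ncol(memberships) must equal nrow(centers)")
  if (object@m <= 1)
    msg <- c(msg, "fuzzifier m must exceed 1")
  if (length(msg)) msg else TRUE
})

#' ClusterCores: high-membership gene sets per cluster
#'
#' Cluster cores are the genes whose membership in a cluster reaches a
#' cutoff; with cutoff above 0.5 cores are pairwise disjoint because
#' membership rows sum to 1. Each core carries the stage at which its
#' cluster center peaks, the basis for stage-specific gene sets and
#' delayed-activation calls.
#'
#' @slot threshold Membership cutoff in (0, 1].
#' @slot coreSets Named list of character vectors of gene ids, one per
#'   cluster.
#' @slot peakStage Integer vector, per cluster the stage index of the
#'   center's maximum.
#' @slot unassigned Character vector of gene ids in no core.
#' @export
setClass("ClusterCores",
         representation(threshold = "numeric", coreSets = "list",
                        peakStage = "integer", unassigned = "character"))

setValidity("ClusterCores", function(object) {
  msg <- character()
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold > 1)
    msg <- c(msg, "threshold must lie in (0, 1]")
  if (length(object@coreSets) != length(object@peakStage))
    msg <- c(msg, "one peak stage per core set is required")
  if (length(object@peakStage) && any(object@peakStage < 1L))
    msg <- c(msg, "peak stages must be positive indices")
  if (object@threshold > 0.5) {
    all_ids <- unlist(object@coreSets, use.names = FALSE)
    if (anyDuplicated(all_ids))
      msg <- c(msg, "core sets must be pairwise disjoint at threshold > 0.5")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FractionExperiment", function(object) {
  methods::callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat("stages: ", paste(S4Vectors::metadata(object)$stageAxis,
                        collapse = " -> "), "\n", sep = "")
  cat("compartments:", paste(sort(unique(cd$compartment)), collapse = " "),
      "\n")
})

setMethod("show", "LayerMatrix", function(object) {
  cat(sprintf("LayerMatrix '%s': %d genes x %d stages (%s)\n",
              object@layer, nrow(object@values), ncol(object@values),
              if (object@logScale) "log2(CPM+1)" else "CPM"))
})

setMethod("show", "FuzzyModel", function(object) {
  cat(sprintf(
    "FuzzyModel: %d clusters, %d genes, m = %.3g, %d iterations (%s)\n",
    nrow(object@centers), nrow(object@memberships), object@m, object@nIter,
    if (object@converged) "converged" else "max iterations reached"))
  cat(sprintf("final objective J_m = %.6g\n",
              object@objective[length(object@objective)]))
})

setMethod("show", "ClusterCores", function(object) {
  cat(sprintf(
    "ClusterCores: %d clusters at membership >= %.2f; %d genes unassigned\n",
    length(object@coreSets), object@threshold, length(object@unassigned)))
  cat("core sizes:", paste(vapply(object@coreSets, length, 1L),
                           collapse = " "), "\n")
})
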