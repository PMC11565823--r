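#' Developmental stage axis
#'
#' The analyses in this package are indexed by an ordered axis of
#' developmental stages. Lags between events (e.g. monosome occupancy
#' followed by polysome occupancy) are differences of stage indices, so the
#' order is configuration, never inferred from data. The default axis covers
#' mouse oocyte maturation and pre-implantation development.
#'
#' @param stages Character vector of unique, ordered stage labels.
#' @return For `stageAxis()`, a character vector of class `"StageAxis"`.
#' @examples
#' stageAxis()
#' stageIndex("2-Cell", stageAxis())
#' @export
stageAxis <- function(stages = defaultStages()) {
  if (!is.character(stages) || length(stages) < 1L)
    stop("'stages' must be a non-empty character vector")
  if (anyDuplicated(stages))
    stop("stage labels must be unique: ",
         paste(unique(stages[duplicated(stages)]), collapse = ", "))
  if (anyNA(stages) || any(!nzchar(stages)))
    stop("stage labels must be non-missing, non-empty strings")
  structure(as.character(stages), class = "StageAxis")
}

#' @rdname stageAxis
#' @export
defaultStages <- function() {
  c("GV", "MII", "zygote", "2-Cell", "4-Cell", "8-Cell",
    "morula", "blastocyst")
}

#' @rdname stageAxis
#' @param stage Stage label(s) to resolve.
#' @param axis A stage axis as returned by [stageAxis()].
#' @return For `stageIndex()`, the integer position(s) of `stage` on `axis`.
#' @export
stageIndex <- function(stage, axis = stageAxis()) {
  idx <- match(stage, axis)
  if (anyNA(idx))
    stop("unknown stage label: ",
         paste(unique(stage[is.na(idx)]), collapse = ", "),
         " (axis: ", paste(axis, collapse = ", "), ")")
  idx
}

# Gradient compartments: ten fractions plus the whole-transcriptome library.
fractionLabels <- function() paste0("F", 1:10)

compartmentLabels <- function() c(fractionLabels(), "total")

#' Layer membership of gradient fractions
#'
#' Equal-volume sucrose-gradient fractions are grouped into three layers by
#' ribosome load: F1-F2 carry mostly free (unbound) mRNA, F3-F5 mostly
#' monosome-bound mRNA and F6-F10 mostly polysome-bound mRNA. The separate
#' whole-transcriptome libraries form the fourth, "transcriptome" layer.
#'
#' @return Named list mapping each layer to its member compartment labels.
#' @examples
#' layerFractions()$monosome
#' @export
layerFractions <- function() {
  list(free          = c("F1", "F2"),
       monosome      = c("F3", "F4", "F5"),
       polysome      = c("F6", "F7", "F8", "F9", "F10"),
       transcriptome = "total")
}

layerNames <- function() names(layerFractions())
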