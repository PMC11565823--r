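#' Read fraction-resolved counts and a sample sheet
#'
#' Reads a gene x sample tab-separated count table (gene ids in the first
#' column, sample ids in the header) together with a sample sheet mapping
#' every sample id to a developmental stage, a gradient compartment
#' (F1-F10 or "total") and a replicate id, and returns a validated
#' [FractionExperiment-class]. Samples present in only one of the two files
#' are an error, as are duplicate gene ids, unknown stage labels and
#' negative or non-integer counts.
#'
#' @param countsPath Path to the tab-separated count table.
#' @param sheetPath Path to the tab-separated sample sheet with columns
#'   `sample_id`, `stage`, `compartment`, `replicate`.
#' @param stages Ordered stage axis, see [stageAxis()].
#' @return A [FractionExperiment-class].
#' @seealso [writeFractionExperiment()] for the inverse operation.
#' @export
readFractionCounts <- function(countsPath, sheetPath, stages = stageAxis()) {
  counts <- readTsvMatrix(countsPath)
  sheet <- utils::read.delim(sheetPath, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "compartment", "replicate")
  if (!all(need %in% colnames(sheet)))
    stop("sample sheet '", sheetPath, "' must have columns: ",
         paste(need, collapse = ", "))
  FractionExperiment(counts, sheet, stages = stages)
}

# Read a TSV with row ids in the first column into a numeric matrix.
readTsvMatrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("malformed table '", path,
         "': need an id column plus at least one data column")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(mat), nrow = nrow(mat)))) & !is.na(mat),
      arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric value for gene '%s' in column '%s' of '%s'",
                   ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]], path))
    storage.mode(mat) <- "numeric"
  }
  rownames(mat) <- ids
  mat
}

#' Write a gene-by-column table as TSV
#'
#' Writes a matrix (or a [LayerMatrix-class], whose values are taken) as a
#' UTF-8 tab-separated file with the gene ids in a first `gene_id` column
#' and a header row. Reading back with [readTsvMatrix] logic reproduces the
#' values exactly for integers and to full double precision otherwise.
#'
#' @param x Matrix or data.frame with rownames, or a [LayerMatrix-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeTsv <- function(x, path) {
  if (methods::is(x, "LayerMatrix")) x <- layerValues(x)
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("refusing to write an empty table to '", path, "'")
  if (is.null(rownames(x)))
    stop("table must have row ids (rownames)")
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' @rdname readFractionCounts
#' @param x A [FractionExperiment-class] to serialize.
#' @export
writeFractionExperiment <- function(x, countsPath, sheetPath) {
  stopifnot(methods::is(x, "FractionExperiment"))
  writeTsv(fractionCounts(x), countsPath)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  sheet <- data.frame(sample_id = rownames(cd),
                      stage = cd$stage,
                      compartment = cd$compartment,
                      replicate = cd$replicate,
                      stringsAsFactors = FALSE)
  utils::write.table(sheet, file = sheetPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(c(countsPath, sheetPath))
}

#' Read a companion modality table
#'
#' Companion data (protein log-intensity, poly(A) tail length in
#' nucleotides, or binary m6A status) come as gene x stage TSV tables.
#' Stage labels may use dataset-specific aliases; `stageAliases` maps them
#' onto the analysis stage axis (e.g. `c("1-cell" = "zygote")`).
#'
#' @param path TSV path, gene ids in the first column, stage labels in the
#'   header.
#' @param modality One of `"protein"`, `"polyA"`, `"m6A"`.
#' @param stages Stage axis the columns must map onto.
#' @param stageAliases Named character vector renaming file columns to axis
#'   labels.
#' @return Numeric genes x stages matrix with an attribute `modality`.
#' @export
readCompanionTable <- function(path, modality = c("protein", "polyA", "m6A"),
                               stages = stageAxis(),
                               stageAliases = character()) {
  modality <- match.arg(modality)
  mat <- readTsvMatrix(path)
  cn <- colnames(mat)
  hit <- cn %in% names(stageAliases)
  cn[hit] <- stageAliases[cn[hit]]
  colnames(mat) <- cn
  unknown <- setdiff(cn, stages)
  if (length(unknown))
    stop("companion stages not on the stage axis: ",
         paste(unknown, collapse = ", "))
  if (modality == "m6A" && !all(mat %in% c(0, 1)))
    stop("m6A companion values must be 0/1 flags")
  structure(mat, modality = modality)
}
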