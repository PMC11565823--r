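#' Counts-per-million normalization
#'
#' Scales every sample (column) to counts per million mapped reads: each
#' column of the result sums to 1e6. A sample with no counts at all cannot
#' be normalized and is reported by name.
#'
#' @param x A [FractionExperiment-class] or a non-negative counts matrix
#'   with sample columns.
#' @return Numeric matrix of CPM values, same dimnames as the input counts.
#' @examples
#' cpmNormalize(matrix(c(5, 5), 2, dimnames = list(c("a", "b"), "s1")))
#' @export
cpmNormalize <- function(x) {
  cnt <- if (methods::is(x, "FractionExperiment")) fractionCounts(x) else
    as.matrix(x)
  if (any(cnt < 0)) stop("counts must be non-negative")
  tot <- colSums(cnt)
  zero <- tot == 0
  if (any(zero))
    stop("sample(s) with all-zero counts cannot be CPM-normalized: ",
         paste(colnames(cnt)[zero], collapse = ", "))
  sweep(cnt, 2, tot, "/") * 1e6
}

#' Aggregate gradient fractions into translational layers
#'
#' Builds the four per-layer gene x stage expression matrices from raw
#' fraction counts: free (F1-F2), monosome (F3-F5), polysome (F6-F10) and
#' transcriptome ("total" libraries). For each layer, stage and replicate
#' the member-fraction raw counts are summed per gene, the summed library
#' is CPM-normalized, and replicates are averaged on the log2(CPM + 1)
#' scale (summing raw counts weights fractions by their actual RNA mass;
#' per-fraction CPM averaging is available via `perFractionCPM`).
#'
#' @param x A [FractionExperiment-class].
#' @param log Return log2(CPM + 1) (default); `FALSE` returns
#'   replicate-averaged CPM.
#' @param perFractionCPM If `TRUE`, CPM-normalize each fraction library
#'   first and average member fractions, instead of summing raw counts.
#' @return Named list of four [LayerMatrix-class] objects.
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 40, seed = 2))
#' layers <- aggregateLayers(sim$experiment)
#' layers$polysome
#' @export
aggregateLayers <- function(x, log = TRUE, perFractionCPM = FALSE) {
  stopifnot(methods::is(x, "FractionExperiment"))
  cd <- SummarizedExperiment::colData(x)
  cnt <- fractionCounts(x)
  axis <- stageLabels(x)
  stagesPresent <- axis[axis %in% unique(cd$stage)]
  lf <- layerFractions()
  out <- list()
  for (ly in layerNames()) {
    members <- lf[[ly]]
    vals <- matrix(NA_real_, nrow(cnt), length(stagesPresent),
                   dimnames = list(rownames(cnt), stagesPresent))
    for (st in stagesPresent) {
      inStage <- cd$stage == st & cd$compartment %in% members
      have <- unique(cd$compartment[inStage])
      if (!length(have))
        stop(sprintf("stage '%s' has no '%s'-layer fractions (%s)",
                     st, ly, paste(members, collapse = ", ")))
      missing <- setdiff(members, have)
      if (length(missing))
        stop(sprintf("stage '%s' lacks fraction(s) %s of the '%s' layer",
                     st, paste(missing, collapse = ", "), ly))
      reps <- sort(unique(cd$replicate[inStage]))
      perRep <- sapply(reps, function(r) {
        sel <- which(inStage & cd$replicate == r)
        if (length(sel) != length(members))
          stop(sprintf(
            "stage '%s' replicate %d has %d of %d '%s' fractions",
            st, r, length(sel), length(members), ly))
        if (perFractionCPM) {
          cp <- cpmNormalize(cnt[, sel, drop = FALSE])
          rowMeans(cp)
        } else {
          lib <- rowSums(cnt[, sel, drop = FALSE])
          if (sum(lib) == 0)
            stop(sprintf("stage '%s' replicate %d '%s' library is empty",
                         st, r, ly))
          lib / sum(lib) * 1e6
        }
      })
      perRep <- matrix(perRep, nrow = nrow(cnt))   # 1-gene edge case
      vals[, st] <- rowMeans(log2(perRep + 1))
    }
    if (!log) vals <- 2^vals - 1
    out[[ly]] <- LayerMatrix(ly, vals, logScale = log)
  }
  out
}

#' Standardize time-course profiles
#'
#' Per-gene z-scoring across stages (sample standard deviation), the
#' standard preprocessing before fuzzy time-course clustering: every
#' retained row has mean 0 and standard deviation 1. Rows with (numerically)
#' zero variance carry no temporal signal and are moved to the excluded
#' set.
#'
#' @param x A [LayerMatrix-class] or a genes x stages matrix with at least
#'   two columns.
#' @param sdTol Rows with standard deviation below this are excluded.
#' @return List of class `"StandardizedProfile"` with elements `values`
#'   (retained z-scored rows) and `excluded` (dropped gene ids).
#' @examples
#' standardizeProfiles(matrix(1:6, 2, byrow = TRUE,
#'   dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
#' @export
standardizeProfiles <- function(x, sdTol = 1e-12) {
  vals <- if (methods::is(x, "LayerMatrix")) layerValues(x) else
    as.matrix(x)
  if (ncol(vals) < 2L)
    stop("standardization needs at least 2 stages")
  mu <- rowMeans(vals)
  sd <- apply(vals, 1L, stats::sd)
  keep <- is.finite(sd) & sd >= sdTol
  z <- (vals[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  structure(list(values = z, excluded = rownames(vals)[!keep]),
            class = "StandardizedProfile")
}

#' @export
print.StandardizedProfile <- function(x, ...) {
  cat(sprintf(
    "StandardizedProfile: %d genes x %d stages (%d excluded)\n",
    nrow(x$values), ncol(x$values), length(x$excluded)))
  invisible(x)
}
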