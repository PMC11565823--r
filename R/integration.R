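#' Stage-lagged cross-omics correlation
#'
#' Correlates, over shared genes, the polysome-layer expression at every
#' stage with a companion modality (protein log-intensity or poly(A) tail
#' length) at every companion stage. Rank correlation is the default since
#' the two modalities live on incommensurate scales. Cells with fewer than
#' `minGenes` genes carrying finite values are flagged missing (`NA`).
#' Binary m6A tables are rejected; use [m6aLayerPercentage()] for those.
#'
#' @param poly Polysome [LayerMatrix-class].
#' @param companion Genes x stages numeric matrix (see
#'   [readCompanionTable()]); an attribute `modality = "m6A"` is rejected.
#' @param method `"rank"` (Spearman, default) or `"linear"` (Pearson).
#' @param minGenes Minimum shared genes per cell.
#' @return List of class `"LagCorrelationMatrix"` with `r` (polysome
#'   stages x companion stages correlation matrix) and `nGenes` (genes per
#'   cell).
#' @export
laggedCorrelation <- function(poly, companion, method = c("rank", "linear"),
                              minGenes = 10L) {
  method <- match.arg(method)
  stopifnot(methods::is(poly, "LayerMatrix"))
  if (identical(attr(companion, "modality"), "m6A"))
    stop("binary m6A tables have no meaningful correlation; ",
         "use m6aLayerPercentage()")
  pv <- layerValues(poly)
  companion <- as.matrix(companion)
  shared <- intersect(rownames(pv), rownames(companion))
  if (length(shared) < minGenes)
    stop("fewer than ", minGenes, " shared genes")
  pv <- pv[shared, , drop = FALSE]
  cv <- companion[shared, , drop = FALSE]
  corMethod <- if (method == "rank") "spearman" else "pearson"
  r <- matrix(NA_real_, ncol(pv), ncol(cv),
              dimnames = list(colnames(pv), colnames(cv)))
  n <- r
  for (s in seq_len(ncol(pv))) for (t in seq_len(ncol(cv))) {
    ok <- is.finite(pv[, s]) & is.finite(cv[, t])
    n[s, t] <- sum(ok)
    if (n[s, t] >= minGenes)
      r[s, t] <- stats::cor(pv[ok, s], cv[ok, t], method = corMethod)
  }
  structure(list(r = r, nGenes = n, method = method),
            class = "LagCorrelationMatrix")
}

#' @export
print.LagCorrelationMatrix <- function(x, ...) {
  cat(sprintf("LagCorrelationMatrix (%s): %d polysome stages x %d companion stages\n",
              x$method, nrow(x$r), ncol(x$r)))
  print(round(x$r, 3))
  invisible(x)
}

#' Best companion lag per polysome stage
#'
#' For every polysome stage (row of a lag-correlation matrix), reports the
#' companion stage with the highest correlation and the signed offset
#' (companion stage index minus polysome stage index); equal maxima break
#' to the earlier companion stage and are flagged. The summary reports the
#' modal lag magnitude over rows together with its direction:
#' `companion_lags` when the companion follows the polysome signal (as
#' protein abundance does) and `companion_leads` when it precedes it (as
#' poly(A) tail length does); `same_stage` for lag 0.
#'
#' @param x A `"LagCorrelationMatrix"` from [laggedCorrelation()].
#' @return List with `perStage` (`data.frame`: `poly_stage`,
#'   `best_companion_stage`, `r`, `signed_lag`, `tie`) and `summary`
#'   (`modal_lag` magnitude, `direction`, `mean_r` over the modal rows).
#' @export
bestLag <- function(x) {
  stopifnot(inherits(x, "LagCorrelationMatrix"))
  r <- x$r
  rows <- list()
  for (s in seq_len(nrow(r))) {
    v <- r[s, ]
    if (all(is.na(v))) stop("row '", rownames(r)[s], "' is all missing")
    best <- max(v, na.rm = TRUE)
    hits <- which(!is.na(v) & v >= best - 1e-12)
    rows[[s]] <- data.frame(poly_stage = rownames(r)[s],
                            best_companion_stage = colnames(r)[hits[1L]],
                            r = v[hits[1L]],
                            signed_lag = hits[1L] - s,
                            tie = length(hits) > 1L,
                            stringsAsFactors = FALSE)
  }
  perStage <- do.call(rbind, rows)
  rownames(perStage) <- NULL
  mag <- abs(perStage$signed_lag)
  tabulated <- table(mag)
  modal <- as.integer(names(tabulated)[which.max(tabulated)])
  modalRows <- mag == modal
  signs <- sign(perStage$signed_lag[modalRows])
  direction <- if (modal == 0L) "same_stage"
    else if (sum(signs) >= 0) "companion_lags" else "companion_leads"
  list(perStage = perStage,
       summary = list(modal_lag = modal, direction = direction,
                      mean_r = mean(perStage$r[modalRows])))
}

#' Percentage of m6A-flagged genes per layer-stage gene set
#'
#' For stage-specific gene sets of each layer (typically cluster cores)
#' and per-stage m6A gene sets, computes 100 * |set intersect m6A| / |set|.
#' Empty sets are flagged with `NA`.
#'
#' @param stageSets Named list (per layer) of named lists (per stage) of
#'   gene-id character vectors.
#' @param m6aSets Named list (per stage) of m6A-flagged gene ids.
#' @return Numeric layers x stages matrix of percentages.
#' @export
m6aLayerPercentage <- function(stageSets, m6aSets) {
  stages <- names(m6aSets)
  out <- matrix(NA_real_, length(stageSets), length(stages),
                dimnames = list(names(stageSets), stages))
  for (ly in names(stageSets)) for (st in stages) {
    set <- stageSets[[ly]][[st]]
    if (!is.null(set) && length(set))
      out[ly, st] <- 100 * length(intersect(set, m6aSets[[st]])) /
        length(set)
  }
  out
}
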