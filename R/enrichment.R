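#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values (monotone after
#' sorting, capped at 1), delegated to the standard implementation after
#' validating the input range.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Polysome-versus-monosome occupancy test at one stage
#'
#' For one developmental stage, each replicate's counts are summed over the
#' polysome fractions (F6-F10) and over the monosome fractions (F3-F5);
#' each summed library is CPM-normalized and per gene a Welch two-sample
#' t-test compares the replicate log2(CPM + 1) values between the two
#' groups. The log2 fold change is the polysome-minus-monosome mean
#' difference. Genes below detection (CPM < `minCpm` in every replicate of
#' both groups) are excluded before testing; p-values are BH-adjusted
#' across the tested genes. A gene is called `poly_up` when
#' log2FC > `lfcThreshold` with significance below `alpha`, `mono_up` for
#' the mirrored condition, otherwise `ns`. Significance uses the FDR by
#' default (`useFdr = FALSE` switches to raw p-values).
#'
#' @param x A [FractionExperiment-class].
#' @param stage Stage label to test.
#' @param minCpm Detection threshold.
#' @param alpha Significance threshold on FDR (or raw p).
#' @param lfcThreshold Absolute log2 fold-change threshold (1 = 2-fold).
#' @param useFdr Use BH-adjusted p-values for calling (default).
#' @return `data.frame` with columns `gene_id`, `stage`, `log2fc`, `p`,
#'   `fdr`, `call`; untested genes are absent.
#' @export
polyVsMonoTest <- function(x, stage, minCpm = 1, alpha = 0.05,
                           lfcThreshold = 1, useFdr = TRUE) {
  stopifnot(methods::is(x, "FractionExperiment"))
  cd <- SummarizedExperiment::colData(x)
  cnt <- fractionCounts(x)
  lf <- layerFractions()
  groupCpm <- function(members) {
    sel <- cd$stage == stage & cd$compartment %in% members
    reps <- sort(unique(cd$replicate[sel]))
    if (length(reps) < 2L)
      stop("need at least 2 replicates of the ",
           paste(members, collapse = "/"), " fractions at stage '",
           stage, "'")
    out <- vapply(reps, function(r) {
      cols <- which(sel & cd$replicate == r)
      lib <- rowSums(cnt[, cols, drop = FALSE])
      lib / sum(lib) * 1e6
    }, numeric(nrow(cnt)))
    colnames(out) <- paste0("rep", reps)
    out
  }
  polyCpm <- groupCpm(lf$polysome)
  monoCpm <- groupCpm(lf$monosome)
  detected <- rowSums(polyCpm >= minCpm) > 0L |
    rowSums(monoCpm >= minCpm) > 0L
  lp <- log2(polyCpm[detected, , drop = FALSE] + 1)
  lm <- log2(monoCpm[detected, , drop = FALSE] + 1)
  n <- nrow(lp)
  pval <- numeric(n)
  lfc <- numeric(n)
  for (g in seq_len(n)) {
    lfc[g] <- mean(lp[g, ]) - mean(lm[g, ])
    if (stats::sd(lp[g, ]) == 0 && stats::sd(lm[g, ]) == 0) {
      pval[g] <- if (lfc[g] == 0) 1 else 0
    } else {
      pval[g] <- stats::t.test(lp[g, ], lm[g, ])$p.value
    }
  }
  fdr <- bhAdjust(pval)
  sig <- if (useFdr) fdr else pval
  call <- rep("ns", n)
  call[lfc > lfcThreshold & sig < alpha] <- "poly_up"
  call[lfc < -lfcThreshold & sig < alpha] <- "mono_up"
  data.frame(gene_id = rownames(lp), stage = stage, log2fc = lfc,
             p = pval, fdr = fdr, call = call, stringsAsFactors = FALSE)
}

#' Translational switch genes at a stage transition
#'
#' Genes enriched in the monosome layer at one stage and in the polysome
#' layer at the next stage: the "active genes" of a developmental
#' transition (stored on monosomes, then translated).
#'
#' @param results List of per-stage `data.frame`s from [polyVsMonoTest()],
#'   named by stage, or one row-bound `data.frame` covering both stages.
#' @param from,to Stage labels of the transition.
#' @return Character vector of switch gene ids.
#' @export
switchGenes <- function(results, from, to) {
  if (is.data.frame(results)) {
    tab <- results
  } else {
    tab <- do.call(rbind, results)
  }
  missing <- setdiff(c(from, to), unique(tab$stage))
  if (length(missing))
    stop("no test results for stage(s): ", paste(missing, collapse = ", "))
  monoUp <- tab$gene_id[tab$stage == from & tab$call == "mono_up"]
  polyUp <- tab$gene_id[tab$stage == to & tab$call == "poly_up"]
  sort(intersect(monoUp, polyUp))
}
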