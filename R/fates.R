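#' Broad translational groups of the six modes
#'
#' Mode 1 is monosome-specific, modes 2-5 are actively translated and
#' mode 6 is untranslated; anything else is unassigned.
#'
#' @param mode Integer vector of mode labels (1-6, `NA` for unassigned).
#' @return Character vector of broad groups.
#' @export
broadGroup <- function(mode) {
  out <- rep("unassigned", length(mode))
  out[!is.na(mode) & mode == 1L] <- "monosome_specific"
  out[!is.na(mode) & mode %in% 2:5] <- "actively_translated"
  out[!is.na(mode) & mode == 6L] <- "untranslated"
  out
}

#' Assign selectivity modes at one stage
#'
#' For one developmental stage, every gene's feature vector is its
#' (transcriptome, monosome, polysome) layer level, each layer z-scored
#' across genes. The features are fuzzy-clustered with c = 6 and the
#' cluster centers are labeled with the canonical mode templates via
#' [labelModes()]. A gene takes the mode of its highest-membership cluster
#' when that membership reaches `threshold`, otherwise it is unassigned.
#' Clustering is initialized at the template vectors themselves, which
#' anchors the decomposition and makes it deterministic.
#'
#' @param layers Named list of [LayerMatrix-class] objects containing at
#'   least `transcriptome`, `monosome` and `polysome` over a shared gene
#'   set (as from [aggregateLayers()]).
#' @param stage Stage label to assign.
#' @param c Number of clusters (6; configurable for exploration, but mode
#'   labeling requires 6).
#' @param m Fuzzifier, see [fuzzyCMeans()].
#' @param threshold Membership cutoff below which a gene stays unassigned.
#' @param seed Seed forwarded to [fuzzyCMeans()].
#' @param initAtTemplates Initialize at the canonical templates (default);
#'   `FALSE` uses seeded random restarts instead.
#' @return `data.frame` with columns `gene_id`, `stage`, `mode`,
#'   `broad_group`, `membership`.
#' @export
assignModes <- function(layers, stage, c = 6L, m = 1.25, threshold = 0.5,
                        seed = 1L, initAtTemplates = TRUE) {
  need <- c("transcriptome", "monosome", "polysome")
  stopifnot(all(need %in% names(layers)))
  genes <- rownames(layerValues(layers$transcriptome))
  for (ly in need)
    if (!identical(rownames(layerValues(layers[[ly]])), genes))
      stop("layer matrices must share one gene set in the same order")
  feat <- vapply(need, function(ly) layerValues(layers[[ly]])[, stage],
                 numeric(length(genes)))
  zfeat <- apply(feat, 2L, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12)
      stop("layer has no variation across genes at stage '", stage, "'")
    (v - mean(v)) / s
  })
  rownames(zfeat) <- genes
  init <- if (initAtTemplates && c == 6L) modeTemplates() else NULL
  model <- fuzzyCMeans(zfeat, c = c, m = m, seed = seed,
                       initCenters = init)
  if (c != 6L)
    stop("mode labeling is defined for c = 6 clusters")
  modeOf <- labelModes(clusterCenters(model))
  u <- memberships(model)
  top <- max.col(u, ties.method = "first")
  topU <- u[cbind(seq_len(nrow(u)), top)]
  mode <- ifelse(topU >= threshold, modeOf[top], NA_integer_)
  data.frame(gene_id = genes, stage = stage, mode = as.integer(mode),
             broad_group = broadGroup(mode), membership = topU,
             stringsAsFactors = FALSE)
}

#' Assign selectivity modes at every stage
#'
#' Runs [assignModes()] stage by stage and returns the per-stage tables
#' plus a genes x stages mode matrix.
#'
#' @inheritParams assignModes
#' @param stages Stage labels to assign (default: all columns of the
#'   transcriptome layer).
#' @return List with `table` (row-bound per-stage assignments) and
#'   `modeMatrix` (genes x stages integer matrix, `NA` = unassigned).
#' @export
assignModesAllStages <- function(layers, stages = NULL, c = 6L, m = 1.25,
                                 threshold = 0.5, seed = 1L,
                                 initAtTemplates = TRUE) {
  if (is.null(stages))
    stages <- colnames(layerValues(layers$transcriptome))
  tabs <- lapply(stages, function(st)
    assignModes(layers, st, c = c, m = m, threshold = threshold,
                seed = seed, initAtTemplates = initAtTemplates))
  tab <- do.call(rbind, tabs)
  genes <- tabs[[1L]]$gene_id
  modeMatrix <- vapply(tabs, function(t) t$mode, integer(length(genes)))
  dimnames(modeMatrix) <- list(genes, stages)
  list(table = tab, modeMatrix = modeMatrix)
}

#' Gene flows between consecutive stages
#'
#' Counts, for every consecutive stage pair, how many genes move from each
#' broad translational group to each other group. Only genes assigned at
#' both stages of a pair enter the flow counts; genes unassigned at either
#' stage are tallied separately in the `excluded` column.
#'
#' @param modeMatrix Genes x stages integer matrix of mode labels (`NA` =
#'   unassigned), as from [assignModesAllStages()] or a simulation truth.
#' @return `data.frame` with columns `from_stage`, `to_stage`,
#'   `from_group`, `to_group`, `n`, plus an attribute `excluded` giving the
#'   per-pair count of genes dropped for missing assignments.
#' @export
flowBetweenStages <- function(modeMatrix) {
  stages <- colnames(modeMatrix)
  if (length(stages) < 2L) stop("flows need at least 2 assigned stages")
  groups <- c("monosome_specific", "actively_translated", "untranslated")
  rows <- list()
  excluded <- integer(0)
  for (i in seq_len(length(stages) - 1L)) {
    a <- modeMatrix[, i]; b <- modeMatrix[, i + 1L]
    ok <- !is.na(a) & !is.na(b)
    excluded[paste(stages[i], stages[i + 1L], sep = " -> ")] <- sum(!ok)
    ga <- factor(broadGroup(a[ok]), levels = groups)
    gb <- factor(broadGroup(b[ok]), levels = groups)
    tab <- table(from_group = ga, to_group = gb)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df$from_stage <- stages[i]
    df$to_stage <- stages[i + 1L]
    rows[[i]] <- df[, c("from_stage", "to_stage", "from_group",
                        "to_group", "Freq")]
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "Freq"] <- "n"
  attr(out, "excluded") <- excluded
  out
}

#' Overlap matrix between monosome and polysome cluster cores
#'
#' Cell (i, j) counts the genes shared by monosome core i and polysome
#' core j, with a one-sided hypergeometric upper-tail enrichment p-value
#' given the core sizes and the gene universe (an extension over raw
#' counts, which are not comparable across unequal core sizes).
#'
#' @param monoCores,polyCores [ClusterCores-class] objects over the same
#'   gene universe.
#' @param universeSize Size of the shared gene universe.
#' @return List with integer matrix `counts` and numeric matrix `p` (both
#'   monosome cores x polysome cores), plus `monoPeak`/`polyPeak` stage
#'   indices.
#' @export
overlapMatrix <- function(monoCores, polyCores, universeSize) {
  stopifnot(methods::is(monoCores, "ClusterCores"),
            methods::is(polyCores, "ClusterCores"))
  a <- coreSets(monoCores); b <- coreSets(polyCores)
  if (universeSize < max(c(0L, lengths(a), lengths(b))))
    stop("universe smaller than a core set")
  counts <- matrix(0L, length(a), length(b),
                   dimnames = list(names(a), names(b)))
  p <- matrix(1, length(a), length(b), dimnames = dimnames(counts))
  for (i in seq_along(a)) for (j in seq_along(b)) {
    k <- length(intersect(a[[i]], b[[j]]))
    counts[i, j] <- k
    p[i, j] <- stats::phyper(k - 1L, length(a[[i]]),
                             universeSize - length(a[[i]]),
                             length(b[[j]]), lower.tail = FALSE)
  }
  list(counts = counts, p = p, monoPeak = peakStages(monoCores),
       polyPeak = peakStages(polyCores))
}

#' Call delayed translational activation lags
#'
#' Classifies genes by the offset between their monosome and polysome
#' occupancy peaks: lag0 (same stage), lag1 (polysome one stage later),
#' lag2 (two stages later); any other pattern, including polysome peaks
#' preceding monosome peaks, is `none` (the signed offset is kept in
#' `signed_lag`). A gene's peak in each layer is the peak stage of the
#' temporal cluster(s) it belongs to: memberships of clusters whose centers
#' peak at the same stage are pooled before applying the core threshold,
#' so that several near-duplicate clusters describing one peak do not
#' dilute each other. Genes below threshold in either layer are `none`
#' with missing peaks. When a gene reaches the threshold at several peak
#' stages of one layer, the earliest peak is taken.
#'
#' @param monoModel,polyModel [FuzzyModel-class] objects fitted to the
#'   standardized monosome and polysome time courses (stage columns in
#'   axis order).
#' @param threshold Pooled-membership cutoff.
#' @return `data.frame` with columns `gene_id`, `mono_peak`, `poly_peak`
#'   (stage indices, `NA` when unassigned), `signed_lag` and `lag_class`.
#' @export
callLags <- function(monoModel, polyModel, threshold = 0.5) {
  peakOf <- function(model) {
    u <- memberships(model)
    centerPeak <- apply(clusterCenters(model), 1L, which.max)
    stagePeaks <- sort(unique(centerPeak))
    pooled <- vapply(stagePeaks, function(s)
      rowSums(u[, centerPeak == s, drop = FALSE]), numeric(nrow(u)))
    dimnames(pooled) <- list(rownames(u), stagePeaks)
    peak <- rep(NA_integer_, nrow(u))
    hit <- pooled >= threshold
    has <- rowSums(hit) > 0L
    peak[has] <- stagePeaks[apply(hit[has, , drop = FALSE], 1L,
                                  which.max)]
    stats::setNames(peak, rownames(u))
  }
  monoPeak <- peakOf(monoModel)
  polyPeak <- peakOf(polyModel)
  genes <- union(names(monoPeak), names(polyPeak))
  mp <- monoPeak[genes]; pp <- polyPeak[genes]
  lag <- unname(pp - mp)
  cls <- rep("none", length(genes))
  cls[!is.na(lag) & lag == 0L] <- "lag0"
  cls[!is.na(lag) & lag == 1L] <- "lag1"
  cls[!is.na(lag) & lag == 2L] <- "lag2"
  data.frame(gene_id = genes, mono_peak = unname(mp),
             poly_peak = unname(pp), signed_lag = lag, lag_class = cls,
             stringsAsFactors = FALSE)
}
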