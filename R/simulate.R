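#' Simulation configuration
#'
#' Bundles every parameter of the synthetic gradient-fraction generator.
#' The defaults emulate the design of a mouse pre-implantation polysome
#' profiling study: 8 developmental stages, ten gradient fractions plus a
#' whole-transcriptome library per stage, three biological replicates, and
#' roughly two million reads per fraction library. Counts are negative
#' binomial with a shared dispersion; planted translational states (six
#' selectivity modes, delayed-activation lag classes) provide ground truth
#' for every downstream analysis.
#'
#' @param nGenes Number of genes (default 1200).
#' @param stages Ordered stage axis, see [stageAxis()].
#' @param nReplicates Biological replicates per stage and compartment.
#' @param librarySize Expected reads per fraction library.
#' @param dispersion Negative-binomial dispersion phi (> 0); the variance of
#'   a count with mean mu is mu + phi * mu^2.
#' @param modeProportions Six non-negative weights (summing to 1) over the
#'   selectivity modes planted for static genes.
#' @param lagProportions Named non-negative weights (summing to 1) over
#'   `lag0`, `lag1`, `lag2`, `none`; genes drawn `none` are static
#'   mode genes, the rest are dynamic genes with planted monosome/polysome
#'   peak stages.
#' @param proteinLag Stages by which planted protein abundance trails the
#'   polysome signal (default 2).
#' @param polyALag Stages by which planted poly(A) tail length leads the
#'   polysome signal (default 1).
#' @param m6aFraction Baseline per-gene-stage probability of an m6A flag;
#'   polysome-assigned genes at zygote/2-Cell get three times this rate
#'   (capped at 0.9).
#' @param levelLog2 Log2 abundances of the low/mid/high planted expression
#'   levels; 3 log2 units apart by default.
#' @param geneSd Gene-level log2 noise around the planted level (constant
#'   across stages within a gene and layer).
#' @param stageSd Additional per-stage log2 jitter.
#' @param seed Integer seed governing all draws.
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nGenes = 1200L,
                             stages = stageAxis(),
                             nReplicates = 3L,
                             librarySize = 2e6,
                             dispersion = 0.05,
                             modeProportions = rep(1 / 6, 6),
                             lagProportions = c(lag0 = 0.12, lag1 = 0.12,
                                                lag2 = 0.12, none = 0.64),
                             proteinLag = 2L,
                             polyALag = 1L,
                             m6aFraction = 0.2,
                             levelLog2 = c(low = 3, mid = 6, high = 9),
                             geneSd = 0.4,
                             stageSd = 0.2,
                             seed = 1L) {
  stopifnot(nGenes >= 1, nReplicates >= 1, librarySize > 0,
            dispersion > 0, proteinLag >= 0, polyALag >= 0,
            m6aFraction >= 0, m6aFraction <= 1,
            geneSd >= 0, stageSd >= 0)
  stages <- stageAxis(stages)
  if (length(modeProportions) != 6L || any(modeProportions < 0) ||
      abs(sum(modeProportions) - 1) > 1e-9)
    stop("'modeProportions' must be 6 non-negative weights summing to 1")
  lagNames <- c("lag0", "lag1", "lag2", "none")
  if (!all(lagNames %in% names(lagProportions)))
    stop("'lagProportions' must be named over: ",
         paste(lagNames, collapse = ", "))
  lagProportions <- lagProportions[lagNames]
  if (any(lagProportions < 0) || abs(sum(lagProportions) - 1) > 1e-9)
    stop("'lagProportions' must be non-negative and sum to 1")
  if (length(levelLog2) != 3L || any(diff(levelLog2) <= 0))
    stop("'levelLog2' must be three increasing log2 levels")
  cfg <- list(nGenes = as.integer(nGenes), stages = stages,
              nReplicates = as.integer(nReplicates),
              librarySize = librarySize, dispersion = dispersion,
              modeProportions = modeProportions,
              lagProportions = lagProportions,
              proteinLag = as.integer(proteinLag),
              polyALag = as.integer(polyALag),
              m6aFraction = m6aFraction,
              levelLog2 = levelLog2, geneSd = geneSd, stageSd = stageSd,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Canonical selectivity-mode templates
#'
#' The six translational-selectivity modes as level templates over the
#' (transcriptome, monosome, polysome) layers, encoded -1 (low), 0 (mid),
#' +1 (high): mode 1 monosome-specific; mode 2 monosome and polysome;
#' mode 3 selective translation of low-abundant mRNAs; mode 4 of
#' modest-abundant mRNAs; mode 5 active translation of highly expressed
#' mRNAs; mode 6 highly transcribed but untranslated.
#'
#' @return 6 x 3 numeric matrix, rows `Mode1..Mode6`, columns
#'   `transcriptome`, `monosome`, `polysome`.
#' @export
modeTemplates <- function() {
  m <- rbind(Mode1 = c(-1,  1, -1),
             Mode2 = c( 0,  1,  1),
             Mode3 = c(-1, -1,  1),
             Mode4 = c( 0,  0,  1),
             Mode5 = c( 1,  1,  1),
             Mode6 = c( 1, -1, -1))
  colnames(m) <- c("transcriptome", "monosome", "polysome")
  m
}

# Free-layer level per mode: only untranslated, highly transcribed mRNAs
# accumulate in the free layer.
modeFreeLevels <- function() c(-1, -1, -1, -1, -1, 1)

# Map a (transcriptome, monosome, polysome) level triple to the nearest
# canonical mode (squared Euclidean; ties broken toward the lowest mode).
nearestMode <- function(triple) {
  d <- rowSums(sweep(modeTemplates(), 2, triple)^2)
  which.min(d)
}

#' Simulate a fraction-resolved polysome-profiling dataset
#'
#' Draws a complete synthetic dataset with planted ground truth. Genes fall
#' into two planted populations:
#'
#' * static "mode" genes carry one of the six selectivity-mode templates
#'   (see [modeTemplates()]) constantly across stages (unless switched via
#'   `modeSwitches`);
#' * dynamic "lag" genes model delayed translational activation: their
#'   monosome signal peaks at a planted stage and the polysome signal at
#'   the same stage (lag0), one stage later (lag1) or two stages later
#'   (lag2), with mid total expression throughout; their free-layer signal
#'   peaks one stage before monosome loading. Their per-stage planted
#'   mode follows by nearest-template lookup (mode 6 off peak, mode 1 at a
#'   monosome-only peak, mode 3 at a polysome-only peak, mode 2 at a joint
#'   peak).
#'
#' Planted log2 abundances per layer are the template level plus gene- and
#' stage-level Gaussian noise. Fraction-level abundance divides a layer's
#' mass equally over its member fractions; each fraction library is scaled
#' to the configured library size and counts are drawn independently per
#' replicate from a negative binomial with the configured dispersion.
#' Whole-transcriptome ("total") libraries are drawn from the transcriptome
#' trajectory the same way.
#'
#' Companion tables: protein log-intensity follows the polysome trajectory
#' `proteinLag` stages earlier (protein accumulates after translation);
#' poly(A) tail length follows the polysome trajectory `polyALag` stages
#' later (tails lengthen before translational activation); binary m6A flags
#' are drawn with an elevated rate for polysome-assigned genes at the
#' zygote/2-Cell stages. Identical seeds give identical output.
#'
#' @param config A [simulationConfig()].
#' @param modeSwitches Optional `data.frame(n, from, to, atStage)`; for each
#'   row, `n` static genes of base mode `from` switch to mode `to` from
#'   stage `atStage` onward (used to plant stage-flow transitions).
#' @return A list with elements `experiment`
#'   ([FractionExperiment-class]), `companions` (list of `protein`,
#'   `polyA`, `m6A` genes x stages matrices) and `truth` (a `GroundTruth`
#'   list: per-gene table, planted per-stage mode matrix, planted log2
#'   layer trajectories, and the config).
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 60, seed = 7))
#' sim$experiment
#' head(sim$truth$genes)
#' @export
simulateDataset <- function(config = simulationConfig(),
                            modeSwitches = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  S <- length(config$stages)
  if (S < 3L) stop("the generator needs at least 3 stages")
  G <- config$nGenes
  genes <- sprintf("gene%04d", seq_len(G))

  # -- planted per-gene states ------------------------------------------
  lagClass <- sample(names(config$lagProportions), G, replace = TRUE,
                     prob = config$lagProportions)
  baseMode <- ifelse(lagClass == "none",
                     sample.int(6L, G, replace = TRUE,
                                prob = config$modeProportions), NA_integer_)
  monoPeak <- rep(NA_integer_, G)
  polyPeak <- rep(NA_integer_, G)
  for (g in which(lagClass != "none")) {
    lag <- c(lag0 = 0L, lag1 = 1L, lag2 = 2L)[[lagClass[g]]]
    monoPeak[g] <- sample.int(S - lag, 1L)
    polyPeak[g] <- monoPeak[g] + lag
  }

  # -- planted per-stage mode matrix (levels in {-1, 0, 1}) -------------
  lvl <- array(0, dim = c(G, S, 4L),
               dimnames = list(genes, config$stages, layerNames()))
  modeMatrix <- matrix(NA_integer_, G, S, dimnames = list(genes,
                                                          config$stages))
  tmpl <- modeTemplates()
  freeLvl <- modeFreeLevels()
  static <- which(lagClass == "none")
  if (length(static)) {
    stageMode <- matrix(rep(baseMode[static], S), ncol = S)
    if (!is.null(modeSwitches)) {
      stopifnot(all(c("n", "from", "to", "atStage") %in%
                      colnames(modeSwitches)))
      for (i in seq_len(nrow(modeSwitches))) {
        at <- stageIndex(modeSwitches$atStage[i], config$stages)
        cand <- which(baseMode[static] == modeSwitches$from[i])
        if (length(cand) < modeSwitches$n[i])
          stop("not enough base-mode-", modeSwitches$from[i],
               " genes for the requested switch")
        pick <- cand[seq_len(modeSwitches$n[i])]
        stageMode[pick, at:S] <- modeSwitches$to[i]
      }
    }
    modeMatrix[static, ] <- stageMode
    for (s in seq_len(S)) {
      ms <- stageMode[, s]
      lvl[static, s, "transcriptome"] <- tmpl[ms, "transcriptome"]
      lvl[static, s, "monosome"]      <- tmpl[ms, "monosome"]
      lvl[static, s, "polysome"]      <- tmpl[ms, "polysome"]
      lvl[static, s, "free"]          <- freeLvl[ms]
    }
  }
  dynamic <- which(lagClass != "none")
  if (length(dynamic)) {
    lvl[dynamic, , "transcriptome"] <- 0
    lvl[dynamic, , "free"] <- -1
    lvl[dynamic, , "monosome"] <- -1
    lvl[dynamic, , "polysome"] <- -1
    for (g in dynamic) {
      # transcripts surface in the free layer before ribosome loading
      lvl[g, max(1L, monoPeak[g] - 1L), "free"] <- 1
      lvl[g, monoPeak[g], "monosome"] <- 1
      lvl[g, polyPeak[g], "polysome"] <- 1
      for (s in seq_len(S))
        modeMatrix[g, s] <- nearestMode(lvl[g, s,
                                            c("transcriptome", "monosome",
                                              "polysome")])
    }
  }

  # -- planted log2 trajectories ----------------------------------------
  mid <- config$levelLog2[["mid"]]
  half <- (config$levelLog2[["high"]] - config$levelLog2[["low"]]) / 2
  traj <- list()
  for (ly in layerNames()) {
    geneOffset <- stats::rnorm(G, 0, config$geneSd)
    jitter <- matrix(stats::rnorm(G * S, 0, config$stageSd), G, S)
    traj[[ly]] <- mid + half * lvl[, , ly] + geneOffset + jitter
    dimnames(traj[[ly]]) <- list(genes, config$stages)
  }

  # -- counts ------------------------------------------------------------
  lf <- layerFractions()
  nComp <- length(compartmentLabels())
  nSamples <- S * nComp * config$nReplicates
  counts <- matrix(0, G, nSamples)
  sampleId <- character(nSamples)
  stageCol <- character(nSamples)
  compCol <- character(nSamples)
  repCol <- integer(nSamples)
  j <- 0L
  for (s in seq_len(S)) {
    abund <- lapply(traj, function(m) 2^m[, s])
    for (comp in compartmentLabels()) {
      ly <- if (comp == "total") "transcriptome" else
        layerNames()[vapply(lf, function(f) comp %in% f, TRUE)][1L]
      a <- abund[[ly]] / length(lf[[ly]])
      mu <- config$librarySize * a / sum(a)
      for (r in seq_len(config$nReplicates)) {
        j <- j + 1L
        counts[, j] <- stats::rnbinom(G, mu = mu,
                                      size = 1 / config$dispersion)
        sampleId[j] <- paste(config$stages[s], comp, r, sep = "_")
        stageCol[j] <- config$stages[s]
        compCol[j] <- comp
        repCol[j] <- r
      }
    }
  }
  dimnames(counts) <- list(genes, sampleId)
  fe <- FractionExperiment(counts,
                           data.frame(sample_id = sampleId,
                                      stage = stageCol,
                                      compartment = compCol,
                                      replicate = repCol),
                           stages = config$stages)

  # -- companion modalities ---------------------------------------------
  polyT <- traj$polysome
  protein <- matrix(NA_real_, G, S, dimnames = list(genes, config$stages))
  polyA <- matrix(NA_real_, G, S, dimnames = list(genes, config$stages))
  for (s in seq_len(S)) {
    protein[, s] <- polyT[, max(1L, s - config$proteinLag)] +
      stats::rnorm(G, 0, 0.5)
    polyA[, s] <- pmax(10, 10 + 7 * polyT[, min(S, s + config$polyALag)] +
                         stats::rnorm(G, 0, 4))
  }
  m6aProb <- matrix(config$m6aFraction, G, S)
  egaStages <- intersect(c("zygote", "2-Cell"), config$stages)
  polyModes <- c(2L, 3L, 4L, 5L)
  for (st in egaStages) {
    s <- stageIndex(st, config$stages)
    hit <- modeMatrix[, s] %in% polyModes
    m6aProb[hit, s] <- min(0.9, 3 * config$m6aFraction)
  }
  m6A <- matrix(stats::rbinom(G * S, 1L, as.vector(m6aProb)), G, S,
                dimnames = list(genes, config$stages))

  truth <- list(genes = data.frame(gene_id = genes, lagClass = lagClass,
                                   baseMode = baseMode, monoPeak = monoPeak,
                                   polyPeak = polyPeak,
                                   stringsAsFactors = FALSE),
                modeMatrix = modeMatrix, trajectories = traj,
                config = config)
  class(truth) <- "GroundTruth"
  list(experiment = fe,
       companions = list(protein = protein, polyA = polyA, m6A = m6A),
       truth = truth)
}

#' Planted fraction-allocation vectors
#'
#' Recomputes, from a `GroundTruth`'s planted trajectories, the allocation
#' vector pi over the ten gradient fractions for every gene at one stage
#' (each row sums to 1): the free/monosome/polysome layer masses divided
#' equally over their member fractions.
#'
#' @param truth `GroundTruth` from [simulateDataset()].
#' @param stage Stage label.
#' @return Numeric genes x 10 matrix of allocation fractions.
#' @export
plantedAllocation <- function(truth, stage) {
  stopifnot(inherits(truth, "GroundTruth"))
  s <- stageIndex(stage, truth$config$stages)
  lf <- layerFractions()
  mass <- cbind(2^truth$trajectories$free[, s],
                2^truth$trajectories$monosome[, s],
                2^truth$trajectories$polysome[, s])
  alloc <- cbind(mass[, 1] / 2, mass[, 1] / 2,
                 mass[, 2] / 3, mass[, 2] / 3, mass[, 2] / 3,
                 mass[, 3] / 5, mass[, 3] / 5, mass[, 3] / 5,
                 mass[, 3] / 5, mass[, 3] / 5)
  colnames(alloc) <- fractionLabels()
  rownames(alloc) <- rownames(truth$trajectories$free)
  alloc / rowSums(alloc)
}

#' Oracle recovery of planted lag classes
#'
#' Reads the planted peak stages directly off a `GroundTruth` and
#' reclassifies every gene (same-stage peaks: lag0; polysome one/two stages
#' after monosome: lag1/lag2; anything else, including static genes without
#' planted peaks: none). By construction this must reproduce the planted
#' lag classes exactly; it is the generator's internal consistency check.
#'
#' @param truth `GroundTruth` from [simulateDataset()].
#' @return Character vector of lag classes, named by gene.
#' @export
truthLagOracle <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  d <- truth$genes$polyPeak - truth$genes$monoPeak
  cls <- rep("none", nrow(truth$genes))
  cls[!is.na(d) & d == 0L] <- "lag0"
  cls[!is.na(d) & d == 1L] <- "lag1"
  cls[!is.na(d) & d == 2L] <- "lag2"
  names(cls) <- truth$genes$gene_id
  cls
}

#' Simulate a null (or spiked) polysome-versus-monosome pair
#'
#' Generates a single-stage ten-fraction dataset in which every null gene
#' allocates equal mass to the monosome group (F3-F5) and the polysome
#' group (F6-F10), so the true group-level log2 fold change is 0 for all of
#' them. Optionally the first `nEffect` genes are spiked with a group-level
#' fold change of `effectLog2FC`, half up and half down so that library
#' depths stay balanced and the planted effects are not distorted by
#' depth normalization. Used to estimate the type-I error and power of
#' [polyVsMonoTest()].
#'
#' @param config A [simulationConfig()] (library size, dispersion,
#'   replicates and seed are used).
#' @param nGenes Number of genes.
#' @param effectLog2FC Absolute planted log2 fold change of spiked genes.
#' @param nEffect Number of spiked genes (0 for a pure null).
#' @return A [FractionExperiment-class] for one stage with an attribute
#'   `trueLog2FC` giving each gene's planted group-level log2 fold change.
#' @export
simulateNullPair <- function(config = simulationConfig(), nGenes = 5000L,
                             effectLog2FC = 0, nEffect = 0L) {
  stopifnot(inherits(config, "SimulationConfig"), nGenes >= 1,
            nEffect >= 0, nEffect <= nGenes)
  set.seed(config$seed + 1000003L)
  genes <- sprintf("gene%05d", seq_len(nGenes))
  stage <- config$stages[1L]
  A <- 2^(config$levelLog2[["mid"]] + stats::rnorm(nGenes, 0, 1))
  delta <- rep(0, nGenes)
  if (nEffect > 0) {
    nUp <- ceiling(nEffect / 2)
    delta[seq_len(nUp)] <- effectLog2FC
    if (nEffect > nUp)
      delta[(nUp + 1):nEffect] <- -effectLog2FC
  }
  r <- 2^delta
  wMono <- 0.9 / (1 + r)
  wPoly <- 0.9 * r / (1 + r)
  massPerFraction <- cbind(A * 0.1 / 2, A * 0.1 / 2,
                           A * wMono / 3, A * wMono / 3, A * wMono / 3,
                           A * wPoly / 5, A * wPoly / 5, A * wPoly / 5,
                           A * wPoly / 5, A * wPoly / 5)
  nSamples <- 10L * config$nReplicates
  counts <- matrix(0, nGenes, nSamples)
  sampleId <- character(nSamples)
  compCol <- character(nSamples)
  repCol <- integer(nSamples)
  j <- 0L
  for (f in seq_len(10L)) {
    mu <- config$librarySize * massPerFraction[, f] /
      sum(massPerFraction[, f])
    for (rp in seq_len(config$nReplicates)) {
      j <- j + 1L
      counts[, j] <- stats::rnbinom(nGenes, mu = mu,
                                    size = 1 / config$dispersion)
      sampleId[j] <- paste(stage, fractionLabels()[f], rp, sep = "_")
      compCol[j] <- fractionLabels()[f]
      repCol[j] <- rp
    }
  }
  dimnames(counts) <- list(genes, sampleId)
  fe <- FractionExperiment(counts,
                           data.frame(sample_id = sampleId, stage = stage,
                                      compartment = compCol,
                                      replicate = repCol),
                           stages = config$stages)
  attr(fe, "trueLog2FC") <- stats::setNames(delta, genes)
  fe
}
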