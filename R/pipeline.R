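#' Pipeline run configuration
#'
#' Collects every parameter of the end-to-end analysis with its default.
#' The configuration is serialized (YAML) next to the outputs so a run can
#' be reproduced from its artifact directory alone. A single global seed
#' is expanded into fixed per-module substreams, so each module is
#' reproducible independently of execution order.
#'
#' @param outDir Output directory (created if needed).
#' @param simulate Generate a synthetic dataset (default); `FALSE` requires
#'   `countsPath` and `sheetPath`.
#' @param countsPath,sheetPath Input TSVs when `simulate = FALSE`.
#' @param simulation A [simulationConfig()] used when simulating.
#' @param stages Stage axis for file inputs.
#' @param cModes Clusters for per-stage mode decomposition (6).
#' @param cTemporal Clusters for per-layer temporal clustering (12).
#' @param m Fuzzifier.
#' @param coreThreshold Membership cutoff for cores and mode assignment.
#' @param sdFilter Flat-profile filter: genes whose across-stage log2 sd in
#'   a layer falls below this are left out of that layer's temporal
#'   clustering.
#' @param minCpm Detection threshold for the occupancy test.
#' @param alpha,lfcThreshold,useFdr Calling thresholds, see
#'   [polyVsMonoTest()].
#' @param seed Global integer seed.
#' @return List of class `"RunConfig"`.
#' @export
runConfig <- function(outDir, simulate = TRUE, countsPath = NULL,
                      sheetPath = NULL,
                      simulation = simulationConfig(seed = seed),
                      stages = stageAxis(), cModes = 6L, cTemporal = 12L,
                      m = 1.25, coreThreshold = 0.5, sdFilter = 1.0,
                      minCpm = 1, alpha = 0.05, lfcThreshold = 1,
                      useFdr = TRUE, seed = 1L) {
  if (missing(outDir)) stop("'outDir' is required")
  if (!simulate && (is.null(countsPath) || is.null(sheetPath)))
    stop("without 'simulate', both 'countsPath' and 'sheetPath' are required")
  if (!simulate)
    for (p in c(countsPath, sheetPath))
      if (!file.exists(p)) stop("input file not found: ", p)
  cfg <- list(outDir = outDir, simulate = simulate,
              countsPath = countsPath, sheetPath = sheetPath,
              simulation = simulation, stages = stageAxis(stages),
              cModes = as.integer(cModes),
              cTemporal = as.integer(cTemporal), m = m,
              coreThreshold = coreThreshold, sdFilter = sdFilter,
              minCpm = minCpm, alpha = alpha,
              lfcThreshold = lfcThreshold, useFdr = useFdr,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

serializeConfig <- function(cfg, path) {
  flat <- cfg
  flat$stages <- as.character(flat$stages)
  flat$simulation <- lapply(unclass(flat$simulation), function(v)
    if (inherits(v, "StageAxis")) as.character(v) else v)
  yaml::write_yaml(unclass(flat), path)
}

#' Run the full fraction-resolved translational-fate analysis
#'
#' Orchestrates the pipeline: simulate (or read) fraction counts; build
#' the four layers; per-layer temporal fuzzy clustering with cores;
#' per-stage mode assignment and broad-group flows; monosome/polysome core
#' overlap matrix; delayed-activation lag calls; per-stage
#' polysome-versus-monosome tests and transition switch genes; and, when
#' companions exist, lagged cross-omics correlations and m6A layer
#' percentages. All outputs are TSV files in `config$outDir`; a
#' `manifest.tsv` lists every file with its MD5 hash, so identical
#' config + seed gives identical manifests. Any failing step aborts with
#' the step named and leaves a `FAILED` marker file.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with the main in-memory results (`layers`,
#'   `modes`, `flows`, `lags`, `enrichment`, `overlap`, `integration`,
#'   `recovery`, `manifestPath`).
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(x, name) {
    path <- file.path(config$outDir, name)
    writeTsv(x, path)
    outputs <<- c(outputs, path)
    path
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("failed at step:", name, "-", conditionMessage(e)),
                 file.path(config$outDir, "FAILED"))
      stop("pipeline step '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cfgPath <- file.path(config$outDir, "config.yaml")
  serializeConfig(config, cfgPath)
  outputs <- c(outputs, cfgPath)

  # -- input -------------------------------------------------------------
  truth <- NULL; companions <- NULL
  fe <- step("input", {
    if (config$simulate) {
      sim <- simulateDataset(config$simulation)
      truth <- sim$truth; companions <- sim$companions
      writeFractionExperiment(sim$experiment,
                              file.path(config$outDir, "counts.tsv"),
                              file.path(config$outDir, "sample_sheet.tsv"))
      outputs <- c(outputs, file.path(config$outDir, "counts.tsv"),
                   file.path(config$outDir, "sample_sheet.tsv"))
      for (mod in names(companions))
        emit(companions[[mod]], paste0("companion_", mod, ".tsv"))
      emit(truth$modeMatrix, "truth_modes.tsv")
      truthTab <- truth$genes
      rownames(truthTab) <- truthTab$gene_id
      emit(as.matrix(truthTab[, -1L]), "truth_genes.tsv")
      sim$experiment
    } else {
      readFractionCounts(config$countsPath, config$sheetPath,
                         stages = config$stages)
    }
  })
  axis <- stageLabels(fe)

  # -- layers ------------------------------------------------------------
  layers <- step("layers", aggregateLayers(fe))
  for (ly in names(layers))
    emit(layers[[ly]], paste0("layer_", ly, ".tsv"))

  # -- temporal clustering + cores --------------------------------------
  temporal <- step("temporal_clustering", {
    lapply(stats::setNames(nm = c("free", "monosome", "polysome")),
           function(ly) {
      vals <- layerValues(layers[[ly]])
      keep <- apply(vals, 1L, stats::sd) >= config$sdFilter
      if (sum(keep) < config$cTemporal)
        stop("fewer than ", config$cTemporal,
             " variable genes in the ", ly, " layer")
      z <- standardizeProfiles(vals[keep, , drop = FALSE])
      model <- fuzzyCMeans(z, c = config$cTemporal, m = config$m,
                           seed = config$seed + 101L)
      cores <- extractCores(model, config$coreThreshold)
      emit(clusterCenters(model), paste0("temporal_centers_", ly, ".tsv"))
      emit(memberships(model), paste0("temporal_memberships_", ly,
                                      ".tsv"))
      list(model = model, cores = cores)
    })
  })

  # -- modes + flows -----------------------------------------------------
  modes <- step("modes", assignModesAllStages(
    layers, c = config$cModes, m = config$m,
    threshold = config$coreThreshold, seed = config$seed + 202L))
  emit(modes$modeMatrix, "mode_matrix.tsv")
  flows <- step("flows", flowBetweenStages(modes$modeMatrix))
  flowTab <- flows
  rownames(flowTab) <- sprintf("flow%03d", seq_len(nrow(flowTab)))
  emit(as.matrix(flowTab), "flows.tsv")

  # -- overlap matrix ----------------------------------------------------
  overlap <- step("overlap", overlapMatrix(
    temporal$monosome$cores, temporal$polysome$cores, nrow(fe)))
  emit(overlap$counts, "overlap_counts.tsv")
  emit(overlap$p, "overlap_p.tsv")

  # -- delayed activation lags ------------------------------------------
  lags <- step("lags", callLags(temporal$monosome$model,
                                temporal$polysome$model,
                                threshold = config$coreThreshold))
  lagTab <- lags
  rownames(lagTab) <- lagTab$gene_id
  emit(as.matrix(lagTab[, -1L]), "lag_calls.tsv")

  # -- occupancy tests + switches ---------------------------------------
  enrich <- step("enrichment", {
    res <- lapply(axis, function(st)
      polyVsMonoTest(fe, st, minCpm = config$minCpm, alpha = config$alpha,
                     lfcThreshold = config$lfcThreshold,
                     useFdr = config$useFdr))
    names(res) <- axis
    res
  })
  enrichTab <- do.call(rbind, enrich)
  rownames(enrichTab) <- sprintf("t%05d", seq_len(nrow(enrichTab)))
  emit(as.matrix(enrichTab), "poly_vs_mono.tsv")
  switches <- step("switches", {
    out <- lapply(seq_len(length(axis) - 1L), function(i)
      switchGenes(enrich, axis[i], axis[i + 1L]))
    names(out) <- paste(axis[-length(axis)], axis[-1L], sep = " -> ")
    out
  })
  swTab <- data.frame(transition = rep(names(switches),
                                       lengths(switches)),
                      gene_id = unlist(switches, use.names = FALSE),
                      stringsAsFactors = FALSE)
  if (nrow(swTab)) {
    rownames(swTab) <- sprintf("s%05d", seq_len(nrow(swTab)))
    emit(as.matrix(swTab), "switch_genes.tsv")
  }

  # -- cross-omics integration ------------------------------------------
  integration <- NULL
  if (!is.null(companions)) {
    integration <- step("integration", {
      prot <- laggedCorrelation(layers$polysome, companions$protein)
      pa <- laggedCorrelation(layers$polysome, companions$polyA)
      stageSets <- lapply(temporal, function(t) {
        sets <- lapply(seq_along(axis), function(s)
          unlist(coreSets(t$cores)[peakStages(t$cores) == s],
                 use.names = FALSE))
        stats::setNames(sets, axis)
      })
      m6aSets <- lapply(stats::setNames(nm = colnames(companions$m6A)),
                        function(st)
                          rownames(companions$m6A)[
                            companions$m6A[, st] == 1])
      list(protein = list(matrix = prot, lag = bestLag(prot)),
           polyA = list(matrix = pa, lag = bestLag(pa)),
           m6aPercent = m6aLayerPercentage(stageSets, m6aSets))
    })
    emit(integration$protein$matrix$r, "lagcorr_protein.tsv")
    emit(integration$polyA$matrix$r, "lagcorr_polyA.tsv")
    emit(integration$m6aPercent, "m6a_percent.tsv")
  }

  # -- recovery report (simulated runs only) ----------------------------
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- step("recovery", {
      list(modeRecovery = modeRecovery(modes$modeMatrix,
                                       truth$modeMatrix),
           lagRecovery = lagRecovery(lags, truth))
    })
    rep <- rbind(mode_recovery_percent = recovery$modeRecovery$percent,
                 assigned_gene_stages = recovery$modeRecovery$nAssigned,
                 lag1_recovery_percent =
                   recovery$lagRecovery$percent["lag1"],
                 planted_lag1_genes = recovery$lagRecovery$n["lag1"])
    colnames(rep) <- "value"
    emit(rep, "recovery_report.tsv")
  }

  manifestPath <- file.path(config$outDir, "manifest.tsv")
  hashes <- tools::md5sum(outputs)
  manifest <- data.frame(file = basename(outputs), md5 = unname(hashes),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(experiment = fe, layers = layers, temporal = temporal,
                 modes = modes, flows = flows, overlap = overlap,
                 lags = lags, enrichment = enrich, switches = switches,
                 integration = integration, recovery = recovery,
                 truth = truth, manifestPath = manifestPath))
}

#' Recovery of planted modes and lags
#'
#' Helpers comparing pipeline output against a simulation's ground truth:
#' `modeRecovery` is the percentage of assigned gene-stage pairs whose
#' called mode equals the planted mode; `lagRecovery` is, per planted lag
#' class, the percentage of its genes whose called class matches.
#'
#' @param modeMatrix Called genes x stages mode matrix (`NA` unassigned).
#' @param truthModes Planted genes x stages mode matrix.
#' @return For `modeRecovery`: list with `percent` and `nAssigned`.
#' @export
modeRecovery <- function(modeMatrix, truthModes) {
  genes <- intersect(rownames(modeMatrix), rownames(truthModes))
  stages <- intersect(colnames(modeMatrix), colnames(truthModes))
  called <- modeMatrix[genes, stages]
  planted <- truthModes[genes, stages]
  ok <- !is.na(called) & !is.na(planted)
  list(percent = 100 * mean(called[ok] == planted[ok]),
       nAssigned = sum(ok))
}

#' @rdname modeRecovery
#' @param lagCalls `data.frame` from [callLags()].
#' @param truth `GroundTruth` from [simulateDataset()].
#' @return For `lagRecovery`: list with per-class `percent` and `n`.
#' @export
lagRecovery <- function(lagCalls, truth) {
  planted <- stats::setNames(truth$genes$lagClass, truth$genes$gene_id)
  called <- stats::setNames(lagCalls$lag_class, lagCalls$gene_id)
  classes <- c("lag0", "lag1", "lag2")
  pct <- n <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    ids <- names(planted)[planted == cl]
    n[cl] <- length(ids)
    hit <- called[ids]
    hit[is.na(hit)] <- "none"
    pct[cl] <- 100 * mean(hit == cl)
  }
  list(percent = pct, n = n)
}
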