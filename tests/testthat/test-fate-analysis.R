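test_that("broad groups are the deterministic image of modes", {
  expect_identical(broadGroup(c(1:6, NA)),
                   c("monosome_specific", rep("actively_translated", 4),
                     "untranslated", "unassigned"))
})

test_that("per-stage mode assignment recovers planted modes", {
  sim <- defaultSim()
  layers <- defaultLayers()
  one <- assignModes(layers, "2-Cell", seed = 2L)
  expect_identical(one$broad_group[!is.na(one$mode) & one$mode == 2L][1],
                   "actively_translated")
  truth <- sim$truth$modeMatrix[, "2-Cell"]
  ok <- !is.na(one$mode)
  expect_gt(mean(one$mode[ok] == truth[one$gene_id[ok]]), 0.9)
  # low-membership genes are unassigned
  expect_true(all(one$membership[is.na(one$mode)] < 0.5))
})

test_that("stage flows count transitions and conserve group sizes", {
  # all genes keep their group: diagonal flow table
  mm <- cbind(GV = c(1L, 3L, 6L), MII = c(1L, 3L, 6L))
  rownames(mm) <- paste0("g", 1:3)
  fl <- flowBetweenStages(mm)
  offDiag <- fl$n[fl$from_group != fl$to_group]
  expect_true(all(offDiag == 0L))
  expect_identical(sum(fl$n), 3L)

  # planted 10-gene monosome_specific -> actively_translated transition
  cfg <- simulationConfig(nGenes = 200L, seed = 13L,
                          lagProportions = c(lag0 = 0, lag1 = 0,
                                             lag2 = 0, none = 1))
  sw <- data.frame(n = 10L, from = 1L, to = 3L, atStage = "2-Cell")
  sim <- simulateDataset(cfg, modeSwitches = sw)
  fl2 <- flowBetweenStages(sim$truth$modeMatrix)
  cell <- fl2$n[fl2$from_stage == "zygote" & fl2$to_stage == "2-Cell" &
                  fl2$from_group == "monosome_specific" &
                  fl2$to_group == "actively_translated"]
  expect_identical(cell, 10L)

  # row sums equal group sizes among doubly assigned genes
  sums <- tapply(fl2$n, fl2[, c("from_stage", "from_group")], sum)
  zg <- broadGroup(sim$truth$modeMatrix[, "zygote"])
  expect_identical(unname(sums["zygote", "monosome_specific"]),
                   sum(zg == "monosome_specific"))
})

test_that("unassigned genes are excluded from flows and reported", {
  mm <- cbind(GV = c(1L, NA, 6L), MII = c(1L, 2L, NA))
  rownames(mm) <- paste0("g", 1:3)
  fl <- flowBetweenStages(mm)
  expect_identical(sum(fl$n), 1L)
  expect_identical(unname(attr(fl, "excluded")), 2L)
})

test_that("overlap matrices match exact hypergeometric enumeration", {
  mkCores <- function(sets, peaks) methods::new(
    "ClusterCores", threshold = 0.6, coreSets = sets,
    peakStage = as.integer(peaks),
    unassigned = character())
  a <- mkCores(list(c1 = paste0("g", 1:5)), 1)
  b <- mkCores(list(c1 = paste0("g", 1:5)), 2)
  om <- overlapMatrix(a, b, 20L)
  expect_identical(om$counts[1, 1], 5L)
  expect_equal(om$p[1, 1], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(om$p[1, 1], 1 / 15504, tolerance = 1e-9)

  disj <- mkCores(list(c1 = paste0("h", 1:4)), 3)
  om2 <- overlapMatrix(a, disj, 20L)
  expect_identical(om2$counts[1, 1], 0L)
  expect_equal(om2$p[1, 1], 1)

  uni <- mkCores(list(c1 = paste0("g", 1:10)), 1)
  om3 <- overlapMatrix(uni, uni, 10L)
  expect_identical(om3$counts[1, 1], 10L)
  expect_equal(om3$p[1, 1], 1)
  expect_error(overlapMatrix(uni, uni, 5L), "universe")

  # random cores against the enumeration oracle
  set.seed(3)
  for (i in 1:20) {
    N <- sample(5:25, 1)
    na <- sample(N, 1); nb <- sample(N, 1)
    A <- sample(paste0("g", 1:N), na)
    B <- sample(paste0("g", 1:N), nb)
    om <- overlapMatrix(mkCores(list(c1 = A), 1),
                        mkCores(list(c1 = B), 1), N)
    expect_equal(om$p[1, 1],
                 hyperOracle(om$counts[1, 1], na, nb, N),
                 tolerance = 1e-12)
  }
})

test_that("lag calls classify peak offsets, including reversed peaks", {
  genes <- paste0("g", 1:5)
  # stages: 3 = zygote, 4 = 2-Cell on the default axis
  mono <- crispModel(genes, c(1L, 1L, 1L, 2L, 2L),
                     centerPeaks = c(3L, 4L))
  poly <- crispModel(genes, c(1L, 2L, 3L, 3L, 1L),
                     centerPeaks = c(4L, 5L, 3L))
  lc <- callLags(mono, poly)
  lc <- lc[order(lc$gene_id), ]
  expect_identical(lc$lag_class, c("lag1", "lag2", "lag0", "none",
                                   "lag0"))
  # polysome peak before monosome peak: none, signed lag kept
  expect_identical(lc$signed_lag[4], -1L)
  expect_identical(lc$mono_peak[1], 3L)
  expect_identical(lc$poly_peak[1], 4L)
})

test_that("pooling memberships by peak stage rescues split clusters", {
  genes <- paste0("g", 1:2)
  # two near-duplicate monosome clusters peaking at the same stage share
  # the membership of g1: neither reaches 0.5 alone, their pool does
  u <- rbind(g1 = c(0.48, 0.48, 0.04), g2 = c(0.02, 0.03, 0.95))
  colnames(u) <- paste0("cluster", 1:3)
  centers <- matrix(-1, 3, 8)
  centers[1, 2] <- 1; centers[2, 2] <- 1; centers[3, 5] <- 1
  dimnames(centers) <- list(paste0("cluster", 1:3), paste0("s", 1:8))
  mono <- methods::new("FuzzyModel", centers = centers, memberships = u,
                       m = 1.25, objective = c(1), seed = 1L, nIter = 1L,
                       converged = TRUE)
  poly <- crispModel(genes, c(1L, 2L), centerPeaks = c(3L, 6L))
  lc <- callLags(mono, poly)
  lc <- lc[order(lc$gene_id), ]
  expect_identical(lc$mono_peak, c(2L, 5L))
  expect_identical(lc$lag_class, c("lag1", "lag1"))
})

test_that("planted lag classes are recovered end to end", {
  sim <- defaultSim()
  layers <- defaultLayers()
  fit <- function(ly) {
    vals <- layerValues(layers[[ly]])
    keep <- apply(vals, 1, sd) >= 1
    fuzzyCMeans(standardizeProfiles(vals[keep, , drop = FALSE]),
                c = 12, m = 1.25, seed = 102)
  }
  lc <- callLags(fit("monosome"), fit("polysome"))
  rec <- lagRecovery(lc, sim$truth)
  expect_gte(rec$percent[["lag1"]], 90)
  expect_gte(rec$percent[["lag0"]], 90)
  expect_gte(rec$percent[["lag2"]], 90)
})
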