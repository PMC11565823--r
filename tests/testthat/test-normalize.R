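test_that("CPM columns sum to a million and zero libraries are named", {
  m <- matrix(c(5, 5, 1, 0, 0, 0), 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_error(cpmNormalize(m), "s3")
  m2 <- m[, 1:2]
  cp <- cpmNormalize(m2)
  expect_equal(cp[, "s1"], c(a = 5e5, b = 5e5))
  expect_equal(cp[, "s2"], c(a = 1e6, b = 0))
  set.seed(9)
  r <- matrix(rpois(200, 30), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  expect_equal(unname(colSums(cpmNormalize(r))), rep(1e6, 4),
               tolerance = 1e-9)
  # scale invariance per sample
  r2 <- r; r2[, 2] <- r[, 2] * 7
  expect_equal(cpmNormalize(r2)[, 2], cpmNormalize(r)[, 2])
})

test_that("layer aggregation normalizes, log-averages and orders genes", {
  # single gene: every layer CPM is 1e6 regardless of fraction split
  comps <- compLabels <- c(paste0("F", 1:10), "total")
  counts <- matrix(c(10L, 30L, rep(7L, 9)), 1,
                   dimnames = list("g1", paste0("s", seq_along(comps))))
  sheet <- data.frame(sample_id = colnames(counts), stage = "GV",
                      compartment = comps, replicate = 1L)
  fe <- FractionExperiment(counts, sheet, stages = stageAxis("GV"))
  lay <- aggregateLayers(fe)
  expect_equal(unname(layerValues(lay$free)[1, 1]), log2(1e6 + 1))
  expect_equal(unname(layerValues(lay$polysome)[1, 1]), log2(1e6 + 1))
  # a stage missing part of a layer is an error
  feMiss <- FractionExperiment(counts[, -3, drop = FALSE], sheet[-3, ],
                               stages = stageAxis("GV"))
  expect_error(aggregateLayers(feMiss), "lacks fraction")

  sim <- simulateDataset(simulationConfig(nGenes = 30L, seed = 5L))
  layers <- aggregateLayers(sim$experiment)
  expect_true(all(vapply(layers, isLogScale, TRUE)))

  # two identical replicates average to either replicate
  cd <- SummarizedExperiment::colData(sim$experiment)
  keep <- cd$replicate == 1L
  cnt1 <- fractionCounts(sim$experiment)[, keep]
  dup <- cbind(cnt1, cnt1)
  colnames(dup) <- c(colnames(cnt1), paste0(colnames(cnt1), "_r2"))
  sheet2 <- data.frame(sample_id = colnames(dup),
                       stage = rep(cd$stage[keep], 2),
                       compartment = rep(cd$compartment[keep], 2),
                       replicate = rep(c(1L, 2L), each = sum(keep)))
  feDup <- FractionExperiment(dup, sheet2)
  feOne <- FractionExperiment(cnt1, sheet2[seq_len(sum(keep)), ])
  expect_equal(layerValues(aggregateLayers(feDup)$polysome),
               layerValues(aggregateLayers(feOne)$polysome))

  # gene reordering commutes with aggregation
  perm <- rev(seq_len(nrow(sim$experiment)))
  feP <- FractionExperiment(fractionCounts(sim$experiment)[perm, ],
                            data.frame(sample_id = colnames(sim$experiment),
                                       cd))
  expect_equal(layerValues(aggregateLayers(feP)$monosome),
               layerValues(layers$monosome)[perm, ])
})

test_that("planted monosome-specific genes sit above their polysome layer", {
  sim <- defaultSim()
  layers <- defaultLayers()
  g1 <- with(sim$truth$genes, gene_id[lagClass == "none" & baseMode == 1L])
  mono <- layerValues(layers$monosome)[g1, ]
  poly <- layerValues(layers$polysome)[g1, ]
  expect_true(all(mono > poly))
})

test_that("standardization gives mean-0 sd-1 rows and is idempotent", {
  z <- standardizeProfiles(matrix(c(1, 2, 3), 1,
                                  dimnames = list("g", c("a", "b", "c"))))
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(sd(z$values[1, ]), 1, tolerance = 1e-12)

  m <- rbind(g1 = c(5, 5, 5), g2 = rnorm(3), g3 = rnorm(3))
  colnames(m) <- c("a", "b", "c")
  z2 <- standardizeProfiles(m)
  expect_identical(z2$excluded, "g1")
  expect_true(all(abs(rowMeans(z2$values)) < 1e-9))
  expect_true(all(abs(apply(z2$values, 1, sd) - 1) < 1e-9))
  z3 <- standardizeProfiles(z2$values)
  expect_equal(z3$values, z2$values, tolerance = 1e-12)
  expect_error(standardizeProfiles(m[, 1, drop = FALSE]), "2 stages")
})
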