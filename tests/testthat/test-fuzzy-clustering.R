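test_that("membership updates respect symmetry and the zero-distance rule", {
  # equidistant point: memberships (0.5, 0.5) for any fuzzifier
  X <- rbind(a = c(-1, 0), b = c(1, 0), mid = c(0, 0))
  for (m in c(1.1, 1.25, 2)) {
    fm <- suppressWarnings(   # one update step on purpose
      fuzzyCMeans(X, c = 2, m = m, initCenters = rbind(c(-1, 0),
                                                       c(1, 0)),
                  maxIter = 1L, tol = 0))
    expect_equal(unname(memberships(fm)["mid", ]), c(0.5, 0.5),
                 tolerance = 1e-9)
    # point coinciding with a center is crisp there
    expect_equal(unname(memberships(fm)["a", ]), c(1, 0))
  }
  expect_error(fuzzyCMeans(X, c = 5), "clusters")
  expect_error(fuzzyCMeans(X, c = 2, m = 1), "exceed 1")
})

test_that("two planted blobs are recovered with crisp cores", {
  blob <- blobFixture()
  fm <- fuzzyCMeans(blob$x, c = 2, m = 1.25, seed = 1)
  u <- memberships(fm)
  expect_true(all(abs(rowSums(u) - 1) < 1e-9))
  expect_true(all(diff(objectiveTrace(fm)) <=
                    1e-8 * objectiveTrace(fm)[1]))
  hard <- max.col(u)
  acc <- max(mean(hard == blob$labels), mean(hard == 3 - blob$labels))
  expect_gte(acc, 0.99)
  cen <- clusterCenters(fm)
  cen <- cen[order(cen[, 1]), ]
  expect_lt(max(abs(cen - blob$centers)), 0.2)

  cores <- extractCores(fm, 0.5)
  expect_length(unassignedGenes(cores), 0L)
  expect_identical(unname(sort(lengths(coreSets(cores)))), c(100L, 100L))
})

test_that("seed determinism and permutation equivariance hold", {
  blob <- blobFixture(seed = 4)
  a <- fuzzyCMeans(blob$x, c = 2, seed = 7)
  b <- fuzzyCMeans(blob$x, c = 2, seed = 7)
  expect_identical(memberships(a), memberships(b))
  expect_identical(clusterCenters(a), clusterCenters(b))

  perm <- sample(nrow(blob$x))
  cp <- fuzzyCMeans(blob$x[perm, ], c = 2, m = 1.25,
                    initCenters = blob$centers)
  cu <- fuzzyCMeans(blob$x, c = 2, m = 1.25, initCenters = blob$centers)
  expect_equal(memberships(cp), memberships(cu)[perm, ],
               tolerance = 1e-12)
})

test_that("near-hard fuzzifier reproduces k-means assignments", {
  blob <- blobFixture(seed = 2)
  fm <- fuzzyCMeans(blob$x, c = 2, m = 1.01, seed = 1)
  hard <- max.col(memberships(fm))
  km <- kmeans(blob$x, centers = blob$centers)
  agree <- max(mean(hard == km$cluster), mean(hard == 3 - km$cluster))
  expect_equal(agree, 1)
})

test_that("an independent fuzzy c-means implementation agrees", {
  skip_if_not_installed("e1071")
  blob <- blobFixture(seed = 6)
  fm <- fuzzyCMeans(blob$x, c = 2, m = 1.5, seed = 3)
  ref <- e1071::cmeans(blob$x, centers = 2, m = 1.5)
  myC <- clusterCenters(fm)[order(clusterCenters(fm)[, 1]), ]
  refC <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(unname(myC), unname(refC), tolerance = 1e-3)
  ord <- order(clusterCenters(fm)[, 1])
  refOrd <- order(ref$centers[, 1])
  expect_equal(unname(memberships(fm)[, ord]),
               unname(ref$membership[, refOrd]), tolerance = 1e-3)
})

test_that("core extraction applies the threshold rules", {
  u <- rbind(g1 = c(0.9, 0.1), g2 = c(0.45, 0.55), g3 = c(0.5, 0.5))
  colnames(u) <- c("cluster1", "cluster2")
  centers <- rbind(cluster1 = c(1, 0, -1), cluster2 = c(-1, 0, 1))
  fm <- methods::new("FuzzyModel", centers = centers, memberships = u,
                     m = 1.25, objective = c(1), seed = 1L, nIter = 1L,
                     converged = TRUE)
  c5 <- extractCores(fm, 0.5)
  expect_identical(coreSets(c5)$cluster1, c("g1", "g3"))
  expect_identical(coreSets(c5)$cluster2, c("g2", "g3"))
  expect_identical(peakStages(c5), c(cluster1 = 1L, cluster2 = 3L))
  c6 <- extractCores(fm, 0.6)
  expect_identical(unassignedGenes(c6), c("g2", "g3"))
  expect_error(extractCores(fm, 0), "threshold")
})

test_that("mode labeling inverts any template permutation exactly", {
  tm <- modeTemplates()
  set.seed(8)
  for (i in 1:25) {
    p <- sample(6)
    expect_identical(unname(labelModes(tm[p, ])), p)
  }
  expect_identical(unname(labelModes(tm)), 1:6)
  # canonical single centers
  expect_identical(unname(labelModes(rbind(c(-1, 1, -1), tm[2:6, ])))[1],
                   1L)
  expect_error(labelModes(matrix(1, 6, 3)), "indistinguishable")
  expect_error(labelModes(tm[1:5, ]), "6 x 3")
})
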