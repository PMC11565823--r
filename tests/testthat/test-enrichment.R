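test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (n in c(1, 2, 17, 1000, 10000)) {
    p <- runif(n)
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
  # ties and duplicated values
  p <- rep(c(0.01, 0.5, 0.04), times = c(5, 3, 7))
  expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
})

# Build a one-stage experiment directly from per-fraction count matrices.
pairExperiment <- function(fractionCountsList, nRep = 3L) {
  genes <- rownames(fractionCountsList[[1]])
  cols <- list(); ids <- c(); comp <- c(); rep <- c()
  for (f in names(fractionCountsList)) {
    m <- fractionCountsList[[f]]
    for (r in seq_len(ncol(m))) {
      cols[[length(cols) + 1L]] <- m[, r]
      ids <- c(ids, paste("GV", f, r, sep = "_"))
      comp <- c(comp, f); rep <- c(rep, r)
    }
  }
  cnt <- do.call(cbind, cols)
  dimnames(cnt) <- list(genes, ids)
  FractionExperiment(cnt, data.frame(sample_id = ids, stage = "GV",
                                     compartment = comp, replicate = rep))
}

test_that("identical occupancy gives zero fold change and ns calls", {
  genes <- paste0("g", 1:5)
  base <- matrix(rep(c(50, 100, 10, 400, 80), 3), 5,
                 dimnames = list(genes, NULL))
  fr <- c(paste0("F", 3:5), paste0("F", 6:10))
  fl <- lapply(setNames(fr, fr), function(f)
    if (f %in% paste0("F", 3:5)) base else base * 3 / 5)
  fe <- pairExperiment(fl)
  res <- polyVsMonoTest(fe, "GV")
  expect_equal(res$log2fc, rep(0, 5))
  expect_true(all(res$call == "ns"))
})

test_that("swapping the two groups negates fold changes", {
  set.seed(7)
  genes <- paste0("g", 1:40)
  mk <- function() matrix(rnbinom(120, mu = 200, size = 20), 40,
                          dimnames = list(genes, NULL))
  monoC <- mk(); polyC <- mk()
  zero <- matrix(0L, 40, 3, dimnames = list(genes, NULL))
  # mass concentrated in one fraction per group; B swaps the groups
  feA <- pairExperiment(list(F3 = monoC, F4 = zero, F5 = zero,
                             F6 = polyC, F7 = zero, F8 = zero,
                             F9 = zero, F10 = zero))
  feB <- pairExperiment(list(F3 = polyC, F4 = zero, F5 = zero,
                             F6 = monoC, F7 = zero, F8 = zero,
                             F9 = zero, F10 = zero))
  a <- polyVsMonoTest(feA, "GV")
  b <- polyVsMonoTest(feB, "GV")
  expect_equal(b$log2fc, -a$log2fc, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("the null simulation is calibrated and spiked genes are found", {
  cfg <- simulationConfig(seed = 1L)
  null <- simulateNullPair(cfg, nGenes = 5000L)
  res <- polyVsMonoTest(null, "GV")
  fpr <- mean(res$p < 0.05)
  expect_gte(fpr, 0.02)
  expect_lte(fpr, 0.08)

  eff <- simulateNullPair(simulationConfig(seed = 2L), nGenes = 2000L,
                          effectLog2FC = 3, nEffect = 1000L)
  r2 <- polyVsMonoTest(eff, "GV")
  truthFc <- attr(eff, "trueLog2FC")[r2$gene_id]
  power <- mean(r2$call[truthFc == 3] == "poly_up")
  expect_gte(power, 0.8)
  expect_gte(mean(r2$call[truthFc == -3] == "mono_up"), 0.8)
  # 8-fold polysome-shifted genes are called poly_up
  expect_gt(mean(r2$log2fc[truthFc == 3]), 1)
})

test_that("switch genes are monosome-enriched then polysome-enriched", {
  res <- list(
    zygote = data.frame(gene_id = c("a", "b", "c"), stage = "zygote",
                        log2fc = c(-3, -3, 0), p = 0.001, fdr = 0.001,
                        call = c("mono_up", "mono_up", "ns")),
    `2-Cell` = data.frame(gene_id = c("a", "b", "c"), stage = "2-Cell",
                          log2fc = c(3, 0, 3), p = 0.001, fdr = 0.001,
                          call = c("poly_up", "ns", "poly_up")))
  expect_identical(switchGenes(res, "zygote", "2-Cell"), "a")
  expect_error(switchGenes(res, "zygote", "4-Cell"), "4-Cell")
})

test_that("planted switch genes are recovered from counts", {
  # two stages; gene set A mono-heavy at stage 1, poly-heavy at stage 2
  cfg <- simulationConfig(seed = 9L)
  mkStage <- function(stage, shift) {
    set.seed(cfg$seed + shift + 17L)
    nG <- 300L
    genes <- sprintf("g%03d", seq_len(nG))
    switchSet <- seq_len(30L)
    delta <- rep(0, nG)
    delta[switchSet] <- if (shift == 0) -3 else 3
    A <- 2^(6 + rnorm(nG, 0, 0.5))
    r <- 2^delta
    wM <- 0.9 / (1 + r); wP <- 0.9 - wM
    cnt <- NULL; ids <- c(); comp <- c(); rp <- c()
    for (f in 1:10) {
      w <- if (f <= 2) 0.1 / 2 else if (f <= 5) wM / 3 else wP / 5
      mu <- 2e5 * (A * w) / sum(A * w)
      for (rep_ in 1:3) {
        cnt <- cbind(cnt, rnbinom(nG, mu = mu, size = 20))
        ids <- c(ids, paste(stage, f, rep_, sep = "_"))
        comp <- c(comp, paste0("F", f)); rp <- c(rp, rep_)
      }
    }
    dimnames(cnt) <- list(genes, ids)
    FractionExperiment(cnt, data.frame(sample_id = ids, stage = stage,
                                       compartment = comp,
                                       replicate = rp))
  }
  feZ <- mkStage("zygote", 0)
  fe2 <- mkStage("2-Cell", 1)
  res <- list(zygote = polyVsMonoTest(feZ, "zygote"),
              `2-Cell` = polyVsMonoTest(fe2, "2-Cell"))
  found <- switchGenes(res, "zygote", "2-Cell")
  planted <- sprintf("g%03d", 1:30)
  expect_gte(length(intersect(found, planted)) / 30, 0.9)
  expect_length(setdiff(found, planted), 0L)
})
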