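# Shared fixtures and independent oracles. The default simulation is
# memoized so that several test files can reuse one draw.

.fixtureCache <- new.env(parent = emptyenv())

defaultSim <- function() {
  if (is.null(.fixtureCache$sim))
    .fixtureCache$sim <- simulateDataset(simulationConfig(seed = 1L))
  .fixtureCache$sim
}

defaultLayers <- function() {
  if (is.null(.fixtureCache$layers))
    .fixtureCache$layers <- aggregateLayers(defaultSim()$experiment)
  .fixtureCache$layers
}

# Two well-separated 3-d blobs (centers +-5, sd 0.5, 100 points each).
blobFixture <- function(seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(300, -5, 0.5), 100),
             matrix(rnorm(300, 5, 0.5), 100))
  rownames(X) <- paste0("p", seq_len(200))
  list(x = X, labels = rep(1:2, each = 100),
       centers = rbind(rep(-5, 3), rep(5, 3)))
}

# Tiny valid counts + sheet pair.
toyDataset <- function() {
  counts <- matrix(c(1L, 2L, 3L, 4L, 5L, 6L), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  sheet <- data.frame(sample_id = c("s1", "s2"), stage = c("GV", "GV"),
                      compartment = c("F1", "F2"),
                      replicate = c(1L, 1L), stringsAsFactors = FALSE)
  list(counts = counts, sheet = sheet)
}

# Brute-force Benjamini-Hochberg step-up: sort, p * n / rank, cumulative
# minimum from the largest rank, capped at 1.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  if (n == 1L) out <- pmin(p, 1)
  out
}

# Exact hypergeometric upper tail by explicit summation of the pmf:
# P(overlap >= k) for |A| = a, |B| = b drawn from a universe of size N.
hyperOracle <- function(k, a, b, N) {
  i <- max(0L, a + b - N):min(a, b)
  pmf <- choose(a, i) * choose(N - a, b - i) / choose(N, b)
  sum(pmf[i >= k])
}

# Hand-built FuzzyModel with crisp memberships and given center peaks,
# for unit tests of downstream peak logic.
crispModel <- function(genes, clusterOf, centerPeaks, nStages = 8L) {
  c <- length(centerPeaks)
  u <- matrix(0, length(genes), c,
              dimnames = list(genes, paste0("cluster", seq_len(c))))
  u[cbind(seq_along(genes), clusterOf)] <- 1
  centers <- matrix(-1, c, nStages,
                    dimnames = list(paste0("cluster", seq_len(c)),
                                    paste0("s", seq_len(nStages))))
  centers[cbind(seq_len(c), centerPeaks)] <- 1
  methods::new("FuzzyModel", centers = centers, memberships = u,
               m = 1.25, objective = c(2, 1), seed = 1L, nIter = 2L,
               converged = TRUE)
}
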