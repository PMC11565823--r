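# All permutations of 1..n in lexicographic order (n is tiny here: 6).
permutationsLex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsLex(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(first, rest[sub[r, ]])
    }
  }
  out
}

# Squared Euclidean distances between rows of X (n x p) and V (c x p).
sqDistances <- function(X, V) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(V))) +
    outer(rep(1, nrow(X)), rowSums(V^2)) - 2 * X %*% t(V)
  pmax(d2, 0)
}

# Membership update: u_gj = [sum_k (d_gj / d_gk)^(2/(m-1))]^-1, with a
# crisp membership on the first zero-distance cluster. Distances are
# scaled by the row minimum so that small fuzzifiers (large exponents)
# cannot overflow: the scaled powers are at most 1 and underflow of the
# far clusters to 0 is exact in the limit.
fcmMemberships <- function(d2, m) {
  rmin <- do.call(pmin, as.data.frame(d2))
  pw <- (d2 / pmax(rmin, .Machine$double.xmin))^(-1 / (m - 1))
  u <- pw / rowSums(pw)
  zero <- d2 <= .Machine$double.eps
  hit <- which(rowSums(zero) > 0L)
  for (g in hit) {
    u[g, ] <- 0
    u[g, which(zero[g, ])[1L]] <- 1
  }
  u
}

fcmObjective <- function(u, d2, m) sum(u^m * d2)

fcmFit <- function(X, centers, m, tol, maxIter) {
  V <- centers
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  while (iter < maxIter) {
    iter <- iter + 1L
    d2 <- sqDistances(X, V)
    u <- fcmMemberships(d2, m)
    w <- u^m
    cw <- colSums(w)
    Vnew <- (t(w) %*% X) / cw
    empty <- cw <= .Machine$double.xmin
    if (any(empty)) Vnew[empty, ] <- V[empty, ]   # keep starved centers
    trace <- c(trace, fcmObjective(u, sqDistances(X, Vnew), m))
    shift <- max(abs(Vnew - V))
    V <- Vnew
    if (shift < tol) { converged <- TRUE; break }
  }
  list(centers = V, memberships = u, objective = trace, nIter = iter,
       converged = converged)
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with Euclidean distances: memberships
#' \eqn{u_{gj} = [\sum_k (d_{gj}/d_{gk})^{2/(m-1)}]^{-1}} and centers
#' \eqn{v_j = \sum_g u_{gj}^m x_g / \sum_g u_{gj}^m}, alternated until the
#' largest center displacement falls below `tol` or `maxIter` is reached.
#' A point at exactly zero distance from a center gets crisp membership 1
#' on the first such cluster. By default initialization draws `c` distinct
#' data rows as starting centers, repeated `nstart` times keeping the
#' restart with the lowest final objective; `initCenters` fixes the start
#' explicitly (e.g. at the canonical mode templates) and suppresses
#' restarts. The objective \eqn{J_m = \sum_g \sum_j u_{gj}^m d_{gj}^2} is
#' recorded per iteration and is non-increasing.
#'
#' @param x A `StandardizedProfile` (see [standardizeProfiles()]) or a
#'   numeric matrix of observations in rows.
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier (> 1); values near 1.25 keep cores crisp for short
#'   standardized time courses.
#' @param tol Convergence tolerance on the maximum center displacement.
#' @param maxIter Iteration cap; hitting it flags non-convergence with a
#'   warning and returns the model anyway.
#' @param seed Integer seed for the initialization draws.
#' @param nstart Number of seeded random restarts.
#' @param initCenters Optional c x p matrix of explicit starting centers.
#' @return A [FuzzyModel-class].
#' @examples
#' pts <- rbind(matrix(rnorm(60, -3, .4), 30), matrix(rnorm(60, 3, .4), 30))
#' rownames(pts) <- paste0("p", 1:60)
#' fuzzyCMeans(pts, c = 2, seed = 1)
#' @export
fuzzyCMeans <- function(x, c, m = 1.25, tol = 1e-8, maxIter = 300L,
                        seed = 1L, nstart = 10L, initCenters = NULL) {
  X <- if (inherits(x, "StandardizedProfile")) x$values else as.matrix(x)
  if (is.null(rownames(X))) rownames(X) <- paste0("row", seq_len(nrow(X)))
  if (c < 2L) stop("'c' must be at least 2")
  if (m <= 1) stop("fuzzifier 'm' must exceed 1")
  if (nrow(X) < c)
    stop("cannot fit ", c, " clusters to ", nrow(X), " observations")
  best <- NULL
  if (!is.null(initCenters)) {
    initCenters <- as.matrix(initCenters)
    stopifnot(nrow(initCenters) == c, ncol(initCenters) == ncol(X))
    best <- fcmFit(X, initCenters, m, tol, maxIter)
  } else {
    set.seed(seed)
    for (i in seq_len(nstart)) {
      V0 <- X[sample.int(nrow(X), c), , drop = FALSE]
      fit <- fcmFit(X, V0, m, tol, maxIter)
      if (is.null(best) ||
          fit$objective[length(fit$objective)] <
            best$objective[length(best$objective)])
        best <- fit
    }
  }
  if (!best$converged)
    warning("fuzzy c-means did not converge within ", maxIter,
            " iterations")
  rownames(best$memberships) <- rownames(X)
  colnames(best$memberships) <- paste0("cluster", seq_len(c))
  rownames(best$centers) <- paste0("cluster", seq_len(c))
  colnames(best$centers) <- colnames(X)
  methods::new("FuzzyModel", centers = best$centers,
               memberships = best$memberships, m = m,
               objective = best$objective, seed = as.integer(seed),
               nIter = best$nIter, converged = best$converged)
}

#' Extract cluster cores
#'
#' A gene belongs to the core of cluster j when its membership there
#' reaches `threshold`; genes in no core are reported as unassigned. The
#' peak stage of each cluster is the position of its center's maximum.
#' Because membership rows sum to 1, thresholds above 0.5 guarantee
#' pairwise-disjoint cores.
#'
#' @param model A [FuzzyModel-class].
#' @param threshold Membership cutoff in (0, 1].
#' @return A [ClusterCores-class].
#' @export
extractCores <- function(model, threshold = 0.5) {
  stopifnot(methods::is(model, "FuzzyModel"))
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  u <- memberships(model)
  cores <- lapply(seq_len(ncol(u)),
                  function(j) rownames(u)[u[, j] >= threshold])
  names(cores) <- colnames(u)
  assigned <- unique(unlist(cores, use.names = FALSE))
  methods::new("ClusterCores", threshold = threshold, coreSets = cores,
               peakStage = apply(clusterCenters(model), 1L, which.max),
               unassigned = setdiff(rownames(u), assigned))
}

#' Label clusters with selectivity modes
#'
#' Matches six cluster centers over the (transcriptome, monosome,
#' polysome) features to the six canonical selectivity-mode templates (see
#' [modeTemplates()]) one-to-one, maximizing total cosine similarity by
#' exhaustive search over all 720 assignments; ties break to the
#' lexicographically smallest permutation. Centers that are all equal have
#' no distinguishable mode structure and raise an error.
#'
#' @param centers 6 x 3 numeric matrix; columns ordered (transcriptome,
#'   monosome, polysome).
#' @return Integer vector of length 6: `modeOf[j]` is the mode label
#'   (1-6) of cluster j.
#' @examples
#' labelModes(modeTemplates()[c(3, 1, 2, 6, 5, 4), ])
#' @export
labelModes <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) != 6L || ncol(centers) != 3L)
    stop("'centers' must be a 6 x 3 matrix over ",
         "(transcriptome, monosome, polysome)")
  if (max(apply(centers, 2L, function(x) diff(range(x)))) < 1e-12)
    stop("modes indistinguishable: all centers are equal")
  tmpl <- modeTemplates()
  cosSim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  simMat <- matrix(0, 6L, 6L)       # simMat[j, k] = cos(center j, mode k)
  for (j in 1:6) for (k in 1:6)
    simMat[j, k] <- cosSim(centers[j, ], tmpl[k, ])
  perms <- permutationsLex(6L)
  total <- vapply(seq_len(nrow(perms)), function(r)
    sum(simMat[cbind(1:6, perms[r, ])]), 0)
  bestScore <- max(total)
  cand <- which(total >= bestScore - 1e-12)
  best <- perms[cand[1L], ]          # perms are in lexicographic order
  stats::setNames(as.integer(best), rownames(centers))
}
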