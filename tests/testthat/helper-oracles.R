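# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive loops and first-principles
# definitions, not the package's code paths.

# Entropy in bits via natural log, looped.
oracleEntropy <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi) / log(2)
  h
}

# Direct evaluation of the temporal specificity score: log10-density
# normalization, JS divergence via entropies, sqrt metric, max/argmax.
oracleSpecificity <- function(V, sqrtForm = TRUE) {
  lg <- log(V + 1, base = 10)
  e <- lg / sum(lg)
  n <- length(e)
  scores <- numeric(n)
  for (s in seq_len(n)) {
    es <- rep(0, n); es[s] <- 1
    m <- (e + es) / 2
    div <- oracleEntropy(m) - (oracleEntropy(e) + oracleEntropy(es)) / 2
    div <- max(0, div)
    d <- if (sqrtForm) sqrt(div) else div
    scores[s] <- 1 - d
  }
  list(scores = scores, max = max(scores), argmax = which.max(scores))
}

# Topological overlap by triple loop.
oracleTOM <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    tom[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Exhaustive optimal-threshold scan with the same candidate-set rule
# (sorted unique coverages plus a below-minimum sentinel), decision rule
# "good if coverage >= t", ties to the smallest threshold.
oracleThreshold <- function(coverage, label) {
  good <- coverage[label == "good"]
  bad <- coverage[label == "bad"]
  u <- sort(unique(coverage))
  sentinel <- if (u[1] > 0) u[1] / 2 else -1
  thr <- c(sentinel, u)
  best <- NULL
  for (t in thr) {
    sens <- sum(good >= t) / length(good)
    spec <- sum(bad < t) / length(bad)
    d2 <- (1 - sens)^2 + (1 - spec)^2
    if (is.null(best) || d2 < best$d2 - 1e-15) best <- list(t = t, d2 = d2)
  }
  best$t
}

# Upper-tail hypergeometric P(X >= k) by enumerating every possible draw
# of size nDraw from a universe of size N containing K successes.
oracleHyperUpper <- function(k, K, N, nDraw) {
  draws <- utils::combn(N, nDraw)
  hits <- 0
  for (c_ in seq_len(ncol(draws)))
    if (sum(draws[, c_] <= K) >= k) hits <- hits + 1
  hits / ncol(draws)
}

# Two-sided Fisher exact p for a 2x2 table by enumerating all tables with
# the observed margins and summing point probabilities not exceeding the
# observed one (the probability-ordering convention).
oracleFisher2x2 <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  amin <- max(0, c1 - m2); amax <- min(m1, c1)
  pObs <- stats::dhyper(a, m1, m2, c1)
  p <- 0
  for (x in amin:amax) {
    px <- stats::dhyper(x, m1, m2, c1)
    if (px <= pObs * (1 + 1e-7)) p <- p + px
  }
  p
}

# Adjusted Rand index between two labelings (mclust provides the
# reference implementation used in recovery checks).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
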