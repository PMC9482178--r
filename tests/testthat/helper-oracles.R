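# Brute-force information-theory oracles built directly on contingency
# tables; deliberately independent of the package's C++ pairwise engine.

oracle_entropy <- function(x, base = exp(1)) {
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log(p, base = base))
}

oracle_joint_entropy <- function(x, y, base = exp(1)) {
  p <- as.numeric(table(x, y))
  p <- p[p > 0] / length(x)
  -sum(p * log(p, base = base))
}

# MI by direct summation of p(x,y) log[p(x,y)/(p(x)p(y))]
oracle_mi <- function(x, y, base = exp(1)) {
  tab <- table(x, y)
  n <- length(x)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  s <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0) s <- s + pij * log(pij / (px[i] * py[j]), base = base)
  }
  as.numeric(s)
}

# Full adjusted-MI matrix via the oracles, using the package's discretizer
# (the binning itself is checked separately against a tally oracle).
oracle_adjusted_mi <- function(counts, scheme = discretizationScheme()) {
  m <- ncol(counts)
  labs <- lapply(seq_len(m), function(j) discretize(counts[, j], scheme))
  a <- diag(1, m)
  for (j in seq_len(m - 1)) for (k in (j + 1):m) {
    hj <- oracle_joint_entropy(labs[[j]], labs[[k]])
    mi <- oracle_mi(labs[[j]], labs[[k]])
    a[j, k] <- a[k, j] <- if (hj > 0) mi / hj else 0
  }
  dimnames(a) <- list(colnames(counts), colnames(counts))
  a
}

random_count_table <- function(n, m, seed, lambda = 8) {
  set.seed(seed)
  MICountTable(matrix(rpois(n * m, lambda), n, m))
}

# symmetric weight matrix with unit diagonal for network-level tests
random_adjacency <- function(m, seed) {
  set.seed(seed)
  v <- matrix(0, m, m)
  v[upper.tri(v)] <- runif(m * (m - 1) / 2)
  v <- v + t(v)
  diag(v) <- 1
  dimnames(v) <- list(paste0("T", seq_len(m)), paste0("T", seq_len(m)))
  v
}
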