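#' Shannon entropy of a binned vector
#'
#' Plug-in entropy estimate \eqn{H = -\sum_x p(x) \log p(x)} over the
#' empirical bin frequencies, in nats (natural log) by default.
#'
#' @param x vector of bin labels (any discrete values; typically the output
#'   of [discretize()]).
#' @param base logarithm base; `exp(1)` for nats (default), 2 for bits.
#' @return nonnegative entropy; 0 iff a single bin is occupied.
#' @examples
#' entropy(c(1, 1, 2, 2))  # log(2)
#' @export
entropy <- function(x, base = exp(1)) {
  if (length(x) == 0L) stop("empty vector: invalid taxon column")
  p <- tabulate(match(x, unique(x)))
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Joint Shannon entropy of two binned vectors
#'
#' \eqn{H(X,Y) = -\sum_{x,y} p(x,y) \log p(x,y)} over the empirical joint
#' frequencies of the paired observations.
#'
#' @param x,y equal-length vectors of bin labels.
#' @inheritParams entropy
#' @return joint entropy; satisfies
#'   \eqn{\max(H(X), H(Y)) \le H(X,Y) \le H(X)+H(Y)}.
#' @examples
#' jointEntropy(c(1, 1, 2, 2), c(1, 2, 1, 2))  # log(4)
#' @export
jointEntropy <- function(x, y, base = exp(1)) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  entropy(paste(x, y, sep = "\r"), base = base)
}

#' Mutual information of two binned vectors
#'
#' Computed through the entropy identity
#' \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)}; tiny negatives from floating point
#' are clamped to zero. Zero iff the empirical joint distribution factorizes;
#' equals \eqn{H(X)} when each variable determines the other.
#'
#' @inheritParams jointEntropy
#' @return mutual information, `>= 0`, symmetric in its arguments.
#' @examples
#' x <- rep(1:2, 50)
#' mutualInfo(x, x)  # = entropy(x)
#' @export
mutualInfo <- function(x, y, base = exp(1)) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  mi <- entropy(x, base) + entropy(y, base) - jointEntropy(x, y, base)
  if (mi < 0) {
    if (mi < -1e-9) stop("negative mutual information beyond tolerance")
    mi <- 0
  }
  mi
}

#' Adjusted mutual-information adjacency matrix
#'
#' Discretizes every taxon profile of a count table, estimates all pairwise
#' mutual informations, and normalizes each entry by the pair's joint entropy.
#' The result satisfies the three adjacency conditions: entries in [0, 1],
#' symmetry, and unit diagonal. The normalization makes the matrix invariant
#' to the logarithm base. Degenerate pairs (both taxa constant, joint entropy
#' zero) are defined to share no information; a zero-variance taxon therefore
#' has an all-zero off-diagonal row.
#'
#' @param table an [MICountTable-class] (or a plain samples x taxa matrix).
#' @param scheme a [discretizationScheme()].
#' @return an [AdjustedMI-class] object.
#' @examples
#' tab <- simulateNullTable(50, 6, seed = 1)
#' adjustedMI(tab)
#' @export
adjustedMI <- function(table, scheme = discretizationScheme()) {
  counts <- if (is(table, "MICountTable")) counts(table) else {
    counts(MICountTable(table))
  }
  if (ncol(counts) < 2L || nrow(counts) < 2L)
    stop("network operations need at least 2 samples and 2 taxa")
  d <- .discretize_table(counts, scheme)
  comp <- cpp_mi_components(d$labels, d$nlev)
  ids <- colnames(counts)
  dimnames(comp$adjusted) <- dimnames(comp$Hjoint) <-
    dimnames(comp$mi) <- list(ids, ids)
  names(comp$H) <- ids
  new("AdjustedMI", values = comp$adjusted, entropies = comp$H,
      jointEntropies = comp$Hjoint, mi = comp$mi,
      nBins = as.integer(d$nlev), method = scheme$method)
}

# Adjusted-MI matrix for a subset (possibly with repeats) of pre-discretized
# columns; used by the bootstrap, where resampled columns are exact copies of
# original taxa and therefore reuse their bin labels.
.adjusted_from_labels <- function(labels, nlev, idx) {
  cpp_mi_components(labels[, idx, drop = FALSE], nlev[idx])$adjusted
}
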