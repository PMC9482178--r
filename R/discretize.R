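#' Discretization scheme for abundance profiles
#'
#' Mutual information is estimated from histograms of each taxon's abundance
#' profile. A scheme fixes the binning method and the bin-count rule applied
#' per taxon.
#'
#' @param method `"equal_width"` (default) partitions the observed range into
#'   bins of equal width; `"equal_frequency"` places bin edges at empirical
#'   quantiles so bins hold roughly equal numbers of samples (duplicate edges
#'   from tied counts are collapsed).
#' @param bins either a positive integer bin count, or a rule name:
#'   `"sturges"` (default, `ceiling(log2(n)) + 1`) or `"sqrt"`
#'   (`ceiling(sqrt(n))`).
#' @return an object of class `DiscretizationScheme`.
#' @examples
#' discretizationScheme("equal_frequency", bins = 4)
#' @export
discretizationScheme <- function(method = c("equal_width", "equal_frequency"),
                                 bins = "sturges") {
  method <- match.arg(method)
  if (is.character(bins)) {
    bins <- match.arg(bins, c("sturges", "sqrt"))
  } else {
    bins <- as.integer(bins)
    if (length(bins) != 1L || is.na(bins) || bins < 1L)
      stop("bins must be a positive integer or a rule name")
  }
  structure(list(method = method, bins = bins),
            class = "DiscretizationScheme")
}

#' @export
print.DiscretizationScheme <- function(x, ...) {
  cat("DiscretizationScheme:", x$method, "| bins:", x$bins, "\n")
  invisible(x)
}

.n_bins <- function(scheme, n) {
  if (is.character(scheme$bins))
    switch(scheme$bins,
           sturges = as.integer(ceiling(log2(n)) + 1),
           sqrt = as.integer(ceiling(sqrt(n))))
  else scheme$bins
}

#' Discretize one abundance profile
#'
#' Maps a numeric vector to integer bin labels `1..L` under a
#' [discretizationScheme()]. A constant vector collapses to a single bin
#' (never an error). Bin edges and the empirical bin probabilities are
#' attached as attributes `"edges"` and `"p"`.
#'
#' @param x numeric vector with at least 2 observations.
#' @param scheme a `DiscretizationScheme`.
#' @return integer vector of bin labels with attributes `edges`, `p`, and
#'   `nlevels` (the number of bins spanned by the edges).
#' @examples
#' b <- discretize(c(0, 0, 10, 10), discretizationScheme(bins = 2))
#' attr(b, "p")
#' @export
discretize <- function(x, scheme = discretizationScheme()) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("x must be a numeric vector with >= 2 observations")
  if (anyNA(x)) stop("x must not contain NA")
  nb <- .n_bins(scheme, length(x))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    edges <- c(rng[1] - 0.5, rng[1] + 0.5)
  } else if (scheme$method == "equal_width") {
    edges <- seq(rng[1], rng[2], length.out = nb + 1L)
  } else {
    edges <- unique(quantile(x, probs = seq(0, 1, length.out = nb + 1L),
                             type = 7, names = FALSE))
    if (length(edges) < 2L) edges <- c(rng[1] - 0.5, rng[2] + 0.5)
  }
  lab <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nlev <- length(edges) - 1L
  p <- tabulate(lab, nbins = nlev) / length(lab)
  structure(as.integer(lab), edges = edges, p = p, nlevels = nlev)
}

.discretize_table <- function(counts, scheme) {
  n <- nrow(counts); m <- ncol(counts)
  labels <- matrix(0L, n, m, dimnames = dimnames(counts))
  nlev <- integer(m)
  for (j in seq_len(m)) {
    b <- discretize(counts[, j], scheme)
    labels[, j] <- b
    nlev[j] <- attr(b, "nlevels")
  }
  list(labels = labels, nlev = nlev)
}
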