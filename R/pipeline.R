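#' Run the full MI-network contaminant filter
#'
#' End-to-end pipeline: adjusted mutual-information adjacency, scale-free
#' threshold selection over `tauGrid`, hard thresholding at the selected
#' cutoff, and removal of isolated taxa. Optionally, quantile-based removal
#' guided by the step tests can be layered on top: taxa below the
#' test-recommended degree quantile are removed as well.
#'
#' @param table an [MICountTable-class] object (or samples x taxa matrix).
#' @param scheme a [discretizationScheme()].
#' @param tauGrid candidate hard thresholds (default 0.05 to 0.95 by 0.05).
#' @param quantileRemoval if `TRUE`, additionally run [scanSteps()] and
#'   remove taxa below the recommended quantile of weighted degree.
#' @param grid,tests,M,B,alpha,seed forwarded to [scanSteps()] when
#'   `quantileRemoval = TRUE`.
#' @return an object of class `MIFilterResult`: list with `adjustedMI`,
#'   `scan` ([ThresholdScan-class]), `network` ([MINetwork-class]), `kept`,
#'   `removed`, `filtered` (the filtered [MICountTable-class]), and, when
#'   requested, `stepScan` and `recommended`.
#' @examples
#' res <- miFilter(simulateCommunity(communitySpec(seed = 1)))
#' res$kept
#' @export
miFilter <- function(table, scheme = discretizationScheme(),
                     tauGrid = seq(0.05, 0.95, by = 0.05),
                     quantileRemoval = FALSE,
                     grid = seq(0.01, 0.96, by = 0.05),
                     tests = "both", M = 500, B = 500, alpha = 0.05,
                     seed = NULL) {
  if (!is(table, "MICountTable")) table <- MICountTable(table)
  adj <- adjustedMI(table, scheme)
  scan <- scanThresholds(adj, tauGrid)
  net <- hardThreshold(adj, selectedTau(scan))
  part <- isolatedTaxa(net)
  kept <- part$kept
  removed <- part$removed
  out <- list(adjustedMI = adj, scan = scan, network = net)
  if (quantileRemoval) {
    ss <- scanSteps(table, scheme = scheme, grid = grid, tests = tests,
                    M = M, B = B, alpha = alpha, seed = seed)
    qr <- removeBelowQuantile(adj, q = ss$recommended)
    removed <- union(removed, qr$removed)
    kept <- setdiff(taxonIDs(table), removed)
    out$stepScan <- ss
    out$recommended <- ss$recommended
  }
  out$kept <- kept
  out$removed <- removed
  out$filtered <- table[, kept]
  class(out) <- "MIFilterResult"
  out
}

#' @export
print.MIFilterResult <- function(x, ...) {
  m <- length(x$kept) + length(x$removed)
  cat(sprintf("MIFilterResult: tau = %.3g; kept %d / %d taxa (%.1f%% filtered)\n",
              networkTau(x$network), length(x$kept), m,
              100 * length(x$removed) / m))
  if (!is.null(x$recommended))
    cat(sprintf("  quantile removal applied up to q = %.2f\n", x$recommended))
  invisible(x)
}
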