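#' Weighted connectivity degrees
#'
#' The weighted degree of taxon j is the sum of its adjusted-MI edge weights
#' to all other taxa (off-diagonal row sum; self-information is excluded so a
#' constant +1 does not distort the ranks of low-degree taxa).
#'
#' @param adj an [AdjustedMI-class] object (or symmetric matrix).
#' @return list with `d` (named numeric vector of weighted degrees) and
#'   `ordering` (taxon IDs sorted by increasing degree; ties broken by
#'   lexicographic taxon ID, so the ordering is deterministic).
#' @examples
#' weightedDegrees(adjustedMI(simulateNullTable(50, 5, seed = 1)))
#' @export
weightedDegrees <- function(adj) {
  v <- if (is(adj, "AdjustedMI")) adjacency(adj) else adj
  if (is.null(colnames(v))) {
    dimnames(v) <- list(paste0("T", seq_len(ncol(v))),
                        paste0("T", seq_len(ncol(v))))
  }
  d <- rowSums(v) - diag(v)
  ord <- names(d)[order(d, names(d), method = "radix")]
  list(d = d, ordering = ord)
}

#' Remove taxa below a degree quantile
#'
#' Removes taxa whose weighted degree lies strictly below the empirical
#' `q`-quantile of all degrees (type-7 linear-interpolation quantile), and
#' returns the principal submatrix on the retained taxa. Pairwise MI does not
#' change when other columns are dropped, so the submatrix is exact — no
#' recomputation is needed.
#'
#' @param adj an [AdjustedMI-class] object or symmetric matrix.
#' @param d output of [weightedDegrees()] (recomputed when `NULL`).
#' @param q quantile in [0, 1).
#' @return list with `reduced` (matrix), `removed` and `retained` (taxon IDs).
#' @examples
#' a <- adjustedMI(simulateNullTable(50, 8, seed = 1))
#' removeBelowQuantile(a, q = 0.5)$removed
#' @export
removeBelowQuantile <- function(adj, d = NULL, q = 0) {
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)")
  v <- if (is(adj, "AdjustedMI")) adjacency(adj) else adj
  if (is.null(d)) d <- weightedDegrees(v)
  cut <- quantile(d$d, probs = q, type = 7, names = FALSE)
  removed <- names(d$d)[d$d < cut]
  retained <- setdiff(colnames(v), removed)
  list(reduced = v[retained, retained, drop = FALSE],
       removed = removed, retained = retained)
}

#' Frobenius information loss of a reduced adjacency
#'
#' \eqn{\Lambda = 1 - \|I'\|_F^2 / \|I\|_F^2}: the fraction of the squared
#' Frobenius norm of the full adjusted-MI matrix lost by restricting to a
#' principal submatrix. 0 when nothing is removed, 1 when everything is.
#'
#' @param full full adjusted-MI matrix (or [AdjustedMI-class]).
#' @param reduced principal submatrix on the retained taxa (0 x 0 allowed).
#' @return loss in [0, 1].
#' @examples
#' a <- adjacency(adjustedMI(simulateNullTable(50, 5, seed = 1)))
#' informationLoss(a, a[-1, -1])
#' @export
informationLoss <- function(full, reduced) {
  fv <- if (is(full, "AdjustedMI")) adjacency(full) else full
  rv <- if (is(reduced, "AdjustedMI")) adjacency(reduced) else reduced
  1 - sum(rv^2) / sum(fv^2)
}

# squared-Frobenius norm of the principal submatrix on `idx` of W2 = v^2
.sub_norm2 <- function(W2, idx) sum(W2[idx, idx])

#' Information-loss profile along a quantile grid
#'
#' For each quantile `q_k` of the weighted connectivity degrees, removes the
#' taxa below it and records the removal count `r_k`, the loss `Lambda_k`,
#' and the step difference `Delta_{k+1} = Lambda_{k+1} - Lambda_k`. The loss
#' is non-decreasing along the grid because removing more taxa can only
#' shrink the submatrix norm.
#'
#' @param adj an [AdjustedMI-class] object or symmetric matrix.
#' @param grid strictly increasing quantiles in [0, 1); default 0.01 to 0.96
#'   by 0.05.
#' @param oneAtATime if `TRUE`, ignore `grid` and instead remove taxa one at
#'   a time in order of increasing weighted degree (lexicographic
#'   tie-break), recording the loss after each removal; the `quantile`
#'   column then holds the removal rank.
#' @return a [LossProfile-class] object.
#' @examples
#' lossProfile(adjustedMI(simulateCommunity(communitySpec(seed = 1))))
#' @export
lossProfile <- function(adj, grid = seq(0.01, 0.96, by = 0.05),
                        oneAtATime = FALSE) {
  v <- if (is(adj, "AdjustedMI")) adjacency(adj) else adj
  d <- weightedDegrees(v)
  total <- sum(v^2)
  ids <- colnames(v)
  if (oneAtATime) {
    ord <- d$ordering
    lam <- numeric(length(ord))
    retained <- vector("list", length(ord))
    for (k in seq_along(ord)) {
      keep <- setdiff(ids, ord[seq_len(k)])
      retained[[k]] <- keep
      lam[k] <- 1 - sum(v[keep, keep]^2) / total
    }
    tab <- data.frame(quantile = seq_along(ord), n_removed = seq_along(ord),
                      lambda = lam, delta = c(lam[1], diff(lam)),
                      taxon = ord)
    return(new("LossProfile", table = tab, retained = retained,
               taxonIDs = ids))
  }
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0 | grid >= 1))
    stop("grid must be strictly increasing within [0, 1)")
  lam <- numeric(length(grid))
  nrem <- integer(length(grid))
  retained <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    r <- removeBelowQuantile(v, d, grid[k])
    retained[[k]] <- r$retained
    nrem[k] <- length(r$removed)
    lam[k] <- 1 - sum(r$reduced^2) / total
  }
  tab <- data.frame(quantile = grid, n_removed = nrem, lambda = lam,
                    delta = c(NA_real_, diff(lam)))
  new("LossProfile", table = tab, retained = retained, taxonIDs = ids)
}
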