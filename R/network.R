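#' Hard-threshold an adjusted-MI matrix into an unweighted network
#'
#' Applies the signum rule: taxa j and j' are connected iff their adjusted
#' mutual information is at least `tau` (inclusive). The diagonal is 1 by the
#' adjacency conditions but never contributes to node degrees.
#'
#' @param adj an [AdjustedMI-class] object (or a symmetric [0,1] matrix with
#'   unit diagonal).
#' @param tau threshold in [0, 1].
#' @return an [MINetwork-class] object.
#' @examples
#' a <- adjustedMI(simulateNullTable(60, 5, seed = 1))
#' hardThreshold(a, 0.2)
#' @export
hardThreshold <- function(adj, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("tau must be a single value in [0, 1]")
  v <- if (is(adj, "AdjustedMI")) adjacency(adj) else adj
  a <- (v >= tau) + 0
  diag(a) <- 1
  deg <- as.integer(rowSums(a) - 1L)
  names(deg) <- colnames(v)
  new("MINetwork", adjacency = a, tau = tau, degrees = deg)
}

#' Empirical degree distribution of an unweighted network
#'
#' @param net an [MINetwork-class] object.
#' @return data.frame with columns `k` (distinct observed degrees) and `p`
#'   (fraction of nodes with that degree); `p` sums to 1.
#' @examples
#' net <- hardThreshold(adjustedMI(simulateNullTable(60, 5, seed = 1)), 0)
#' degreeDistribution(net)
#' @export
degreeDistribution <- function(net) {
  deg <- degrees(net)
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)),
             p = as.numeric(tab) / length(deg))
}

#' Fit a power law to a degree distribution
#'
#' Scale-free topology check: ordinary least squares of `log p(k)` on
#' `log k` (a power law \eqn{P(k) \sim k^{-\gamma}} is linear only in
#' log-log coordinates). Degree-zero nodes cannot enter the fit and are
#' excluded from it, though not from mean connectivity. At least two distinct
#' positive degrees are required; otherwise the fit is flagged undefined.
#'
#' @param dist data.frame `(k, p)` from [degreeDistribution()].
#' @return list with `slope` (of the log-log regression), `gamma`
#'   (`abs(slope)`, the exponent magnitude), `intercept`, `r_squared`,
#'   `n_points` (distinct degrees used), and `defined` (logical). With
#'   exactly two points the fit is exact (`r_squared = 1`) and `n_points`
#'   flags the low support.
#' @examples
#' fitPowerLaw(data.frame(k = c(1, 2, 4, 8), p = c(1, 2, 4, 8)^-2 / 1.328125))
#' @export
fitPowerLaw <- function(dist) {
  use <- dist$k >= 1 & dist$p > 0
  kk <- dist$k[use]; pp <- dist$p[use]
  if (length(kk) < 2L)
    return(list(slope = NA_real_, gamma = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n_points = length(kk), defined = FALSE))
  fit <- lm(log(pp) ~ log(kk))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log(pp) - mean(log(pp)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  slope <- unname(fit$coefficients[2L])
  list(slope = slope, gamma = abs(slope),
       intercept = unname(fit$coefficients[1L]),
       r_squared = r2, n_points = length(kk), defined = TRUE)
}

#' Scan hard thresholds for scale-free topology
#'
#' Thresholds the adjusted-MI matrix at every value of `grid`, fits the
#' power-law degree distribution, and selects the threshold with the highest
#' R squared; exact ties are broken by larger mean connectivity so the
#' network keeps as much information as possible. Thresholds whose fit is
#' undefined (fewer than two distinct positive degrees) are excluded from
#' selection.
#'
#' @param adj an [AdjustedMI-class] object.
#' @param grid candidate thresholds in [0, 1]; default 0.05 to 0.95 by 0.05.
#' @return a [ThresholdScan-class] object.
#' @examples
#' a <- adjustedMI(simulateCommunity(communitySpec(seed = 1)))
#' scanThresholds(a)
#' @export
scanThresholds <- function(adj, grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(grid) == 0L || any(grid < 0 | grid > 1))
    stop("grid must be non-empty with values in [0, 1]")
  rows <- lapply(grid, function(tau) {
    net <- hardThreshold(adj, tau)
    f <- fitPowerLaw(degreeDistribution(net))
    data.frame(tau = tau, r_squared = f$r_squared,
               mean_k = mean(degrees(net)), slope = f$slope,
               gamma = f$gamma, n_points = f$n_points)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$r_squared)
  if (!any(ok))
    stop("power-law fit undefined at every threshold; ",
         "try a denser grid or a different discretization")
  cand <- tab[ok, ]
  best_r2 <- max(cand$r_squared)
  ties <- cand[abs(cand$r_squared - best_r2) < 1e-12, ]
  sel <- ties$tau[which.max(ties$mean_k)]
  new("ThresholdScan", table = tab, selectedTau = sel)
}

#' Partition taxa into connected (kept) and isolated (removed)
#'
#' Isolated nodes (degree zero) share no information with any other taxon
#' and are flagged as putative contaminants; all other taxa are kept. The two
#' sets partition the taxa exactly.
#'
#' @param net an [MINetwork-class] object built at the selected threshold.
#' @return list with character vectors `kept` and `removed`.
#' @examples
#' a <- adjustedMI(simulateCommunity(communitySpec(seed = 1)))
#' isolatedTaxa(hardThreshold(a, 0.3))
#' @export
isolatedTaxa <- function(net) {
  deg <- degrees(net)
  removed <- names(deg)[deg == 0L]
  kept <- names(deg)[deg > 0L]
  if (length(kept) == 0L)
    warning("all taxa are isolated at this threshold; everything removed")
  list(kept = kept, removed = removed)
}
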