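.filter_report <- function(method, table, kept, labels = NULL) {
  m <- ncol(counts(table))
  ids <- taxonIDs(table)
  out <- list(method = method, n_preserved = length(kept),
              n_removed = m - length(kept),
              percent_filtered = 100 * (m - length(kept)) / m,
              percent_contamination_preserved = NA_real_,
              retained = kept)
  if (!is.null(labels)) {
    labels <- .check_labels(labels, ids)
    contam <- ids[!labels]
    out$percent_contamination_preserved <-
      if (length(contam)) 100 * sum(kept %in% contam) / length(contam) else 0
  }
  structure(out, class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("%s: %d taxa preserved (%.1f%% filtered)", x$method,
              x$n_preserved, x$percent_filtered))
  if (!is.na(x$percent_contamination_preserved))
    cat(sprintf("; %.1f%% of contamination preserved",
                x$percent_contamination_preserved))
  cat("\n")
  invisible(x)
}

# labels: named logical (TRUE = true taxon), or character "true"/"contaminant"
.check_labels <- function(labels, ids) {
  if (is.character(labels)) {
    lv <- tolower(labels)
    if (!all(lv %in% c("true", "contaminant")))
      stop("labels must be 'true' or 'contaminant'")
    labels <- stats::setNames(lv == "true", names(labels))
  }
  if (is.null(names(labels))) {
    if (length(labels) != length(ids))
      stop("unnamed labels must match the number of taxa")
    names(labels) <- ids
  }
  if (!all(ids %in% names(labels)))
    stop("labels missing for taxa: ",
         paste(utils::head(setdiff(ids, names(labels)), 5), collapse = ", "))
  labels[ids]
}

.rel_abund <- function(cnt) {
  tot <- rowSums(cnt)
  if (any(tot == 0)) {
    warning("excluding ", sum(tot == 0),
            " all-zero sample(s) from relative-abundance computation")
    cnt <- cnt[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(cnt, 1, tot, "/")
}

#' Traditional filter 1: per-sample relative abundance
#'
#' Retains taxa whose relative abundance exceeds `threshold` (strictly) in at
#' least one sample. Commonly applied at 0.1%, 1% or 5%.
#'
#' @param table an [MICountTable-class] object.
#' @param threshold relative-abundance cutoff in (0, 1).
#' @param labels optional ground-truth labels (named logical, TRUE = true
#'   taxon, or character `"true"`/`"contaminant"`).
#' @return a `FilterReport` list: method, n_preserved, n_removed,
#'   percent_filtered, percent_contamination_preserved, retained IDs.
#' @examples
#' filterByRelAbund(simulateCommunity(communitySpec(seed = 1)), 0.01)
#' @export
filterByRelAbund <- function(table, threshold = 0.01, labels = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ra <- .rel_abund(counts(table))
  kept <- colnames(ra)[apply(ra, 2, max) > threshold]
  .filter_report(sprintf("rel_abund>%g%%", 100 * threshold), table, kept,
                 labels)
}

#' Traditional filter 2: minimum reads in minimum samples
#'
#' Retains taxa with at least `minReads` reads in at least `minSamples`
#' samples (both boundaries inclusive).
#'
#' @inheritParams filterByRelAbund
#' @param minReads,minSamples inclusive count and sample thresholds.
#' @return a `FilterReport` list.
#' @export
filterByCounts <- function(table, minReads = 5, minSamples = 3,
                           labels = NULL) {
  cnt <- counts(table)
  kept <- colnames(cnt)[colSums(cnt >= minReads) >= minSamples]
  .filter_report(sprintf("reads>=%d_in>=%d", minReads, minSamples), table,
                 kept, labels)
}

#' Traditional filter 3: prevalence
#'
#' Retains taxa present (nonzero) in strictly more than `minSamples` samples.
#'
#' @inheritParams filterByRelAbund
#' @param minSamples strict prevalence threshold (taxa in exactly
#'   `minSamples` samples are removed).
#' @return a `FilterReport` list.
#' @export
filterByPrevalence <- function(table, minSamples = 5, labels = NULL) {
  cnt <- counts(table)
  kept <- colnames(cnt)[colSums(cnt > 0) > minSamples]
  .filter_report(sprintf("prevalence>%d", minSamples), table, kept, labels)
}

#' Traditional filter 4: sample depth, then taxon totals and prevalence
#'
#' First removes samples with fewer than `minSampleReads` total reads, then —
#' on the reduced table — removes taxa with fewer than `minTaxonReads` total
#' reads and taxa present in fewer than `minPrevalence` (a fraction) of the
#' remaining samples. The sample filter is applied first because it changes
#' the taxon statistics.
#'
#' @inheritParams filterByRelAbund
#' @param minSampleReads sample-depth cutoff (strict, samples below removed).
#' @param minTaxonReads taxon total-read cutoff (strict).
#' @param minPrevalence prevalence fraction cutoff (strict).
#' @return a `FilterReport` list.
#' @export
filterByDepthAndCounts <- function(table, minSampleReads = 100,
                                   minTaxonReads = 10, minPrevalence = 0.01,
                                   labels = NULL) {
  cnt <- counts(table)
  cnt <- cnt[rowSums(cnt) >= minSampleReads, , drop = FALSE]
  if (nrow(cnt) == 0L) stop("all samples removed by the depth filter")
  keep <- colSums(cnt) >= minTaxonReads &
    colSums(cnt > 0) >= minPrevalence * nrow(cnt)
  .filter_report("depth+counts+prevalence", table, colnames(cnt)[keep],
                 labels)
}

#' ROC analysis of network-based taxon classification
#'
#' At each threshold `tau` a taxon is predicted to be a true community member
#' iff it is non-isolated (degree >= 1) in the unweighted network at `tau`;
#' this is exactly the pipeline's filtering rule, so the curve traces its
#' operating points as `tau` varies. TPF and FPF are computed against the
#' ground-truth labels and the AUC by the trapezoid rule. Because
#' non-isolation at `tau` is equivalent to a taxon's strongest adjusted-MI
#' edge reaching `tau`, the curve coincides with the ROC of that
#' maximum-edge score.
#'
#' @param adj an [AdjustedMI-class] object or symmetric matrix.
#' @param labels ground-truth labels (named logical, TRUE = true taxon, or
#'   character `"true"`/`"contaminant"`).
#' @param grid thresholds; defaults to all distinct off-diagonal values plus
#'   the endpoints, which yields the exact step curve.
#' @return list with `points` (data.frame tau, fpf, tpf) and `auc`.
#' @examples
#' tab <- simulateCommunity(communitySpec(seed = 1))
#' rocAnalysis(adjustedMI(tab), attr(tab, "labels"))$auc
#' @export
rocAnalysis <- function(adj, labels, grid = NULL) {
  v <- if (is(adj, "AdjustedMI")) adjacency(adj) else adj
  ids <- colnames(v)
  labels <- .check_labels(labels, ids)
  if (all(labels) || !any(labels))
    stop("labels contain a single class; AUC is undefined")
  score <- apply(v - diag(diag(v)), 1, max)  # strongest off-diagonal edge
  if (is.null(grid))
    grid <- sort(unique(c(0, score, 1, max(score) + 1e-9)))
  pts <- t(vapply(grid, function(tau) {
    pred <- score >= tau
    c(fpf = mean(pred[!labels]), tpf = mean(pred[labels]))
  }, numeric(2)))
  ord <- order(pts[, "fpf"], pts[, "tpf"])
  fpf <- c(0, pts[ord, "fpf"], 1)
  tpf <- c(0, pts[ord, "tpf"], 1)
  auc <- sum(diff(fpf) * (utils::head(tpf, -1) + utils::tail(tpf, -1)) / 2)
  list(points = data.frame(tau = grid, fpf = pts[, "fpf"],
                           tpf = pts[, "tpf"]),
       auc = auc)
}

#' Side-by-side comparison of filtering methods
#'
#' Runs the four traditional filters (filter 1 at each requested
#' relative-abundance threshold) and the full MI-network pipeline on the same
#' table and tabulates taxa preserved, percent filtered and — when labels are
#' given — percent of contamination preserved.
#'
#' @param table an [MICountTable-class] object.
#' @param labels optional ground-truth labels.
#' @param relAbundThresholds thresholds for the relative-abundance filter.
#' @param methods subset of `c("rel_abund", "counts", "prevalence",
#'   "depth", "mi")`.
#' @param scheme,tauGrid settings forwarded to the MI pipeline.
#' @return list with `report` (one data.frame row per method) and `retained`
#'   (list of retained taxon-ID vectors).
#' @examples
#' tab <- simulateCommunity(communitySpec(seed = 1))
#' comparisonReport(tab, attr(tab, "labels"))$report
#' @export
comparisonReport <- function(table, labels = NULL,
                             relAbundThresholds = c(0.001, 0.01, 0.05),
                             methods = c("rel_abund", "counts", "prevalence",
                                         "depth", "mi"),
                             scheme = discretizationScheme(),
                             tauGrid = seq(0.05, 0.95, by = 0.05)) {
  methods <- match.arg(methods, several.ok = TRUE)
  reps <- list()
  if ("rel_abund" %in% methods)
    for (th in relAbundThresholds)
      reps <- c(reps, list(filterByRelAbund(table, th, labels)))
  if ("counts" %in% methods)
    reps <- c(reps, list(filterByCounts(table, labels = labels)))
  if ("prevalence" %in% methods)
    reps <- c(reps, list(filterByPrevalence(table, labels = labels)))
  if ("depth" %in% methods)
    reps <- c(reps, list(filterByDepthAndCounts(table, labels = labels)))
  if ("mi" %in% methods) {
    fit <- miFilter(table, scheme = scheme, tauGrid = tauGrid)
    reps <- c(reps, list(.filter_report("MI-network", table, fit$kept,
                                        labels)))
  }
  report <- do.call(rbind, lapply(reps, function(r)
    data.frame(method = r$method, n_preserved = r$n_preserved,
               n_removed = r$n_removed,
               percent_filtered = r$percent_filtered,
               percent_contamination_preserved =
                 r$percent_contamination_preserved)))
  list(report = report,
       retained = stats::setNames(lapply(reps, `[[`, "retained"),
                                  report$method))
}
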