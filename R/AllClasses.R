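#' @import methods
#' @importFrom stats cov lm quantile rbinom rmultinom rnbinom rnorm runif var
#' @importFrom utils count.fields read.delim write.table head
#' @useDynLib MIFilter, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.check_count_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    return("counts must be a numeric matrix")
  if (anyNA(x))
    return("counts must not contain NA")
  if (any(x < 0))
    return("counts must be nonnegative")
  if (any(abs(x - round(x)) > 1e-8))
    return("counts must be integral")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    return("counts must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(x)))
    return("duplicate sample IDs")
  if (anyDuplicated(colnames(x)))
    return("duplicate taxon IDs")
  TRUE
}

#' MICountTable: a samples x taxa abundance matrix
#'
#' Container for an ASV/OTU count table. Rows are samples, columns are taxa;
#' entries are nonnegative integer read counts. Row and column names are the
#' sample and taxon identifiers and must be unique.
#'
#' @slot counts nonnegative integer matrix, samples in rows, taxa in columns.
#' @aliases MICountTable-class
#' @exportClass MICountTable
setClass("MICountTable", slots = c(counts = "matrix"),
         validity = function(object) .check_count_matrix(object@counts))

#' Construct an MICountTable
#'
#' @param counts numeric matrix of nonnegative integer counts, samples x taxa
#'   (use [readCountTable()] for files laid out taxa-as-rows).
#' @param sampleIDs,taxonIDs optional character vectors overriding the
#'   dimnames of `counts`; generated as `S1..Sn` / `T1..Tm` when absent.
#' @return an [MICountTable-class] object.
#' @examples
#' tab <- MICountTable(matrix(rpois(20, 5), 5, 4))
#' counts(tab)[1:2, 1:2]
#' @export
MICountTable <- function(counts, sampleIDs = NULL, taxonIDs = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!is.null(sampleIDs)) rownames(counts) <- sampleIDs
  if (!is.null(taxonIDs)) colnames(counts) <- taxonIDs
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("T", seq_len(ncol(counts)))
  counts <- round(counts)
  new("MICountTable", counts = counts)
}

#' AdjustedMI: normalized mutual-information adjacency
#'
#' Symmetric m x m matrix of pairwise mutual information between discretized
#' taxon profiles, each entry divided by the pair's joint entropy so that
#' values lie in [0, 1] with a unit diagonal (the three network-adjacency
#' conditions). Marginal entropies, joint entropies and raw MI (all in nats)
#' are kept alongside.
#'
#' @slot values m x m adjusted-MI matrix in [0, 1], unit diagonal.
#' @slot entropies per-taxon Shannon entropy (nats).
#' @slot jointEntropies m x m pairwise joint entropies (nats).
#' @slot mi m x m raw mutual information (nats); diagonal holds entropies.
#' @slot nBins number of occupied-capable bins used per taxon.
#' @slot method discretization method used.
#' @aliases AdjustedMI-class
#' @exportClass AdjustedMI
setClass("AdjustedMI",
         slots = c(values = "matrix", entropies = "numeric",
                   jointEntropies = "matrix", mi = "matrix",
                   nBins = "integer", method = "character"),
         validity = function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (is.null(colnames(v))) return("values must carry taxon IDs")
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) return("entries outside [0, 1]")
  if (max(abs(v - t(v))) > 1e-12) return("matrix not symmetric")
  if (max(abs(diag(v) - 1)) > 1e-12) return("diagonal must be 1")
  TRUE
})

#' MINetwork: hard-thresholded unweighted taxon network
#'
#' Binary adjacency obtained by thresholding an [AdjustedMI-class] matrix at
#' a cutoff tau (inclusive, signum rule). The diagonal is set to 1 by the
#' adjacency conditions but never counted in node degrees.
#'
#' @slot adjacency binary m x m matrix, unit diagonal.
#' @slot tau the hard threshold in [0, 1].
#' @slot degrees named integer vector of off-diagonal node degrees.
#' @aliases MINetwork-class
#' @exportClass MINetwork
setClass("MINetwork",
         slots = c(adjacency = "matrix", tau = "numeric", degrees = "integer"),
         validity = function(object) {
  a <- object@adjacency
  if (!all(a %in% c(0, 1))) return("adjacency must be binary")
  if (max(abs(a - t(a))) > 0) return("adjacency not symmetric")
  if (object@tau < 0 || object@tau > 1) return("tau must lie in [0, 1]")
  deg <- as.integer(rowSums(a) - diag(a))
  if (!identical(deg, unname(object@degrees)))
    return("degrees inconsistent with adjacency")
  TRUE
})

#' ThresholdScan: scale-free fit across a grid of thresholds
#'
#' One row per candidate threshold with the log-log power-law fit statistics
#' (R squared, slope, estimated exponent) and mean connectivity; the selected
#' threshold maximizes R squared, ties broken by larger mean connectivity.
#'
#' @slot table data.frame with columns tau, r_squared, mean_k, slope, gamma,
#'   n_points.
#' @slot selectedTau the chosen threshold.
#' @aliases ThresholdScan-class
#' @exportClass ThresholdScan
setClass("ThresholdScan",
         slots = c(table = "data.frame", selectedTau = "numeric"))

#' LossProfile: Frobenius information loss along a quantile grid
#'
#' For each quantile of the weighted connectivity degrees, records how many
#' taxa fall below it, the information loss Lambda of the reduced adjusted-MI
#' matrix, and the step difference Delta.
#'
#' @slot table data.frame with columns quantile, n_removed, lambda, delta.
#' @slot retained list of retained taxon-ID vectors, one per grid point.
#' @slot taxonIDs taxon IDs of the full matrix.
#' @aliases LossProfile-class
#' @exportClass LossProfile
setClass("LossProfile",
         slots = c(table = "data.frame", retained = "list",
                   taxonIDs = "character"))
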