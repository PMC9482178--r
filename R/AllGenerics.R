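#' @importFrom BiocGenerics counts
NULL

#' Accessors for MIFilter classes
#'
#' `counts()` returns the samples x taxa count matrix; `sampleIDs()` and
#' `taxonIDs()` the identifiers; `adjacency()` the (weighted or binary)
#' adjacency matrix; `degrees()` the node degrees of an unweighted network;
#' `networkTau()` its threshold; `selectedTau()` the threshold chosen by a
#' scan; `scanTable()` and `lossTable()` the underlying data frames;
#' `retainedSets()` the per-quantile retained taxon sets.
#'
#' @param object an MIFilter S4 object.
#' @return the slot contents described above.
#' @name accessors
#' @aliases counts,MICountTable-method sampleIDs taxonIDs adjacency degrees
#'   networkTau selectedTau scanTable lossTable retainedSets
NULL

#' @rdname accessors
#' @export
setMethod("counts", "MICountTable", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setMethod("sampleIDs", "MICountTable", function(object) rownames(object@counts))

#' @rdname accessors
#' @export
setGeneric("taxonIDs", function(object) standardGeneric("taxonIDs"))
#' @rdname accessors
#' @export
setMethod("taxonIDs", "MICountTable", function(object) colnames(object@counts))
#' @rdname accessors
#' @export
setMethod("taxonIDs", "AdjustedMI", function(object) colnames(object@values))
#' @rdname accessors
#' @export
setMethod("taxonIDs", "MINetwork", function(object) colnames(object@adjacency))
#' @rdname accessors
#' @export
setMethod("taxonIDs", "LossProfile", function(object) object@taxonIDs)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "AdjustedMI", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("adjacency", "MINetwork", function(object) object@adjacency)

#' @rdname accessors
#' @export
setGeneric("degrees", function(object) standardGeneric("degrees"))
#' @rdname accessors
#' @export
setMethod("degrees", "MINetwork", function(object) object@degrees)

#' @rdname accessors
#' @export
setGeneric("networkTau", function(object) standardGeneric("networkTau"))
#' @rdname accessors
#' @export
setMethod("networkTau", "MINetwork", function(object) object@tau)

#' @rdname accessors
#' @export
setGeneric("selectedTau", function(object) standardGeneric("selectedTau"))
#' @rdname accessors
#' @export
setMethod("selectedTau", "ThresholdScan", function(object) object@selectedTau)

#' @rdname accessors
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))
#' @rdname accessors
#' @export
setMethod("scanTable", "ThresholdScan", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("lossTable", function(object) standardGeneric("lossTable"))
#' @rdname accessors
#' @export
setMethod("lossTable", "LossProfile", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("retainedSets", function(object) standardGeneric("retainedSets"))
#' @rdname accessors
#' @export
setMethod("retainedSets", "LossProfile", function(object) object@retained)

setMethod("show", "MICountTable", function(object) {
  cat("MICountTable:", nrow(object@counts), "samples x",
      ncol(object@counts), "taxa\n")
  cat("  total reads:", format(sum(object@counts), big.mark = ","), "\n")
})

setMethod("show", "AdjustedMI", function(object) {
  m <- ncol(object@values)
  off <- object@values[upper.tri(object@values)]
  cat("AdjustedMI:", m, "taxa (", object@method, "discretization )\n")
  cat(sprintf("  off-diagonal range: [%.3f, %.3f]\n", min(off), max(off)))
})

setMethod("show", "MINetwork", function(object) {
  deg <- object@degrees
  cat(sprintf("MINetwork: %d taxa at tau = %.3g\n", length(deg), object@tau))
  cat(sprintf("  edges: %d; mean degree: %.3f; isolated: %d\n",
              sum(deg) / 2, mean(deg), sum(deg == 0)))
})

setMethod("show", "ThresholdScan", function(object) {
  cat("ThresholdScan over", nrow(object@table), "thresholds\n")
  cat(sprintf("  selected tau = %.3g\n", object@selectedTau))
})

setMethod("show", "LossProfile", function(object) {
  cat("LossProfile over", nrow(object@table), "quantiles\n")
  print(head(object@table, 4))
})

#' Subset an MICountTable
#'
#' @param x an MICountTable.
#' @param i,j sample and taxon indices.
#' @param drop ignored (always FALSE).
#' @param ... ignored.
#' @return an MICountTable restricted to the given samples/taxa.
#' @export
setMethod("[", "MICountTable", function(x, i, j, ..., drop = FALSE) {
  MICountTable(x@counts[i, j, drop = FALSE])
})

#' @describeIn MICountTable dimensions (samples, taxa).
#' @param x an MICountTable.
#' @export
setMethod("dim", "MICountTable", function(x) dim(x@counts))
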