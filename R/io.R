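#' Read a count table from TSV, CSV or BIOM
#'
#' TSV/CSV files must have a header row of taxon IDs and a first column of
#' sample IDs (or the transpose, with `taxaAsRows = TRUE`; the table is
#' always returned samples x taxa). BIOM files are read through the
#' \pkg{biomformat} package (observations-as-rows, i.e. taxa-as-rows,
#' as the format prescribes).
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"biom"`; default guessed from the
#'   file extension.
#' @param taxaAsRows set `TRUE` when rows are taxa and columns samples
#'   (ignored for BIOM, which is always observations-as-rows).
#' @return an [MICountTable-class] object.
#' @export
readCountTable <- function(path, format = c("auto", "tsv", "csv", "biom"),
                           taxaAsRows = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", biom = "biom", "tsv")
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    mat <- as(biomformat::biom_data(b), "matrix")
    return(.validate_read(t(mat), path))
  }
  sep <- if (format == "csv") "," else "\t"
  nf <- count.fields(path, sep = sep, quote = "\"")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("malformed row in ", path, ": line ", bad + 0L, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- ids
  if (taxaAsRows) mat <- t(mat)
  .validate_read(mat, path)
}

.validate_read <- function(mat, path) {
  if (!is.numeric(mat))
    stop("non-numeric entries in ", path)
  bad <- which(mat < 0 | abs(mat - round(mat)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count in ", path, " at sample '",
         rownames(mat)[bad[1L, 1L]], "', taxon '", colnames(mat)[bad[1L, 2L]],
         "' (value ", mat[bad[1L, , drop = FALSE]], ")")
  MICountTable(mat)
}

#' Write a count table as TSV/CSV
#'
#' Samples as rows, taxa as columns, header line of taxon IDs, first column
#' `sample_id`. Round-trips through [readCountTable()].
#'
#' @param table an [MICountTable-class] object.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(table, path, sep = "\t") {
  cnt <- counts(table)
  df <- data.frame(sample_id = rownames(cnt), cnt, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as an edge-list TSV
#'
#' Columns `source`, `target`, `weight`. For a weighted [AdjustedMI-class]
#' matrix, edges with weight above `cutoff` (default 0: all positive) are
#' written; for an [MINetwork-class], all edges with weight 1.
#'
#' @param x an [AdjustedMI-class] or [MINetwork-class] object.
#' @param path output path.
#' @param cutoff minimum weight for inclusion (weighted input only).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(x, path, cutoff = 0) {
  v <- adjacency(x)
  ut <- upper.tri(v)
  idx <- which(ut & v > cutoff, arr.ind = TRUE)
  df <- data.frame(source = rownames(v)[idx[, 1L]],
                   target = colnames(v)[idx[, 2L]],
                   weight = v[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' @param x an [AdjustedMI-class] (weighted) or [MINetwork-class]
#'   (unweighted) object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(x, path) {
  v <- adjacency(x)
  diag(v) <- 0
  g <- igraph::graph_from_adjacency_matrix(v, mode = "undirected",
                                           weighted = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read ground-truth taxon labels
#'
#' Two-column TSV (`taxon_id`, `label`) with labels `true` or `contaminant`.
#'
#' @param path file path.
#' @return named character vector of labels.
#' @export
readTaxonLabels <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs two columns: taxon_id, label")
  lab <- tolower(df[[2L]])
  if (!all(lab %in% c("true", "contaminant")))
    stop("labels must be 'true' or 'contaminant'")
  stats::setNames(lab, as.character(df[[1L]]))
}

#' Write ground-truth taxon labels
#'
#' @param labels named character vector (`true`/`contaminant`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTaxonLabels <- function(labels, path) {
  write.table(data.frame(taxon_id = names(labels), label = unname(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Bundles the pipeline settings: tau grid 0.05--0.95 by 0.05, quantile grid
#' 0.01--0.96 by 0.05, M = B = 500 resamples, alpha = 0.05, Sturges
#' equal-width discretization.
#'
#' @param ... overrides for any field.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(...) {
  cfg <- list(method = "equal_width", bins = "sturges",
              tau_grid = seq(0.05, 0.95, by = 0.05),
              quantile_grid = seq(0.01, 0.96, by = 0.05),
              M = 500, B = 500, alpha = 0.05, seed = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}

#' Write run metadata (configuration and versions) as JSON
#'
#' Embeds the exact configuration and package/R versions in every artifact's
#' sidecar so a run can be reproduced from it, seed included.
#'
#' @param config a [runConfig()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunMetadata <- function(config, path) {
  meta <- list(config = unclass(config),
               package = as.character(utils::packageVersion("MIFilter")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
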