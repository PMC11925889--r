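#' Validate and construct a feature-by-sample count table
#'
#' A count table is an ordinary numeric matrix with features as rows and
#' samples as columns, unique row and column names, and non-negative integer
#' entries. All analysis functions in the package accept such matrices; this
#' constructor centralises validation so malformed inputs fail early with a
#' precise message.
#'
#' @param counts Numeric matrix, features x samples, with dimnames.
#' @param round_counts If \code{TRUE}, non-integer numeric entries are rounded
#'   to the nearest integer instead of being rejected.
#' @return The validated integer-mode matrix (features x samples).
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 5, 4), nrow = 3,
#'             dimnames = list(paste0("ASV", 1:3), c("s1", "s2")))
#' count_table(m)
#' @export
count_table <- function(counts, round_counts = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  dup_f <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(counts))
    stop("counts must not contain missing values")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  nonint <- abs(counts - round(counts)) > 1e-8
  if (any(nonint)) {
    if (round_counts) {
      counts <- round(counts)
    } else {
      idx <- which(nonint, arr.ind = TRUE)
      stop(sprintf(
        "non-integer count at feature '%s', sample '%s' (use round_counts = TRUE to round)",
        rownames(counts)[idx[1, 1]], colnames(counts)[idx[1, 2]]))
    }
  }
  if (nrow(counts) < 1L) stop("count table needs at least one feature")
  if (ncol(counts) < 2L) stop("count table needs at least two samples")
  storage.mode(counts) <- "double"
  counts
}

#' Read a feature-by-sample count table from TSV
#'
#' Expects a tab-separated file with a header row and a leading id column.
#' The default orientation follows the common QIIME2 export dialect
#' (features as rows); set \code{orientation = "samples_as_rows"} to
#' transpose on read.
#'
#' @param path Path to a tab-separated file.
#' @param orientation Either \code{"features_as_rows"} (default) or
#'   \code{"samples_as_rows"}.
#' @param round_counts Passed to \code{\link{count_table}}.
#' @return Validated count matrix (features x samples).
#' @export
read_count_table <- function(path,
                             orientation = c("features_as_rows", "samples_as_rows"),
                             round_counts = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table file needs an id column plus data columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count table: ", path)
  rownames(m) <- ids
  if (orientation == "samples_as_rows") m <- t(m)
  count_table(m, round_counts = round_counts)
}

#' Write a count table to TSV
#'
#' @param counts Count matrix (features x samples).
#' @param path Output path.
#' @param id_column Name of the leading id column in the header.
#' @export
write_count_table <- function(counts, path, id_column = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample-to-group mapping)
#'
#' @param path Tab-separated file with a header; first column holds sample
#'   ids unless \code{sample_col} is given.
#' @param group_col Name of the column holding the group label.
#' @param sample_col Name of the column holding sample ids (default: first).
#' @return A data.frame with columns \code{sample_id} and \code{group}
#'   (factor). Group sizes are attached as attribute \code{"group_sizes"}.
#' @export
read_metadata <- function(path, group_col = "group", sample_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("metadata needs at least a sample and a group column")
  if (is.null(sample_col)) sample_col <- colnames(df)[1L]
  if (!group_col %in% colnames(df))
    stop("group column '", group_col, "' not found in ", path)
  sample_metadata(data.frame(sample_id = as.character(df[[sample_col]]),
                             group = df[[group_col]],
                             stringsAsFactors = FALSE))
}

#' Validate sample metadata
#'
#' @param meta data.frame with columns \code{sample_id} and \code{group}.
#' @return The validated data.frame, \code{group} coerced to factor, with a
#'   \code{"group_sizes"} attribute.
#' @export
sample_metadata <- function(meta) {
  if (!all(c("sample_id", "group") %in% colnames(meta)))
    stop("metadata must have columns 'sample_id' and 'group'")
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup))
    stop("sample listed more than once in metadata: ", paste(dup, collapse = ", "))
  if (anyNA(meta$group) || any(!nzchar(as.character(meta$group))))
    stop("missing group value for sample(s): ",
         paste(meta$sample_id[is.na(meta$group) | !nzchar(as.character(meta$group))],
               collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$group <- factor(meta$group)
  attr(meta, "group_sizes") <- table(meta$group)
  meta
}

#' Align metadata to the samples of a count table
#'
#' @param counts Count (or relative-abundance) matrix, samples as columns.
#' @param meta Metadata data.frame.
#' @return Metadata rows reordered to match \code{colnames(counts)}.
#' @export
join_metadata <- function(counts, meta) {
  meta <- sample_metadata(meta)
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  out <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  out$group <- droplevels(out$group)
  attr(out, "group_sizes") <- table(out$group)
  rownames(out) <- NULL
  out
}

#' Read a trait panel (behavior / physiology measurements)
#'
#' Missing values are permitted in traits and handled pairwise-complete in
#' downstream correlations.
#'
#' @param path Tab-separated file; first column sample ids, remaining columns
#'   numeric traits.
#' @return data.frame with \code{sample_id} plus numeric trait columns.
#' @export
read_traits <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  for (j in seq_along(df)[-1L]) {
    if (!is.numeric(df[[j]])) stop("trait column '", colnames(df)[j], "' is not numeric")
    if (any(!is.finite(df[[j]]) & !is.na(df[[j]])))
      stop("non-finite value in trait column '", colnames(df)[j], "'")
  }
  df
}

#' Write a trait panel to TSV
#' @param traits data.frame with a \code{sample_id} column.
#' @param path Output path.
#' @export
write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a co-occurrence network
#'
#' Writes either a tab-separated edge list (source, target, rho, p, q) or a
#' GraphML file carrying node attributes (centralities, module id, abundance
#' class) alongside the edge weights.
#'
#' @param net A \code{cooccurrence_network} (see \code{\link{build_network}}).
#' @param path Output path.
#' @param format \code{"edge_list_tsv"} or \code{"graphml"}.
#' @export
write_network <- function(net, path, format = c("edge_list_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "cooccurrence_network"))
  if (format == "edge_list_tsv") {
    edges <- net$edges[, c("from", "to", "rho", "p", "q"), drop = FALSE]
    colnames(edges) <- c("source", "target", "rho", "p", "q")
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a co-occurrence network to an igraph object
#' @param net A \code{cooccurrence_network}.
#' @return An undirected igraph graph with node and edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

#' Read a run configuration file (YAML key/value)
#' @param path Path to a YAML file.
#' @return Named list of parameters.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a run configuration file
#' @param config Named list.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (|rho| >= %g, %s-adjusted p < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$params$rho_min,
              x$params$correction, x$params$alpha))
  invisible(x)
}
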