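# Flat-text interchange: abundance tables (taxa rows x sample columns),
# metadata/soil tables, square distance matrices and Gephi-importable edge
# lists, all as TSV.

#' Write / read an abundance table as TSV
#'
#' The on-disk layout is taxa in rows and samples in columns (the common
#' ASV-table orientation), with the taxon id in the first column.
#'
#' @param table An [abundance_table()].
#' @param path File path.
#' @param metadata_path Optional path for the metadata TSV.
#' @return `write_abundance_tsv`: invisibly, `path`.
#' @export
write_abundance_tsv <- function(table, path, metadata_path = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  out <- data.frame(taxon_id = colnames(table$counts),
                    t(table$counts), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path) && !is.null(table$metadata)) {
    write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @return `read_abundance_tsv`: an [abundance_table()].
#' @export
read_abundance_tsv <- function(path, metadata_path = NULL) {
  raw <- read.delim(path, check.names = FALSE)
  counts <- t(as.matrix(raw[, -1, drop = FALSE]))
  colnames(counts) <- raw[[1]]
  md <- if (!is.null(metadata_path)) read.delim(metadata_path) else NULL
  abundance_table(counts, md)
}

#' Write a square distance matrix as TSV
#'
#' @param dm Square matrix with dimnames.
#' @param path File path.
#' @export
write_distance_tsv <- function(dm, path) {
  out <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network's edge list as TSV (source, target, r, sign, p)
#'
#' The format a graph tool (e.g. Gephi) imports directly.
#'
#' @param net A [build_network()] result.
#' @param path File path.
#' @export
write_edge_list_tsv <- function(net, path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  e <- igraph::as_data_frame(net$graph, what = "edges")
  names(e)[1:2] <- c("source", "target")
  write.table(e[, c("source", "target", "r", "sign", "p")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
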