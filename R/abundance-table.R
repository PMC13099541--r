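# AbundanceTable: samples x taxa integer count matrix + per-sample metadata.

#' Construct an abundance table
#'
#' The central container of the package: a samples-by-taxa matrix of
#' non-negative integer counts (ASV counts, or counts aggregated to any
#' taxonomic level) with a per-sample metadata table.
#'
#' @param counts Numeric matrix, samples in rows, taxa in columns,
#'   non-negative integers. Row and column names are required and must be
#'   unique.
#' @param metadata Optional data.frame with a `sample_id` column matching
#'   `rownames(counts)`; typically carries `density`, `depth`, `replicate`.
#' @return An object of class `"abundance_table"`.
#' @export
abundance_table <- function(counts, metadata = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must have sample (row) and taxon (column) names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("sample and taxon names must be unique")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata)) stop("metadata needs `sample_id`")
    if (!setequal(metadata$sample_id, rownames(counts))) {
      stop("metadata sample_ids must match count matrix rows")
    }
    metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(counts = counts, metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$counts), "samples x",
      ncol(x$counts), "taxa;",
      if (is.null(x$metadata)) "no metadata" else "with metadata", "\n")
  invisible(x)
}

#' Subset an abundance table
#'
#' @param x An [abundance_table()].
#' @param samples,taxa Character, integer or logical indices; `NULL` keeps all.
#' @return The subsetted [abundance_table()].
#' @export
subset_abundance <- function(x, samples = NULL, taxa = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(taxa)) counts <- counts[, taxa, drop = FALSE]
  md <- x$metadata
  if (!is.null(md)) md <- md[md$sample_id %in% rownames(counts), , drop = FALSE]
  abundance_table(counts, md)
}
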