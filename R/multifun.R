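# Soil multifunctionality: min-max normalization, averaging (M) and
# threshold (T) indices over the seven function variables.

#' The default seven soil-function variables
#'
#' Nutrient pools (SOC, TN), available nutrient pools (AN, NN) and the key
#' biochemical process rates (URE, PHO, NR).
#' @export
FUNCTION_VARIABLES <- c("SOC", "TN", "AN", "NN", "URE", "PHO", "NR")

#' Min-max normalize a function table to \[0, 1\]
#'
#' Per variable: `(x - min) / (max - min)`, bounds computed across all
#' samples. A constant variable is mapped to all zeros with a warning (the
#' variable stays in the set, keeping the index denominator fixed).
#'
#' @param ftable Data.frame or matrix of samples x function variables
#'   (non-negative values); extra non-numeric columns are rejected.
#' @param variables Columns to normalize; default [FUNCTION_VARIABLES]
#'   intersected with the available columns, or all columns.
#' @return Numeric matrix in `[0, 1]` with attribute `bounds` (per-variable
#'   min and max used).
#' @export
minmax_normalize <- function(ftable, variables = NULL) {
  ftable <- as.data.frame(ftable)
  if (is.null(variables)) {
    variables <- if (all(FUNCTION_VARIABLES %in% names(ftable))) {
      FUNCTION_VARIABLES
    } else names(ftable)
  }
  missing_v <- setdiff(variables, names(ftable))
  if (length(missing_v)) {
    stop("missing function variable(s): ", paste(missing_v, collapse = ", "))
  }
  x <- as.matrix(ftable[, variables, drop = FALSE])
  if (!is.numeric(x)) stop("function variables must be numeric")
  if (nrow(x) < 2) stop("min-max normalization needs at least 2 samples")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  constant <- hi == lo
  if (any(constant)) {
    warning("constant variable(s) normalized to 0: ",
            paste(variables[constant], collapse = ", "))
  }
  norm <- sweep(sweep(x, 2, lo), 2, ifelse(constant, 1, hi - lo), "/")
  norm[, constant] <- 0
  rownames(norm) <- rownames(ftable)
  attr(norm, "bounds") <- data.frame(variable = variables, min = lo, max = hi,
                                     row.names = NULL)
  norm
}

#' Averaging multifunctionality index (M-index)
#'
#' Arithmetic mean of the normalized function variables per sample.
#'
#' @param normalized Matrix from [minmax_normalize()].
#' @param variables Optional subset of columns; all must be present.
#' @return Named numeric vector in `[0, 1]`.
#' @export
m_index <- function(normalized, variables = NULL) {
  if (is.null(variables)) variables <- colnames(normalized)
  missing_v <- setdiff(variables, colnames(normalized))
  if (length(missing_v)) {
    stop("missing function variable(s): ", paste(missing_v, collapse = ", "))
  }
  rowMeans(normalized[, variables, drop = FALSE])
}

#' Threshold multifunctionality index (T-index)
#'
#' Per variable the cutoff is `quantile` times the maximum normalized value
#' over samples (0.7 of a non-degenerate min-max column, i.e. 0.7). The
#' index is the proportion of variables strictly exceeding their cutoff
#' (ties at the cutoff do not count; with `quantile = 1` no value exceeds
#' the maximum, so T = 0).
#'
#' @param normalized Matrix from [minmax_normalize()].
#' @param quantile Threshold fraction of the per-variable maximum
#'   (default 0.7).
#' @param variables Optional subset of columns.
#' @return Named numeric vector in `{0, 1/k, ..., 1}` for k variables.
#' @export
t_index <- function(normalized, quantile = 0.7, variables = NULL) {
  if (is.null(variables)) variables <- colnames(normalized)
  missing_v <- setdiff(variables, colnames(normalized))
  if (length(missing_v)) {
    stop("missing function variable(s): ", paste(missing_v, collapse = ", "))
  }
  x <- normalized[, variables, drop = FALSE]
  cutoff <- quantile * apply(x, 2, max)
  rowMeans(sweep(x, 2, cutoff, ">"))
}

#' Per-sample multifunctionality scores
#'
#' Convenience wrapper: normalize, then compute M and T.
#'
#' @param ftable Samples x variables table (e.g. columns of a
#'   [generate_soil_table()] output).
#' @param variables Function variables; default [FUNCTION_VARIABLES].
#' @param quantile T-index threshold fraction (default 0.7).
#' @param sample_ids Optional ids (default rownames of `ftable`).
#' @return Data.frame of class `"multifun_scores"`: `sample_id`, `M_index`,
#'   `T_index`; attribute `bounds` holds the normalization bounds.
#' @export
multifun_scores <- function(ftable, variables = FUNCTION_VARIABLES,
                            quantile = 0.7, sample_ids = NULL) {
  norm <- minmax_normalize(ftable, variables)
  if (is.null(sample_ids)) sample_ids <- rownames(norm)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(norm)))
  out <- data.frame(sample_id = sample_ids,
                    M_index = unname(m_index(norm)),
                    T_index = unname(t_index(norm, quantile)),
                    stringsAsFactors = FALSE)
  attr(out, "bounds") <- attr(norm, "bounds")
  attr(out, "quantile") <- quantile
  class(out) <- c("multifun_scores", "data.frame")
  out
}

#' Group summary of multifunctionality scores
#'
#' Mean and sd of M and T per density-by-depth cell, in long format.
#'
#' @param scores A [multifun_scores()] data.frame.
#' @param metadata Data.frame with `sample_id`, `density`, `depth`.
#' @return Long data.frame: `density`, `depth`, `index`, `mean`, `sd`, `n`.
#'   Design cells absent from the data are reported as `NA` with a warning.
#' @export
multifun_response <- function(scores, metadata) {
  m <- merge(as.data.frame(scores), metadata, by = "sample_id")
  if (nrow(m) == 0) stop("scores and metadata share no sample ids")
  cells <- unique(metadata[, c("density", "depth")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- m[m$density == cells$density[i] & m$depth == cells$depth[i], ]
    if (nrow(sub) == 0) {
      warning("empty cell: ", cells$density[i], "/", cells$depth[i])
      return(data.frame(density = cells$density[i], depth = cells$depth[i],
                        index = c("M_index", "T_index"),
                        mean = NA_real_, sd = NA_real_, n = 0L))
    }
    data.frame(density = cells$density[i], depth = cells$depth[i],
               index = c("M_index", "T_index"),
               mean = c(mean(sub$M_index), mean(sub$T_index)),
               sd = c(sd(sub$M_index), sd(sub$T_index)),
               n = nrow(sub))
  }))
  rownames(out) <- NULL
  out
}
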