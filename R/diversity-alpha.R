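# Alpha diversity: rarefaction, Good's coverage and the classical
# richness/diversity estimators, implemented from their definitions.

#' Rarefy an abundance table to equal depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' total counts (a single draw, not an average over draws). Samples whose
#' total is below `depth` are dropped with a message; a sample whose total
#' equals `depth` is returned unchanged.
#'
#' @param table An [abundance_table()].
#' @param depth Target total count per sample; the conventional default is
#'   20000 reads.
#' @param seed Integer seed for the subsampling.
#' @return A rarefied [abundance_table()].
#' @export
rarefy_counts <- function(table, depth = 20000L, seed = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0) stop("depth must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  totals <- rowSums(table$counts)
  drop <- totals < depth
  if (any(drop)) {
    message("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(rownames(table$counts)[drop], collapse = ", "))
  }
  keep <- which(!drop)
  if (length(keep) == 0L) stop("no sample reaches the rarefaction depth")
  counts <- table$counts[keep, , drop = FALSE]
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    if (sum(x) == depth) next
    reads <- rep.int(seq_along(x), x)
    counts[i, ] <- tabulate(sample(reads, depth), nbins = length(x))
  }
  md <- table$metadata
  if (!is.null(md)) md <- md[md$sample_id %in% rownames(counts), , drop = FALSE]
  abundance_table(counts, md)
}

#' Good's coverage per sample
#'
#' Coverage = 1 - F1/N where F1 is the number of singleton taxa (count
#' exactly 1) and N the sample's total count. Empty samples yield `NA` with
#' a warning.
#'
#' @param table An [abundance_table()].
#' @return Named numeric vector in `[0, 1]`.
#' @export
goods_coverage <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  apply(table$counts, 1, function(x) {
    n <- sum(x)
    if (n == 0) {
      warning("empty sample: coverage undefined")
      return(NA_real_)
    }
    1 - sum(x == 1) / n
  })
}

chao1_estimator <- function(x) {
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1)) # bias-corrected form
}

ace_estimator <- function(x, rare_cutoff = 10) {
  x <- x[x > 0]
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  if (n_rare == 0) return(s_abund)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE undefined: all rare taxa are singletons")
    return(NA_real_)
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  g2 <- max(s_rare / c_ace * sum(seq_len(rare_cutoff) *
                                   (seq_len(rare_cutoff) - 1) * fi) /
              (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

shannon_index <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Alpha diversity indices per sample
#'
#' Estimators, computed from integer counts per sample:
#' \describe{
#'   \item{observed}{number of taxa with count > 0}
#'   \item{chao1}{bias-corrected Chao1, `S + F1(F1-1)/(2(F2+1))`}
#'   \item{ace}{abundance-based coverage estimator, rare cutoff 10}
#'   \item{shannon}{`-sum p_i ln p_i` (natural log)}
#'   \item{simpson}{Gini-Simpson `1 - sum p_i^2` (higher = more diverse);
#'     set `simpson_form = "dominance"` for `sum p_i^2`}
#'   \item{pielou}{Shannon / ln(observed); `NA` for single-taxon samples}
#' }
#'
#' @param table An [abundance_table()] of integer counts.
#' @param metrics Character vector of metric names (any of the above).
#' @param simpson_form `"gini"` (default) or `"dominance"`.
#' @return Data.frame: `sample_id`, one column per metric.
#' @export
alpha_diversity <- function(table,
                            metrics = c("observed", "chao1", "ace",
                                        "shannon", "simpson", "pielou"),
                            simpson_form = c("gini", "dominance")) {
  stopifnot(inherits(table, "abundance_table"))
  simpson_form <- match.arg(simpson_form)
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- data.frame(sample_id = rownames(table$counts),
                    stringsAsFactors = FALSE)
  fx <- list(
    observed = function(x) sum(x > 0),
    chao1 = chao1_estimator,
    ace = ace_estimator,
    shannon = shannon_index,
    simpson = function(x) {
      p <- x / sum(x)
      d <- sum(p^2)
      if (simpson_form == "gini") 1 - d else d
    },
    pielou = function(x) {
      s <- sum(x > 0)
      if (s < 2) {
        warning("Pielou evenness undefined for single-taxon sample")
        return(NA_real_)
      }
      shannon_index(x) / log(s)
    }
  )
  for (m in metrics) out[[m]] <- apply(table$counts, 1, fx[[m]])
  out
}
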