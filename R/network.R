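# Co-occurrence network construction: prevalence filter, pairwise Spearman
# correlations with a two-sided t-approximation p, |r|/p thresholding, and
# topology summaries in the Gephi conventions.

#' Edge rule for co-occurrence network construction
#'
#' @param r_threshold Edge requires `|r| >` this (strict); default 0.6.
#' @param p_threshold Edge requires `p <` this (strict); default 0.05.
#' @param prevalence_fraction Taxa must be present (count > 0) in at least
#'   this fraction of samples before correlation; default 0.8.
#' @param p_adjust `"none"` (default: raw per-pair p-values) or `"BH"`
#'   for Benjamini-Hochberg adjustment across pairs before thresholding.
#' @return List of class `"edge_rule"`.
#' @export
edge_rule <- function(r_threshold = 0.6, p_threshold = 0.05,
                      prevalence_fraction = 0.8,
                      p_adjust = c("none", "BH")) {
  stopifnot(r_threshold > 0, r_threshold <= 1,
            p_threshold > 0, p_threshold <= 1,
            prevalence_fraction > 0, prevalence_fraction <= 1)
  structure(list(r_threshold = r_threshold, p_threshold = p_threshold,
                 prevalence_fraction = prevalence_fraction,
                 p_adjust = match.arg(p_adjust)),
            class = "edge_rule")
}

#' Prevalence filter
#'
#' Keeps taxa with nonzero counts in at least `ceiling(fraction * n_samples)`
#' samples ("at least" makes the boundary inclusive: 8 of 10 samples passes
#' a 0.8 filter).
#'
#' @param table An [abundance_table()].
#' @param fraction Required prevalence fraction in (0, 1].
#' @return The filtered [abundance_table()]; empty result gives a warning.
#' @export
prevalence_filter <- function(table, fraction = 0.8) {
  stopifnot(inherits(table, "abundance_table"),
            fraction > 0, fraction <= 1)
  need <- ceiling(fraction * nrow(table$counts))
  keep <- colSums(table$counts > 0) >= need
  if (!any(keep)) warning("prevalence filter removed every taxon")
  abundance_table(table$counts[, keep, drop = FALSE], table$metadata)
}

#' Pairwise Spearman correlation and p-value matrices
#'
#' Tie-aware Spearman r (Pearson correlation of mid-ranks) for every taxon
#' pair, with two-sided p-values from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df. For small n an exact
#' permutation p-value over all `n!` orderings is available. Constant taxa
#' yield `NA` correlations (never edges).
#'
#' @param table An [abundance_table()] (taxa in columns).
#' @param method Only `"spearman"` is implemented.
#' @param p_method `"t"` (default) or `"exact"` (full permutation
#'   distribution; only for n <= 8).
#' @return List with matrices `r` and `p` (diagonal r = 1, p = 0).
#' @export
correlation_matrix <- function(table, method = "spearman",
                               p_method = c("t", "exact")) {
  stopifnot(inherits(table, "abundance_table"))
  method <- match.arg(method, "spearman")
  p_method <- match.arg(p_method)
  x <- table$counts
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples for correlation")
  constant <- apply(x, 2, function(v) length(unique(v)) == 1)
  r <- suppressWarnings(cor(x, method = "spearman"))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- ifelse(constant, NA_real_, 1)
  if (p_method == "exact") {
    if (n > 8) stop("exact permutation p only supported for n <= 8")
    perms <- all_permutations(n)
    p <- matrix(NA_real_, ncol(x), ncol(x), dimnames = dimnames(r))
    for (i in seq_len(ncol(x))) {
      for (j in seq_len(ncol(x))) {
        if (i == j || is.na(r[i, j])) next
        ri <- rank(x[, i]); rj <- rank(x[, j])
        robs <- abs(r[i, j])
        rs <- apply(perms, 1, function(p_) abs(cor(ri, rj[p_])))
        p[i, j] <- mean(rs >= robs - 1e-12)
      }
    }
    diag(p)[!constant] <- 0
  } else {
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    diag(p) <- ifelse(constant, NA_real_, 0)
  }
  list(r = r, p = p)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Build a co-occurrence network from correlation matrices
#'
#' An undirected edge links taxa i and j iff `|r| > r_threshold` AND
#' `p < p_threshold` (both strict, so r exactly at the threshold is not an
#' edge). Edge sign is the sign of r. Isolated nodes are dropped by default
#' (matching an edge-list import into a graph tool); set
#' `keep_isolated = TRUE` to retain every filtered taxon as a node.
#'
#' @param r,p Conformable square matrices from [correlation_matrix()].
#' @param rule An [edge_rule()].
#' @param group Optional label for the network (e.g. "VHD/0-20/bacteria").
#' @param keep_isolated Keep degree-0 nodes? Default `FALSE`.
#' @return Object of class `"cooccurrence_network"`: list with `graph`
#'   (igraph, edge attributes `r`, `p`, `sign`), `rule`, `group`.
#' @export
build_network <- function(r, p, rule = edge_rule(), group = NULL,
                          keep_isolated = FALSE) {
  r <- as.matrix(r); p <- as.matrix(p)
  if (!all(dim(r) == dim(p))) stop("r and p matrices must be conformable")
  if (rule$p_adjust == "BH") {
    pv <- p[upper.tri(p)]
    pv <- stats::p.adjust(pv, "BH")
    p[upper.tri(p)] <- pv
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  idx <- which(upper.tri(r) & !is.na(r) & !is.na(p) &
                 abs(r) > rule$r_threshold & p < rule$p_threshold,
               arr.ind = TRUE)
  taxa <- colnames(r)
  if (is.null(taxa)) taxa <- as.character(seq_len(ncol(r)))
  edges <- data.frame(from = taxa[idx[, 1]], to = taxa[idx[, 2]],
                      r = r[idx], p = p[idx],
                      sign = ifelse(r[idx] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  vertices <- if (keep_isolated) data.frame(name = taxa) else NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  structure(list(graph = g, rule = rule, group = group),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("co-occurrence network",
      if (!is.null(x$group)) paste0("[", x$group, "]"), ":",
      igraph::vcount(x$graph), "nodes,", igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Topological properties of a co-occurrence network
#'
#' Computes the standard summary: node/edge counts, positive and negative
#' edge counts, average degree `2E/N`, density `2E/(N(N-1))`, average path
#' length (mean shortest path over connected pairs, i.e. within
#' components), diameter (max shortest path over components), clustering
#' coefficient (mean local clustering, nodes of degree < 2 contributing 0 —
#' the Gephi convention; `clustering = "global"` switches to transitivity),
#' and Louvain modularity on the unweighted sign-ignored graph under a
#' fixed seed.
#'
#' @param net A [build_network()] result (or a bare igraph).
#' @param modularity_seed Seed for the Louvain run.
#' @param clustering `"local_average"` (default) or `"global"`.
#' @return One-row data.frame of class `"topology_summary"`.
#' @export
topology <- function(net, modularity_seed = 1L,
                     clustering = c("local_average", "global")) {
  clustering <- match.arg(clustering)
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n < 2) stop("network must have at least 2 nodes")
  e <- igraph::ecount(g)
  signs <- igraph::edge_attr(g, "sign")
  pos <- if (is.null(signs)) NA_integer_ else sum(signs == "+")
  neg <- if (is.null(signs)) NA_integer_ else sum(signs == "-")
  gu <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  apl <- igraph::mean_distance(gu, directed = FALSE, unconnected = TRUE)
  diam <- igraph::diameter(gu, directed = FALSE, unconnected = TRUE)
  cc <- if (clustering == "global") {
    igraph::transitivity(gu, type = "global")
  } else {
    loc <- igraph::transitivity(gu, type = "local", isolates = "zero")
    mean(loc)
  }
  set.seed(modularity_seed)
  comm <- igraph::cluster_louvain(gu, weights = NA)
  mod <- igraph::modularity(gu, igraph::membership(comm))
  out <- data.frame(
    group = if (inherits(net, "cooccurrence_network") && !is.null(net$group)) {
      net$group
    } else NA_character_,
    nodes_num = n, edges_num = e,
    positive_cor_num = pos, negative_cor_num = neg,
    average_degree = 2 * e / n,
    average_path_length = apl,
    network_diameter = diam,
    network_density = 2 * e / (n * (n - 1)),
    clustering_coefficient = cc,
    modularity = mod,
    stringsAsFactors = FALSE
  )
  class(out) <- c("topology_summary", "data.frame")
  out
}

#' Derived topology metrics from printed node/edge counts
#'
#' Recomputes `average_degree = 2E/N` and `network_density = 2E/(N(N-1))`
#' from node and edge counts alone — the internal-consistency check applied
#' to published topology tables.
#'
#' @param nodes,edges Integer vectors (recycled).
#' @return Data.frame with `nodes`, `edges`, `average_degree`,
#'   `network_density`.
#' @export
derived_topology_metrics <- function(nodes, edges) {
  data.frame(nodes = nodes, edges = edges,
             average_degree = 2 * edges / nodes,
             network_density = 2 * edges / (nodes * (nodes - 1)))
}

#' Long-format comparison of topology summaries
#'
#' @param summaries List of [topology()] rows (or a data.frame of them);
#'   list names override the `group` column.
#' @return Long data.frame: `group`, `metric`, `value`, metrics preserved
#'   bit-exactly.
#' @export
compare_topologies <- function(summaries) {
  if (inherits(summaries, "data.frame")) summaries <- list(summaries)
  rows <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    s <- as.data.frame(summaries[[i]])
    if (!is.null(names(summaries)) && nzchar(names(summaries)[i])) {
      s$group <- names(summaries)[i]
    }
    s
  }))
  metrics <- setdiff(names(rows), "group")
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(group = rows$group, metric = m,
               value = as.numeric(rows[[m]]), stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
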