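# Network robustness: natural connectivity under random node removal and
# the stability slope of its decline.

as_adjacency01 <- function(graph) {
  if (inherits(graph, "cooccurrence_network")) graph <- graph$graph
  if (inherits(graph, "igraph")) {
    a <- igraph::as_adjacency_matrix(
      igraph::simplify(igraph::as_undirected(graph, mode = "collapse")),
      sparse = FALSE)
  } else {
    a <- as.matrix(graph)
    if (nrow(a) != ncol(a)) stop("adjacency must be square")
  }
  a <- (a != 0) * 1 # signs and weights ignored: binary adjacency
  diag(a) <- 0
  (a + t(a) > 0) * 1
}

#' Natural connectivity of a graph
#'
#' `ln((1/N) * sum_i exp(lambda_i))` over the eigenvalues `lambda_i` of the
#' binary (sign-ignored, unweighted) adjacency matrix: the log of the
#' average closed-walk generating function, a spectral redundancy measure
#' used as a robustness index. The empty node set is defined as 0 by
#' convention.
#'
#' @param graph An igraph, a [build_network()] result, or an adjacency
#'   matrix. Edge signs/weights are ignored.
#' @return Scalar natural connectivity.
#' @export
#' @examples
#' natural_connectivity(igraph::make_full_graph(3)) # ~0.9963
natural_connectivity <- function(graph) {
  a <- as_adjacency01(graph)
  n <- nrow(a)
  if (n == 0) return(0)
  if (n > 2000) warning("large graph (N > 2000): eigendecomposition will be ",
                        "slow; consider subsampling nodes")
  natural_connectivity_cpp(a)
}

#' Random node-removal robustness simulation
#'
#' For each removal fraction `f`, repeats `n_simulations` times: remove
#' `floor(f * N)` uniformly chosen nodes and compute the natural
#' connectivity of the remaining graph; the per-fraction mean (and sd)
#' over simulations is recorded. A fraction removing 0 nodes returns the
#' intact value; one leaving no nodes returns 0 by the empty-graph
#' convention.
#'
#' @param graph See [natural_connectivity()]; needs N >= 3.
#' @param fractions Strictly increasing removal fractions; default 1%-99%
#'   in 1% steps.
#' @param n_simulations Random removals per fraction (default 1000).
#' @param seed Integer seed (curves are bit-reproducible given it).
#' @return Object of class `"robustness_curve"`: data.frame `fraction`,
#'   `mean_nc`, `sd_nc`, with attributes `n_simulations` and `seed`.
#' @export
removal_simulation <- function(graph, fractions = seq(0.01, 0.99, by = 0.01),
                               n_simulations = 1000L, seed = NULL) {
  a <- as_adjacency01(graph)
  if (nrow(a) < 3) stop("need a graph with at least 3 nodes")
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("fractions must be strictly increasing")
  }
  if (!is.null(seed)) set.seed(seed)
  sim <- removal_simulation_cpp(a, as.numeric(fractions),
                                as.integer(n_simulations))
  out <- data.frame(fraction = as.numeric(fractions),
                    mean_nc = sim$mean_nc, sd_nc = sim$sd_nc)
  attr(out, "n_simulations") <- as.integer(n_simulations)
  attr(out, "seed") <- seed
  class(out) <- c("robustness_curve", "data.frame")
  out
}

#' Stability slope of a robustness curve
#'
#' Ordinary least-squares slope of the mean natural connectivity against
#' removal fraction over the fit range (default: the full grid). Smaller
#' `|slope|` means a flatter decline, i.e. a more stable network.
#'
#' @param curve A [removal_simulation()] result (or any data.frame with
#'   `fraction` and `mean_nc`).
#' @param fit_range Optional `c(min, max)` restricting the fractions used.
#' @return List of class `"stability_score"`: `slope` (natural-connectivity
#'   units per unit removal fraction), `intercept`, `fit_range`.
#' @export
stability_slope <- function(curve, fit_range = NULL) {
  df <- as.data.frame(curve)
  if (!is.null(fit_range)) {
    df <- df[df$fraction >= fit_range[1] & df$fraction <= fit_range[2], ]
  }
  if (nrow(df) < 3) stop("need at least 3 grid points for the slope fit")
  fit <- lm(mean_nc ~ fraction, data = df)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 fit_range = range(df$fraction)),
            class = "stability_score")
}

#' @export
print.stability_score <- function(x, ...) {
  cat("stability slope:", signif(x$slope, 5),
      "(fit over fractions", x$fit_range[1], "-", x$fit_range[2], ")\n")
  invisible(x)
}

#' Rank groups by network stability
#'
#' Sorts by ascending `|slope|` (most stable first); ties broken by a
#' stable sort on the group label.
#'
#' @param scores Named list of [stability_slope()] results (names = group
#'   labels), or a data.frame with `group` and `slope`.
#' @return Data.frame `rank`, `group`, `slope`, `abs_slope`, most stable
#'   first.
#' @export
rank_stability <- function(scores) {
  if (inherits(scores, "data.frame")) {
    df <- data.frame(group = as.character(scores$group),
                     slope = scores$slope, stringsAsFactors = FALSE)
  } else {
    if (length(scores) < 2) stop("need at least 2 scores to rank")
    df <- data.frame(group = names(scores),
                     slope = vapply(scores, function(s) s$slope, 0),
                     stringsAsFactors = FALSE)
  }
  df$abs_slope <- abs(df$slope)
  df <- df[order(df$abs_slope, df$group), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "group", "slope", "abs_slope")]
}
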