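# Small fixtures built in code.

# abundance table from a plain matrix, auto-naming samples/taxa
toy_table <- function(counts, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("t%02d", seq_len(ncol(counts)))
  }
  abundance_table(counts, metadata)
}

# random integer abundance table for property checks
random_table <- function(n_samples, n_taxa, seed, lambda = 10) {
  set.seed(seed)
  toy_table(matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa))
}

# Erdos-Renyi igraph
random_graph <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p)
}

# independent natural-connectivity oracle: plain R eigendecomposition
nc_oracle <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  a <- (a != 0) * 1
  if (nrow(a) == 0) return(0)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  log(mean(exp(ev)))
}

# independent path-product oracle for effect decomposition: recursive
# enumeration written separately from the package's implementation
oracle_total_effect <- function(edges, from, to) {
  total <- 0
  recurse <- function(node, prod) {
    hit <- edges[edges$from == node, , drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      pr <- prod * hit$coef[k]
      if (hit$to[k] == to) total <<- total + pr else recurse(hit$to[k], pr)
    }
  }
  recurse(from, 1)
  total
}

# enumerate all set partitions of 1..n (for exhaustive modularity search)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}
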