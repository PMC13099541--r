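# Beta diversity from definitions: Bray-Curtis, principal coordinates,
# PERMANOVA (pseudo-F on a distance matrix) and the Mantel test.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = 1 - 2 * sum(min(a_i, b_i)) / (sum a + sum b)`.
#'
#' @param table An [abundance_table()] (counts or relative abundances).
#' @return Square symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = sample ids.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$counts
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  totals <- rowSums(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- totals[i] + totals[j]
      if (denom == 0) stop("Bray-Curtis undefined: two empty samples")
      d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(x[i, ], x[j, ])) / denom
    }
  }
  d
}

check_distance_matrix <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || !isTRUE(all.equal(dm, t(dm), tolerance = 1e-10))) {
    stop("distance matrix must be square and symmetric")
  }
  dm
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the double-centred Gower matrix
#' `-0.5 * J D^2 J`. Axes with positive eigenvalues carry coordinates
#' `v_k * sqrt(lambda_k)`; proportion explained is relative to the sum of
#' positive eigenvalues. Negative eigenvalues (non-Euclidean distances) are
#' reported, with a warning, never silently dropped; `correction =
#' "cailliez"` adds the Cailliez constant to off-diagonal distances first.
#'
#' @param dm Square symmetric dissimilarity matrix.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return List of class `"pcoa_ordination"`: `coordinates` (samples x
#'   axes), `eigenvalues` (all, decreasing), `proportion_explained` (over
#'   positive axes), `negative_eigenvalues` (logical).
#' @export
pcoa <- function(dm, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  dm <- check_distance_matrix(dm)
  n <- nrow(dm)
  if (correction == "cailliez") {
    # smallest c making d + c Euclidean-embeddable (Cailliez 1983)
    d2 <- dm^2
    jc <- diag(n) - matrix(1 / n, n, n)
    b1 <- -0.5 * jc %*% d2 %*% jc
    b2 <- -0.5 * jc %*% dm %*% jc
    sp <- rbind(cbind(matrix(0, n, n), 2 * b1),
                cbind(-diag(n), -4 * b2))
    cc <- max(Re(eigen(sp, only.values = TRUE)$values))
    if (cc > 0) dm <- dm + cc * (1 - diag(n))
  }
  jc <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * jc %*% (dm^2) %*% jc
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  ev <- eig$values
  pos <- ev > max(abs(ev)) * 1e-12
  if (any(ev < -max(abs(ev)) * 1e-8)) {
    warning("negative eigenvalues present (non-Euclidean distances); ",
            "reported uncorrected")
  }
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), nrow = sum(pos))
  dimnames(coords) <- list(rownames(dm), paste0("Axis", seq_len(ncol(coords))))
  structure(
    list(coordinates = coords, eigenvalues = ev,
         proportion_explained = ev[pos] / sum(ev[pos]),
         negative_eigenvalues = any(ev < -max(abs(ev)) * 1e-8)),
    class = "pcoa_ordination"
  )
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  k <- min(2L, length(x$proportion_explained))
  cat("PCoA:", nrow(x$coordinates), "samples;",
      "first axes explain",
      paste0(sprintf("%.2f%%", 100 * x$proportion_explained[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

# among/within sums of squared distances for a one-way grouping
permanova_f <- function(d2, grouping, n, a) {
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA (one-way, pseudo-F on a distance matrix)
#'
#' Pseudo-F from among- versus within-group sums of squared distances, with
#' significance by free permutation of the sample labels:
#' `p = (1 + #permutations with F >= F_obs) / (1 + n_permutations)`.
#'
#' @param dm Square symmetric distance matrix.
#' @param grouping Factor-like vector, one label per sample.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed.
#' @return List of class `"permutation_test"`: `statistic` (pseudo-F),
#'   `p_value`, `n_permutations`, `seed`, `method`.
#' @export
permanova <- function(dm, grouping, n_permutations = 999L, seed = NULL) {
  dm <- check_distance_matrix(dm)
  n <- nrow(dm)
  grouping <- as.character(grouping)
  if (length(grouping) != n) stop("grouping length must match matrix size")
  tab <- table(grouping)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (length(tab) == n) stop("degenerate grouping: every sample its own group")
  if (any(tab < 2)) warning("group(s) with a single sample: ",
                            paste(names(tab)[tab < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  d2 <- dm^2
  a <- length(tab)
  f_obs <- permanova_f(d2, grouping, n, a)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    fp <- permanova_f(d2, grouping[sample.int(n)], n, a)
    if (fp >= f_obs) exceed <- exceed + 1L
  }
  structure(list(statistic = f_obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed,
                 method = "PERMANOVA (pseudo-F)"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(x$method, ": statistic =", signif(x$statistic, 5),
      ", p =", signif(x$p_value, 4),
      " (", x$n_permutations, "permutations )\n")
  invisible(x)
}

upper_tri <- function(m) m[upper.tri(m)]

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) between the upper-triangle entries of
#' two distance matrices over the same samples; the permutation null
#' shuffles rows and columns of the second matrix simultaneously. The
#' p-value is one-sided (positive association), the vegan convention.
#'
#' @param dm1,dm2 Square symmetric matrices over the same samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `"permutation_test"` list with `statistic` = Mantel r.
#' @export
mantel_test <- function(dm1, dm2, method = c("spearman", "pearson"),
                        n_permutations = 999L, seed = NULL) {
  method <- match.arg(method)
  dm1 <- check_distance_matrix(dm1)
  dm2 <- check_distance_matrix(dm2)
  n <- nrow(dm1)
  if (nrow(dm2) != n) stop("distance matrices must match in size")
  if (!is.null(seed)) set.seed(seed)
  # the off-diagonal value multiset is invariant under simultaneous
  # row/column permutation, so for Spearman the off-diagonal ranks can be
  # computed once and re-read from the permuted matrix
  rank_offdiag <- function(m) {
    v <- rank(upper_tri(m))
    r <- m
    r[upper.tri(r)] <- v
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    r
  }
  if (method == "spearman") {
    r1 <- rank_offdiag(dm1); r2 <- rank_offdiag(dm2)
  } else {
    r1 <- dm1; r2 <- dm2
  }
  v1 <- upper_tri(r1)
  r_obs <- cor(v1, upper_tri(r2))
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    if (cor(v1, upper_tri(r2[p, p])) >= r_obs) exceed <- exceed + 1L
  }
  structure(list(statistic = r_obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed,
                 method = paste0("Mantel (", method, ")")),
            class = "permutation_test")
}
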