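# Partial least squares path modeling, written from the algorithm:
# mode-A (reflective) outer estimation, centroid inner scheme by default,
# OLS structural coefficients, percentile bootstrap, and exact
# direct/indirect/total effect decomposition by path enumeration.

#' Specify a PLS path model
#'
#' @param blocks Named list: latent block name -> character vector of its
#'   manifest indicator (column) names. Every indicator belongs to exactly
#'   one block.
#' @param paths Data.frame with columns `from`, `to` giving the directed
#'   structural edges between block names; must form a DAG.
#' @param scheme Inner weighting scheme: `"centroid"` (default),
#'   `"factorial"` or `"path"`.
#' @param nboot Default bootstrap replicates for [fit_plspm()] (1000).
#' @return List of class `"path_model_spec"`.
#' @export
#' @examples
#' spec <- path_model_spec(
#'   blocks = list(density = "trees_ha", env = c("pH", "SOC"), mf = "M_index"),
#'   paths = data.frame(from = c("density", "env"), to = c("env", "mf")))
path_model_spec <- function(blocks, paths,
                            scheme = c("centroid", "factorial", "path"),
                            nboot = 1000L) {
  scheme <- match.arg(scheme)
  if (is.null(names(blocks)) || anyDuplicated(names(blocks))) {
    stop("blocks must be a uniquely named list")
  }
  ind <- unlist(blocks)
  if (anyDuplicated(ind)) {
    stop("each indicator must be assigned to exactly one block")
  }
  paths <- as.data.frame(paths)
  if (!all(c("from", "to") %in% names(paths))) stop("paths needs from/to")
  if (!all(c(paths$from, paths$to) %in% names(blocks))) {
    stop("path endpoints must be block names")
  }
  if (!is_dag(paths, names(blocks))) stop("structural paths must form a DAG")
  structure(list(blocks = blocks, paths = paths, scheme = scheme,
                 nboot = as.integer(nboot)),
            class = "path_model_spec")
}

is_dag <- function(paths, nodes) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in paths$to) indeg[v] <- indeg[v] + 1L
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  edges <- paths
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- edges$to[edges$from == v]
    edges <- edges[edges$from != v, , drop = FALSE]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(nodes)
}

std_cols <- function(x) {
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, mu)^2)) # population scaling, plspm-style
  if (any(s == 0)) stop("constant indicator column")
  sweep(sweep(x, 2, mu), 2, s, "/")
}

# one full PLS estimation on an indicator matrix (rows already selected)
plspm_core <- function(x, spec, tol = 1e-6, max_iter = 300L) {
  bn <- names(spec$blocks)
  nb <- length(bn)
  idx <- lapply(spec$blocks, function(v) match(v, colnames(x)))
  xs <- std_cols(x)
  adj <- matrix(0, nb, nb, dimnames = list(bn, bn))
  adj[cbind(match(spec$paths$from, bn), match(spec$paths$to, bn))] <- 1
  neighbor <- (adj + t(adj)) > 0

  w <- lapply(idx, function(ii) rep(1, length(ii)))
  lv <- matrix(0, nrow(xs), nb, dimnames = list(NULL, bn))
  score <- function(b, wb) {
    v <- xs[, idx[[b]], drop = FALSE] %*% wb
    v / sqrt(mean((v - mean(v))^2))
  }
  for (b in seq_len(nb)) lv[, b] <- score(b, w[[b]])

  iters <- 0L
  delta <- Inf
  repeat {
    iters <- iters + 1L
    w_old <- w
    r_lv <- cor(lv)
    z <- matrix(0, nrow(xs), nb)
    for (b in seq_len(nb)) {
      nbrs <- which(neighbor[b, ])
      if (!length(nbrs)) { z[, b] <- lv[, b]; next }
      e <- switch(spec$scheme,
        centroid = sign(r_lv[b, nbrs]),
        factorial = r_lv[b, nbrs],
        path = {
          pred <- which(adj[, b] == 1)
          succ <- which(adj[b, ] == 1)
          ee <- numeric(length(nbrs))
          if (length(pred)) {
            bet <- qr.solve(lv[, pred, drop = FALSE], lv[, b])
            ee[match(pred, nbrs)] <- bet
          }
          if (length(succ)) ee[match(succ, nbrs)] <- r_lv[b, succ]
          ee
        })
      z[, b] <- lv[, nbrs, drop = FALSE] %*% e
    }
    for (b in seq_len(nb)) {
      # mode A: outer weights = covariances of indicators with the inner
      # estimate; LV sign anchored to its first indicator
      zb <- z[, b]
      wb <- as.numeric(crossprod(xs[, idx[[b]], drop = FALSE], zb)) / length(zb)
      if (wb[1] < 0) wb <- -wb
      nrm <- sqrt(sum(wb^2))
      if (nrm == 0) stop("degenerate outer weights in block ", bn[b])
      w[[b]] <- wb / nrm
      lv[, b] <- score(b, w[[b]])
    }
    delta <- max(unlist(Map(function(a, b) max(abs(a / sqrt(sum(a^2)) -
                                                    b / sqrt(sum(b^2)))),
                            w, w_old)))
    if (delta < tol) break
    if (iters >= max_iter) {
      stop(sprintf("PLS-PM did not converge in %d iterations (last delta %.3g)",
                   max_iter, delta))
    }
  }

  coefs <- spec$paths
  coefs$coef <- NA_real_
  r2 <- setNames(rep(NA_real_, nb), bn)
  for (b in seq_len(nb)) {
    pred <- which(adj[, b] == 1)
    if (!length(pred)) next
    xb <- lv[, pred, drop = FALSE]
    bet <- qr.solve(xb, lv[, b])
    fitted <- xb %*% bet
    r2[b] <- 1 - mean((lv[, b] - fitted)^2) / mean((lv[, b] - mean(lv[, b]))^2)
    for (k in seq_along(pred)) {
      coefs$coef[coefs$from == bn[pred[k]] & coefs$to == bn[b]] <- bet[k]
    }
  }
  list(path_coefficients = coefs, r_squared = r2,
       outer_weights = w, scores = lv, iterations = iters)
}

#' Fit a PLS path model
#'
#' Indicators are standardized; outer weights start at 1 and the algorithm
#' alternates inner estimation (centroid scheme by default) with mode-A
#' outer estimation until the largest outer-weight change falls below `tol`
#' (error after `max_iter`). Latent scores are standardized and
#' sign-anchored to each block's first indicator; structural path
#' coefficients are OLS fits of each endogenous latent on its structural
#' predecessors, with an R-squared per endogenous block. When `nboot > 0`
#' the sampling distribution of every path coefficient is bootstrapped
#' (resampling rows, seeded) to give standard errors and percentile 95%
#' intervals.
#'
#' @param data Data.frame containing every indicator named in the spec.
#' @param spec A [path_model_spec()].
#' @param nboot Bootstrap replicates; defaults to the spec's `nboot`; 0
#'   skips the bootstrap.
#' @param seed Integer seed for the bootstrap.
#' @param tol,max_iter Convergence control.
#' @return List of class `"plspm_fit"`: `path_coefficients` (data.frame
#'   `from`, `to`, `coef` and, after bootstrap, `se`, `ci_lower`,
#'   `ci_upper`), `r_squared`, `iterations`, `scores`, `outer_weights`,
#'   `spec`, `nboot`.
#' @export
fit_plspm <- function(data, spec, nboot = spec$nboot, seed = NULL,
                      tol = 1e-6, max_iter = 300L) {
  stopifnot(inherits(spec, "path_model_spec"))
  data <- as.data.frame(data)
  ind <- unlist(spec$blocks)
  missing_i <- setdiff(ind, names(data))
  if (length(missing_i)) {
    stop("missing indicator column(s): ", paste(missing_i, collapse = ", "))
  }
  n_pred <- max(table(spec$paths$to))
  if (nrow(data) <= n_pred + 1) stop("too few rows for the structural model")
  x <- as.matrix(data[, ind, drop = FALSE])
  fit <- plspm_core(x, spec, tol, max_iter)
  if (nboot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- matrix(NA_real_, nboot, nrow(fit$path_coefficients))
    for (b in seq_len(nboot)) {
      rows <- sample.int(nrow(x), replace = TRUE)
      bf <- tryCatch(plspm_core(x[rows, , drop = FALSE], spec, tol, max_iter),
                     error = function(e) NULL)
      if (!is.null(bf)) boot[b, ] <- bf$path_coefficients$coef
    }
    fit$path_coefficients$se <- apply(boot, 2, sd, na.rm = TRUE)
    fit$path_coefficients$ci_lower <- apply(boot, 2, quantile, 0.025, na.rm = TRUE)
    fit$path_coefficients$ci_upper <- apply(boot, 2, quantile, 0.975, na.rm = TRUE)
  }
  fit$spec <- spec
  fit$nboot <- as.integer(nboot)
  class(fit) <- "plspm_fit"
  fit
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat("PLS path model (", x$spec$scheme, " scheme), converged in ",
      x$iterations, " iteration(s)\n", sep = "")
  print(x$path_coefficients, digits = 3)
  r2 <- x$r_squared[!is.na(x$r_squared)]
  cat("R^2:", paste(sprintf("%s = %.3f", names(r2), r2), collapse = "; "), "\n")
  invisible(x)
}

enumerate_paths <- function(edges, from, to) {
  out <- list()
  walk <- function(node, path, prod) {
    nxt <- which(edges$from == node)
    for (k in nxt) {
      v <- edges$to[k]
      pr <- prod * edges$coef[k]
      if (v == to) {
        out[[length(out) + 1]] <<- list(path = c(path, v), product = pr)
      } else {
        walk(v, c(path, v), pr)
      }
    }
  }
  walk(from, from, 1)
  out
}

#' Direct, indirect and total effect decomposition
#'
#' For every ordered block pair connected by at least one directed path:
#' the direct effect is the structural coefficient of the direct edge (0 if
#' absent), each indirect effect is the product of coefficients along one
#' multi-edge path, the total effect is direct plus the sum of indirect
#' effects, and the indirect share is the summed indirect effect over the
#' total.
#'
#' @param x A [fit_plspm()] result, or a data.frame of edges with columns
#'   `from`, `to`, `coef` (a DAG).
#' @return List of class `"effect_decomposition"`: `effects` (data.frame
#'   `from`, `to`, `direct`, `indirect`, `total`, `indirect_share`) and
#'   `paths` (per-path products, `path` strings like "a -> b -> c").
#' @export
effect_decomposition <- function(x) {
  edges <- if (inherits(x, "plspm_fit")) {
    x$path_coefficients[, c("from", "to", "coef")]
  } else {
    as.data.frame(x)[, c("from", "to", "coef")]
  }
  nodes <- unique(c(edges$from, edges$to))
  if (!is_dag(edges, nodes)) stop("effect decomposition requires a DAG")
  eff <- NULL
  paths_tab <- NULL
  for (a in nodes) {
    for (b in setdiff(nodes, a)) {
      pl <- enumerate_paths(edges, a, b)
      if (!length(pl)) next
      lens <- vapply(pl, function(p) length(p$path), 0L)
      prods <- vapply(pl, function(p) p$product, 0)
      direct <- sum(prods[lens == 2])
      indirect <- sum(prods[lens > 2])
      eff <- rbind(eff, data.frame(
        from = a, to = b, direct = direct, indirect = indirect,
        total = direct + indirect,
        indirect_share = if (direct + indirect != 0) {
          indirect / (direct + indirect)
        } else NA_real_,
        stringsAsFactors = FALSE))
      paths_tab <- rbind(paths_tab, data.frame(
        from = a, to = b,
        path = vapply(pl, function(p) paste(p$path, collapse = " -> "), ""),
        product = prods, stringsAsFactors = FALSE))
    }
  }
  structure(list(effects = eff, paths = paths_tab),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  print(x$effects, digits = 3)
  invisible(x)
}
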