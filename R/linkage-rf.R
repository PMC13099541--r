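# Linking network properties to multifunctionality: predictor assembly,
# random-forest permutation importance (%IncMSE), the stability regression
# and the stability median split.

#' Assemble a per-plot predictor matrix
#'
#' Inner join of any number of per-plot feature tables (alpha-diversity
#' summaries, composition summaries, topology metrics, stability slopes)
#' with the response, on shared key columns. Plots dropped by the join are
#' reported.
#'
#' @param response Data.frame holding the key columns and the response.
#' @param ... Further data.frames, each holding the key columns plus
#'   feature columns with unique names.
#' @param keys Join keys; default `"plot"` (use e.g. `c("plot", "depth")`).
#' @return Data.frame: keys, response column(s), then all features; error
#'   if the join is empty.
#' @export
assemble_predictors <- function(response, ..., keys = "plot") {
  tabs <- list(...)
  out <- as.data.frame(response)
  for (tb in tabs) {
    tb <- as.data.frame(tb)
    if (!all(keys %in% names(tb))) {
      stop("table lacks key column(s): ", paste(keys, collapse = ", "))
    }
    before <- do.call(paste, out[keys])
    out <- merge(out, tb, by = keys)
    dropped <- setdiff(before, do.call(paste, out[keys]))
    if (length(dropped)) {
      message("dropped by join: ", paste(dropped, collapse = ", "))
    }
    if (nrow(out) == 0) {
      stop("empty join; no shared plots (lost: ",
           paste(head(dropped, 10), collapse = ", "), ")")
    }
  }
  if (anyDuplicated(names(out))) stop("predictor names must be unique")
  out
}

#' Random-forest permutation importance (%IncMSE)
#'
#' Fits a random-forest regressor (randomForest) and computes, per
#' predictor, the percent increase in out-of-bag mean squared error when
#' that predictor's column is permuted: for each tree the OOB MSE is
#' evaluated with the original and the permuted column, and the per-tree
#' percent increases are averaged. Model fit is reported as the OOB
#' R-squared.
#'
#' @param data Data.frame of predictors plus the response column.
#' @param response Name of the response column.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed (forest growth and the permutation).
#' @return List of class `"importance_ranking"`: `importance` (data.frame
#'   `predictor`, `pct_inc_mse`, sorted decreasing), `r_squared`,
#'   `n_trees`, `seed`.
#' @export
rf_importance <- function(data, response = "M_index", n_trees = 500L,
                          seed = NULL) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) stop("response column not found: ", response)
  if (nrow(data) < 10) stop("need at least 10 rows")
  y <- data[[response]]
  if (var(y) == 0) stop("constant response")
  x <- data[, setdiff(names(data), response), drop = FALSE]
  x <- x[, vapply(x, is.numeric, TRUE), drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = n_trees,
                                   keep.inbag = TRUE, keep.forest = TRUE)
  oob <- rf$inbag == 0 # n x ntree
  pred <- predict(rf, x, predict.all = TRUE)$individual
  mse0 <- colSums((y - pred)^2 * oob) / colSums(oob)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    xp <- x
    xp[[j]] <- xp[[j]][sample.int(nrow(xp))]
    pj <- predict(rf, xp, predict.all = TRUE)$individual
    msej <- colSums((y - pj)^2 * oob) / colSums(oob)
    ok <- mse0 > 0
    mean(100 * (msej[ok] - mse0[ok]) / mse0[ok])
  }, 0)
  ranking <- data.frame(predictor = names(x), pct_inc_mse = imp,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$pct_inc_mse), ]
  rownames(ranking) <- NULL
  structure(list(importance = ranking,
                 r_squared = 1 - mean((y - rf$predicted)^2) / mean((y - mean(y))^2),
                 n_trees = as.integer(n_trees), seed = seed),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("random-forest importance (OOB R^2 =", signif(x$r_squared, 3), "):\n")
  print(head(x$importance, 10))
  invisible(x)
}

#' Regression of multifunctionality on network stability
#'
#' Ordinary least squares of the response on the stability score, with the
#' usual t-based slope p-value.
#'
#' @param stability,multifun Numeric vectors of equal length (>= 3).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
stability_regression <- function(stability, multifun) {
  if (length(stability) != length(multifun)) stop("length mismatch")
  if (length(stability) < 3) stop("need at least 3 points")
  if (var(stability) == 0) stop("zero variance in the stability scores")
  fit <- lm(multifun ~ stability)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]), n = length(stability))
}

#' Compare multifunctionality across a stability median split
#'
#' Converts slopes to stability scores (`-|slope|`, larger = more stable),
#' splits at the median (scores at or above the median fall in the
#' high-stability group), and summarizes the response per density x depth x
#' stability group.
#'
#' @param slopes Numeric vector of stability slopes per plot.
#' @param multifun Numeric response per plot.
#' @param metadata Data.frame with `density` and `depth` per plot.
#' @return List: `table` (long summary: density, depth, stability_group,
#'   mean, sd, n) and `scores` (per-plot stability score and group).
#' @export
stability_median_split <- function(slopes, multifun, metadata) {
  if (length(slopes) < 4) stop("need at least 4 plots")
  score <- -abs(slopes) # larger = more stable
  if (length(unique(score)) == 1) stop("degenerate split: all scores equal")
  med <- stats::median(score)
  group <- ifelse(score >= med, "high_stability", "low_stability")
  df <- data.frame(metadata, multifun = multifun, score = score,
                   stability_group = group, stringsAsFactors = FALSE)
  tab <- aggregate(multifun ~ density + depth + stability_group, df,
                   function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  tab <- cbind(tab[, c("density", "depth", "stability_group")],
               as.data.frame(tab$multifun))
  names(tab)[4:6] <- c("mean", "sd", "n")
  list(table = tab, scores = df)
}
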