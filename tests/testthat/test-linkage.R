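test_that("predictor assembly inner-joins on keys and passes values through", {
  resp <- data.frame(plot = c("p1", "p2", "p3"), M_index = c(0.2, 0.5, 0.8))
  topo <- data.frame(plot = c("p1", "p2", "p3"), edges = c(10, 20, 30))
  div <- data.frame(plot = c("p2", "p3", "p4"), shannon = c(1.1, 2.2, 3.3))
  pm <- suppressMessages(assemble_predictors(resp, topo, div))
  expect_equal(pm$plot, c("p2", "p3"))
  expect_equal(ncol(pm), 4) # keys + response + 2 features
  expect_identical(pm$edges, c(20, 30))
  expect_identical(pm$shannon, c(1.1, 2.2))
  bad <- data.frame(plot = c("q1", "q2"), z = 1:2)
  expect_error(suppressMessages(assemble_predictors(resp, bad)), "empty join")
})

test_that("%IncMSE ranks a planted predictor first and stays a permutation", {
  set.seed(2)
  n <- 200
  x <- as.data.frame(matrix(rnorm(n * 10), n))
  names(x) <- paste0("x", 1:10)
  x$y <- 5 * x$x1 + rnorm(n)
  for (s in c(1, 2, 3)) {
    imp <- rf_importance(x, "y", n_trees = 300, seed = s)
    expect_equal(imp$importance$predictor[1], "x1")
    expect_setequal(imp$importance$predictor, paste0("x", 1:10))
  }
  expect_gt(imp$r_squared, 0.8)
  # duplicated predictor column: ranking is still a valid permutation
  x2 <- x; x2$x1_copy <- x2$x1
  imp2 <- rf_importance(x2, "y", n_trees = 300, seed = 1)
  expect_setequal(imp2$importance$predictor, c(paste0("x", 1:10), "x1_copy"))
  expect_true(all(c("x1", "x1_copy") %in% head(imp2$importance$predictor, 3)))
  expect_error(rf_importance(transform(x, y = 1), "y"), "constant response")
})

test_that("stability regression recovers planted lines", {
  x <- seq(-2, 2, length.out = 20)
  # a perfect fit triggers summary.lm's reliability warning; expected here
  exact <- suppressWarnings(stability_regression(x, 0.3 + 0.5 * x))
  expect_equal(exact$slope, 0.5, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)
  set.seed(3)
  xs <- rnorm(100)
  noisy <- stability_regression(xs, 1 + 0.5 * xs + rnorm(100, 0, 0.1))
  expect_equal(noisy$slope, 0.5, tolerance = 0.05)
  expect_lt(noisy$r_squared, 1)
  expect_error(stability_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("median split sends scores at/above the median to high stability", {
  md <- data.frame(density = rep(c("HD", "LD"), each = 2), depth = "0-20")
  out <- stability_median_split(c(-1, -2, -3, -4), c(0.9, 0.8, 0.3, 0.2), md)
  hi <- out$scores$stability_group == "high_stability"
  expect_setequal(which(hi), c(1, 2)) # |slope| 1,2 are the stabler plots
  # odd count: the median element lands in the high-stability group
  md5 <- data.frame(density = "HD", depth = "0-20")[rep(1, 5), ]
  out5 <- stability_median_split(-(1:5), runif(5), md5)
  expect_equal(sum(out5$scores$stability_group == "high_stability"), 3)
  # planted high-stability => high multifun shows in the summary
  expect_gt(mean(out$scores$multifun[hi]), mean(out$scores$multifun[!hi]))
  expect_error(stability_median_split(rep(1, 4), runif(4), md), "degenerate")
})

test_that("single-indicator PLS-PM equals standardized OLS and is exact when noiseless", {
  d <- study_design()
  sc <- linkage_scenario(path_coefficients = c(0.7, 0.5, 0.9), noise_sd = 0)
  ld <- generate_linked_dataset(d, sc, n = 200, seed = 4)
  spec <- path_model_spec(
    blocks = list(density = "density", env = "environment",
                  net = "network", mf = "multifun"),
    paths = data.frame(from = c("density", "env", "net"),
                       to = c("env", "net", "mf")))
  fit <- fit_plspm(ld$chain, spec, nboot = 0)
  expect_equal(unname(fit$r_squared[c("env", "net", "mf")]), rep(1, 3),
               tolerance = 1e-10)
  expect_equal(fit$path_coefficients$coef, c(1, 1, 1), tolerance = 1e-10)
  # with noise: path coefficient equals the standardized OLS slope per stage
  ld2 <- generate_linked_dataset(d, linkage_scenario(noise_sd = 0.3),
                                 n = 300, seed = 5)
  fit2 <- fit_plspm(ld2$chain, spec, nboot = 0)
  beta_ols <- unname(coef(lm(scale(ld2$chain$environment) ~
                               scale(ld2$chain$density)))[2])
  i <- which(fit2$path_coefficients$from == "density")
  expect_equal(fit2$path_coefficients$coef[i], beta_ols, tolerance = 1e-6)
})

test_that("PLS-PM recovers planted standardized paths with bootstrap CIs", {
  d <- study_design()
  sc <- linkage_scenario(path_coefficients = c(0.6, -0.9, -0.2),
                         noise_sd = 0.1)
  ld <- generate_linked_dataset(d, sc, n = 500, seed = 6)
  spec <- path_model_spec(
    blocks = list(density = "density", env = "environment",
                  net = "network", mf = "multifun"),
    paths = data.frame(from = c("density", "env", "net"),
                       to = c("env", "net", "mf")))
  fit <- fit_plspm(ld$chain, spec, nboot = 300, seed = 1)
  expect_equal(fit$path_coefficients$coef, ld$truth$std_path_coefficients,
               tolerance = 0.05)
  expect_true(all(fit$path_coefficients$ci_lower <=
                    fit$path_coefficients$coef))
  expect_true(all(fit$path_coefficients$ci_upper >=
                    fit$path_coefficients$coef))
  expect_true(all(fit$path_coefficients$se > 0))
})

test_that("multi-indicator reflective blocks recover a planted path", {
  set.seed(12)
  n <- 400
  f1 <- rnorm(n)
  f2 <- 0.8 * f1 + rnorm(n, 0, sqrt(1 - 0.64))
  mk <- function(f) sapply(1:3, function(i) 0.9 * f + rnorm(n, 0, 0.3))
  dat <- data.frame(mk(f1), mk(f2))
  names(dat) <- c(paste0("a", 1:3), paste0("b", 1:3))
  spec <- path_model_spec(
    blocks = list(A = paste0("a", 1:3), B = paste0("b", 1:3)),
    paths = data.frame(from = "A", to = "B"))
  fit <- fit_plspm(dat, spec, nboot = 0)
  # attenuated relative to 0.8 by indicator noise, but strongly positive
  expect_gt(fit$path_coefficients$coef, 0.6)
  expect_gt(fit$iterations, 1)
  expect_true(all(unlist(fit$outer_weights) > 0))
})

test_that("path model specification validates blocks and rejects cycles", {
  expect_error(path_model_spec(list(a = "x", b = "x"),
                               data.frame(from = "a", to = "b")),
               "exactly one block")
  expect_error(path_model_spec(list(a = "x", b = "y"),
                               data.frame(from = c("a", "b"), to = c("b", "a"))),
               "DAG")
})

test_that("effect decomposition is additive and matches the path oracle", {
  # single edge: total = direct, no indirect share
  one <- effect_decomposition(data.frame(from = "a", to = "b", coef = 0.4))
  expect_equal(one$effects$total, 0.4)
  expect_equal(one$effects$indirect, 0)
  expect_equal(one$effects$indirect_share, 0)
  # random DAGs: total(A->B) = direct + sum of path products, vs oracle
  set.seed(13)
  for (rep in 1:5) {
    nodes <- letters[1:5]
    edges <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    edges <- edges[match(edges$from, nodes) < match(edges$to, nodes), ]
    edges <- edges[runif(nrow(edges)) < 0.6, ]
    if (nrow(edges) == 0) next
    edges$coef <- round(runif(nrow(edges), -1, 1), 2)
    dec <- effect_decomposition(edges)
    for (k in seq_len(nrow(dec$effects))) {
      expect_equal(dec$effects$total[k],
                   oracle_total_effect(edges, dec$effects$from[k],
                                       dec$effects$to[k]),
                   tolerance = 1e-12)
      expect_equal(dec$effects$total[k],
                   dec$effects$direct[k] + dec$effects$indirect[k])
    }
  }
  cyc <- data.frame(from = c("a", "b"), to = c("b", "a"), coef = c(1, 1))
  expect_error(effect_decomposition(cyc), "DAG")
})
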