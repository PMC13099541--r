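test_that("rarefaction conserves the target depth and drops shallow samples", {
  tab <- toy_table(rbind(c(5000, 3000, 2000), c(100, 50, 20), c(700, 200, 100)))
  expect_message(rar <- rarefy_counts(tab, depth = 1000, seed = 1), "dropping")
  expect_equal(unname(rowSums(rar$counts)), c(1000, 1000))
  # a sample whose total equals the depth is returned unchanged
  exact <- toy_table(matrix(c(600, 400, 300, 700), 2, byrow = TRUE))
  out <- rarefy_counts(exact, depth = 1000, seed = 1)
  expect_equal(out$counts, exact$counts)
  expect_error(rarefy_counts(tab, depth = 0), "positive")
  # reproducible under a fixed seed
  r1 <- rarefy_counts(tab, 1000, seed = 9)
  r2 <- rarefy_counts(tab, 1000, seed = 9)
  expect_identical(r1$counts, r2$counts)
})

test_that("rarefaction default depth is 20000 and preserves proportions", {
  set.seed(5)
  x <- rmultinom(1, 60000, c(0.5, 0.3, 0.15, 0.05))[, 1]
  tab <- toy_table(matrix(x, 1))
  rar <- suppressMessages(rarefy_counts(tab, seed = 2))
  expect_equal(sum(rar$counts), 20000)
  p_pre <- x / sum(x)
  p_post <- rar$counts[1, ] / 20000
  mc <- 4 * sqrt(p_pre * (1 - p_pre) / 20000)
  expect_true(all(abs(p_post - p_pre) < pmax(mc, 0.005)))
})

test_that("Good's coverage follows 1 - F1/N", {
  expect_equal(unname(goods_coverage(toy_table(matrix(c(10, 5, 2, 0), 1)))), 1)
  expect_equal(unname(goods_coverage(toy_table(matrix(c(1, 1, 1, 1), 1)))), 0)
  expect_equal(unname(goods_coverage(toy_table(matrix(c(10, 1), 1)))), 1 - 1 / 11)
  expect_warning(cv <- goods_coverage(toy_table(matrix(c(0, 0), 1))), "empty")
  expect_true(is.na(cv))
})

test_that("alpha diversity matches closed forms on toy samples", {
  uniform <- toy_table(matrix(c(5, 5, 5, 5), 1))
  a <- alpha_diversity(uniform)
  expect_equal(a$shannon, log(4))
  expect_equal(a$pielou, 1)
  single <- toy_table(matrix(c(9, 0), 1))
  expect_warning(s <- alpha_diversity(single), "Pielou")
  expect_equal(s$simpson, 0)
  expect_true(is.na(s$pielou))
  # bias-corrected Chao1 on counts [5,2,1,1]: 4 + 2*1/(2*2) = 4.5
  expect_equal(alpha_diversity(toy_table(matrix(c(5, 2, 1, 1), 1)),
                               "chao1")$chao1, 4.5)
  # dominance form of Simpson is the complement of the Gini form
  two <- toy_table(matrix(c(3, 1), 1))
  expect_equal(alpha_diversity(two, "simpson")$simpson,
               1 - alpha_diversity(two, "simpson",
                                   simpson_form = "dominance")$simpson)
})

test_that("alpha estimators agree with vegan and satisfy their bounds", {
  skip_if_not_installed("vegan")
  tab <- random_table(8, 40, seed = 21, lambda = 4)
  a <- alpha_diversity(tab)
  expect_equal(a$shannon, unname(vegan::diversity(tab$counts)),
               tolerance = 1e-12)
  expect_equal(a$simpson, unname(vegan::diversity(tab$counts, "simpson")),
               tolerance = 1e-12)
  est <- vegan::estimateR(tab$counts)
  expect_equal(a$chao1, unname(est["S.chao1", ]), tolerance = 1e-8)
  expect_equal(a$ace, unname(est["S.ACE", ]), tolerance = 1e-8)
  # invariants
  expect_true(all(a$chao1 >= a$observed))
  expect_true(all(a$shannon >= 0 & a$shannon <= log(a$observed)))
  expect_true(all(a$simpson >= 0 & a$simpson < 1))
  expect_true(all(a$pielou >= 0 & a$pielou <= 1))
})

test_that("Bray-Curtis matches hand values, its metric properties and vegan", {
  same <- toy_table(rbind(c(3, 2, 1), c(3, 2, 1)))
  expect_equal(unname(bray_curtis(same)[1, 2]), 0)
  disjoint <- toy_table(rbind(c(5, 0), c(0, 7)))
  expect_equal(unname(bray_curtis(disjoint)[1, 2]), 1)
  hand <- toy_table(rbind(c(6, 0), c(2, 2)))
  expect_equal(unname(bray_curtis(hand)[1, 2]), 0.6)

  tab <- random_table(6, 25, seed = 31)
  d <- bray_curtis(tab)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  skip_if_not_installed("vegan")
  expect_equal(d, as.matrix(vegan::vegdist(tab$counts, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA recovers Euclidean configurations and reports axes", {
  # two samples at distance 1: one positive axis explaining all variation
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(d2)
  expect_equal(length(ord$proportion_explained), 1)
  expect_equal(ord$proportion_explained, 1)
  # Euclidean-embeddable: coordinates reproduce pairwise distances to 1e-8
  set.seed(41)
  pts <- matrix(rnorm(21), 7, 3)
  dm <- as.matrix(dist(pts))
  ord <- pcoa(dm)
  expect_false(ord$negative_eigenvalues)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - dm)), 1e-8)
  expect_true(all(diff(ord$proportion_explained) <= 1e-12))
  # duplicated sample coincides in the ordination
  dm3 <- as.matrix(dist(pts[c(1, 1, 2:5), ]))
  ord3 <- pcoa(dm3)
  expect_lt(max(abs(ord3$coordinates[1, ] - ord3$coordinates[2, ])), 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA proportions agree with classical MDS eigenvalues", {
  tab <- random_table(8, 30, seed = 51)
  dm <- bray_curtis(tab)
  ord <- suppressWarnings(pcoa(dm))
  mds <- suppressWarnings(cmdscale(as.dist(dm), k = 7, eig = TRUE))
  pos <- mds$eig[mds$eig > 1e-10]
  expect_equal(ord$proportion_explained[seq_along(pos)],
               pos / sum(pos), tolerance = 1e-8)
})

test_that("PERMANOVA pseudo-F matches vegan and is label-order invariant", {
  skip_if_not_installed("vegan")
  tab <- random_table(12, 20, seed = 61)
  grp <- rep(c("a", "b", "c"), each = 4)
  dm <- bray_curtis(tab)
  res <- permanova(dm, grp, n_permutations = 99, seed = 1)
  ad <- vegan::adonis2(as.dist(dm) ~ g, data = data.frame(g = grp),
                       permutations = 99)
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-10)
  # permuting the sample order (consistently) does not change F
  p <- sample(12)
  res2 <- permanova(dm[p, p], grp[p], n_permutations = 99, seed = 1)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
})

test_that("PERMANOVA p attains its resolution under maximal separation", {
  # a permutation reproducing the split always ties F, so group sizes are
  # chosen large enough that this is essentially impossible
  # (P ~ 2*10!10!/20! ~ 1e-5 per permutation)
  counts <- rbind(matrix(rep(c(50, 0, 10), each = 10), 10),
                  matrix(rep(c(0, 50, 10), each = 10), 10))
  tab <- toy_table(counts)
  dm <- bray_curtis(tab)
  res <- permanova(dm, rep(c("x", "y"), each = 10),
                   n_permutations = 199, seed = 2)
  expect_equal(res$p_value, 1 / 200)
  expect_warning(
    permanova(dm, c("x", rep("y", 19)), n_permutations = 9, seed = 1),
    "single sample")
  expect_error(permanova(dm, as.character(1:20), n_permutations = 9),
               "degenerate")
})

test_that("Mantel statistic behaves under identity, monotone maps and vegan", {
  tab <- random_table(9, 25, seed = 71)
  dm <- bray_curtis(tab)
  expect_equal(mantel_test(dm, dm, n_permutations = 99, seed = 1)$statistic, 1)
  # Spearman is invariant to monotone transforms
  expect_equal(mantel_test(dm, dm^2, n_permutations = 99, seed = 1)$statistic, 1)
  skip_if_not_installed("vegan")
  dm2 <- as.matrix(dist(matrix(rnorm(27), 9)))
  rownames(dm2) <- colnames(dm2) <- rownames(dm)
  ours <- mantel_test(dm, dm2, n_permutations = 199, seed = 3)
  ref <- vegan::mantel(as.dist(dm), as.dist(dm2), method = "spearman",
                       permutations = 199)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_error(mantel_test(dm, dm2[1:8, 1:8]), "match")
})
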