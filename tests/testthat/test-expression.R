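# Expression binning, two-class clustering, concordance, normalization,
# PCA and tissue fold-change ANOVA.

test_that("binning maps values onto the 0-6 scale monotonically", {
  bp <- c(0, 1, 4, 16, 64, 256, 1024)
  m <- matrix(c(0, 0.5, 3, 100, 5000), 1)
  expect_equal(as.vector(bin_expression(m, bp)), c(0L, 0L, 1L, 4L, 6L))

  set.seed(71)
  v <- matrix(runif(1000, 0, 2000), 50)
  b <- bin_expression(v, bp)
  expect_true(all(b %in% 0:6))
  # idempotence: re-binning bin-interval midpoints returns the same bin
  mids <- c((bp[-7] + bp[-1]) / 2, 2 * bp[7])
  expect_equal(as.vector(bin_expression(matrix(mids[b + 1], nrow(b)), bp)), as.vector(b))
  # monotone
  vv <- sort(runif(100, 0, 2000))
  expect_true(!is.unsorted(as.vector(bin_expression(matrix(vv, 1), bp))))

  expect_error(bin_expression(m, c(0, 2, 1, 4, 5, 6, 7)), "increasing")
  expect_error(bin_expression(m, c(1, 2, 3, 4, 5, 6, 7)), "must be 0")
})

test_that("two-class clustering separates shape-distinct classes", {
  gt <- fake_expression_truth(40, classes = rep(c("high", "low"), 20),
                              seed = 72)
  cfg <- sim_config(expression = list(lognormal_sd = 0.3))
  mats <- simulate_expression(gt, cfg, seed = 72)
  m <- mats$spX
  labels <- cluster_two_class(m)
  truth <- gt$expression_class[rownames(m)]
  expect_gte(mean(labels[names(truth)] == truth), 0.95)

  # labels invariant under row permutation
  perm <- sample(nrow(m))
  labels_p <- cluster_two_class(m[perm, ])
  expect_equal(labels_p[names(truth)], labels[names(truth)],
               ignore_attr = TRUE)

  # anti-correlated profiles land in different clusters
  m2 <- rbind(up = c(1, 10, 100, 1000), down = c(1000, 100, 10, 1))
  l2 <- cluster_two_class(m2)
  expect_true(l2["up"] != l2["down"])

  # zero-variance rows go to the low class
  m3 <- rbind(m, flat = rep(5, ncol(m)))
  l3 <- cluster_two_class(m3)
  expect_equal(unname(l3["flat"]), "low")
  expect_equal(attr(l3, "zero_variance"), "flat")

  expect_error(cluster_two_class(m2[1, , drop = FALSE]), "at least 2")
})

test_that("concordance conserves pairs and reports breakdowns", {
  la <- c(g1 = "high", g2 = "low", g3 = "high")
  lb <- c(h1 = "high", h2 = "low", h3 = "low")
  map <- data.frame(gene_a = c("g1", "g2", "g3"),
                    gene_b = c("h1", "h2", "h3"), stringsAsFactors = FALSE)
  cc <- concordance(la, lb, map,
                    categories = c(g1 = "Acetylation", g2 = "Methylation",
                                   g3 = "Acetylation"))
  expect_equal(cc$n_same, 2)
  expect_equal(cc$n_diff, 1)
  expect_equal(cc$n_same + cc$n_diff, nrow(map))
  expect_equal(unname(cc$same_by_class), c(1L, 1L))
  expect_equal(as.vector(cc$diff_by_category["Acetylation"]), 1L)

  expect_equal(concordance(la, stats::setNames(la, names(lb)), map)$n_diff, 0)
  one <- concordance(c(x = "high"), c(y = "low"),
                     data.frame(gene_a = "x", gene_b = "y"))
  expect_equal(c(one$n_same, one$n_diff), c(0, 1))
  expect_error(concordance(la, lb, data.frame(gene_a = "gX", gene_b = "h1")),
               "unlabeled")
})

test_that("swapped classes yield binomial discordance downstream", {
  set.seed(73)
  n <- 200
  cls <- sample(c("high", "low"), n, TRUE)
  swap <- runif(n) < 0.3
  cls_b <- ifelse(swap, ifelse(cls == "high", "low", "high"), cls)
  gt_a <- fake_expression_truth(n, species = "spA", classes = cls)
  gt_b <- fake_expression_truth(n, species = "spB", classes = cls_b)
  cfg <- sim_config(expression = list(lognormal_sd = 0.3))
  ma <- simulate_expression(gt_a, cfg)$spA
  mb <- simulate_expression(gt_b, cfg)$spB
  map <- data.frame(gene_a = rownames(ma), gene_b = rownames(mb))
  cc <- concordance(cluster_two_class(ma), cluster_two_class(mb), map)
  half_width <- 1.96 * sqrt(n * 0.3 * 0.7)
  expect_gt(cc$n_diff, n * 0.3 - half_width - 5)
  expect_lt(cc$n_diff, n * 0.3 + half_width + 5)
})

test_that("reference normalization is exact and scale-invariant", {
  m <- matrix(c(2, 4, 8, 16), 2, 2,
              dimnames = list(c("Act5C", "g1"), c("t1", "t2")))
  out <- normalize_to_reference(m, "Act5C", pseudocount = 0)
  expect_equal(unname(out["Act5C", ]), c(0, 0))
  expect_equal(unname(out["g1", ]), log10(c(4 / 2, 16 / 8)))

  scaled <- m
  scaled[, 1] <- scaled[, 1] * 7
  expect_equal(normalize_to_reference(scaled, "Act5C", pseudocount = 0), out)

  m0 <- m; m0["Act5C", 1] <- 0
  expect_error(normalize_to_reference(m0, "Act5C", pseudocount = 0), "zero")
  expect_error(normalize_to_reference(m, "absent"), "absent")
})

test_that("PCA variance fractions normalize and reflect planted structure", {
  set.seed(74)
  # rank-1: a single outer product, first component takes everything
  u <- rnorm(20); v <- rnorm(7)
  m1 <- outer(u, v)
  colnames(m1) <- paste0("t", 1:7); rownames(m1) <- paste0("g", 1:20)
  m1b <- outer(rnorm(20), v)
  dimnames(m1b) <- dimnames(m1)
  res1 <- pca_tissue(m1, m1b)
  expect_equal(res1$var_fractions[1] + res1$var_fractions[2], 1,
               tolerance = 1e-8)
  expect_equal(sum(res1$var_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(res1$var_fractions) <= 1e-12))

  # two orthogonal planted factors with 9:1 variance split
  f1 <- c(1, 1, 1, 1, -1, -1, -1) / sqrt(7)
  f2 <- c(1, -1, 1, -1, 1, -1, 1) / sqrt(7)
  mk <- function(n) {
    s <- outer(rnorm(n, sd = 3), f1) + outer(rnorm(n, sd = 1), f2)
    dimnames(s) <- list(paste0("g", 1:n), paste0("t", 1:7))
    s
  }
  res2 <- pca_tissue(mk(400), mk(400))
  expect_equal(unname(res2$var_fractions[1]), 0.9, tolerance = 0.05)
  expect_equal(unname(res2$var_fractions[2]), 0.1, tolerance = 0.05)

  # permutation invariance in gene order
  perm <- sample(20)
  res3 <- pca_tissue(m1[perm, ], m1b)
  expect_equal(res3$var_fractions, res1$var_fractions)

  expect_error(pca_tissue(m1[, 1, drop = FALSE], m1b[, 1, drop = FALSE]),
               "2 tissues")
})

test_that("tissue fold-change ANOVA recovers planted shifts", {
  set.seed(75)
  tissues <- paste0("t", 1:5)
  ma <- matrix(rlnorm(200, 3, 0.2), 40, 5,
               dimnames = list(paste0("a", 1:40), tissues))
  mb <- matrix(rlnorm(200, 3, 0.2), 40, 5,
               dimnames = list(paste0("b", 1:40), tissues))
  map <- data.frame(gene_a = rownames(ma), gene_b = rownames(mb))

  ident <- tissue_fold_change_anova(ma, ma, data.frame(
    gene_a = rownames(ma), gene_b = rownames(ma)))
  expect_equal(unname(ident$means), rep(0, 5))
  expect_equal(ident$p_value, 1)

  # shift one tissue by a known factor
  ma2 <- ma; ma2[, "t3"] <- ma2[, "t3"] * 10^1.2
  res <- tissue_fold_change_anova(ma2, mb, map, pseudocount = 0)
  base <- tissue_fold_change_anova(ma, mb, map, pseudocount = 0)
  expect_equal(unname(res$means["t3"] - base$means["t3"]), 1.2,
               tolerance = 1e-9)
  expect_lt(res$p_value, 1e-4)

  # pair order irrelevant
  perm <- sample(nrow(map))
  res_p <- tissue_fold_change_anova(ma2, mb, map[perm, ], pseudocount = 0)
  expect_equal(res_p$means, res$means)
  expect_equal(res_p$p_value, res$p_value)
})
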