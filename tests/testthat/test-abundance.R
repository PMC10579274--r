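test_that("absolute abundance is relative abundance times qPCR total", {
  rel <- rbind(s1 = c(0.25, 0.75), s2 = c(0.5, 0.5))
  ab <- absolute_abundance(rel, c(4e8, 2e8))
  expect_equal(unname(ab["s1", 1]), 1e8)
  expect_equal(unname(rowSums(ab)), c(4e8, 2e8))
  rel0 <- rbind(c(0.4, 0), c(0.7, 0))
  expect_true(all(absolute_abundance(rel0, c(10, 10))[, 2] == 0))
  expect_error(absolute_abundance(rbind(c(-0.1, 0.5)), 10), "nonnegative")
  expect_error(absolute_abundance(rbind(c(0.6, 0.6)), 10), "sum")
})

test_that("tube-level abundance recovers simulator truth in the noiseless limit", {
  sim <- simulate_experiment(sim_config(n_taxa = 15, seed = 2, qpcr_cv = 0,
                                        reads_per_fraction = Inf,
                                        emergent_taxa = 0))
  ta <- tube_abundance(sim$fractions)
  for (tb in rownames(ta$abundance))
    expect_equal(unname(ta$abundance[tb, ]), sim$truth$abundance,
                 tolerance = 1e-8)
})

test_that("log2 change applies the +1 convention", {
  expect_equal(log2_change(4e6, 8e6), 1, tolerance = 1e-6)
  expect_equal(log2_change(0, 7), 3)
  expect_equal(log2_change(123, 123), 0)
  expect_error(log2_change(-1, 2), "nonnegative")
})

test_that("alpha diversity closed forms", {
  expect_equal(chao1(c(1, 1, 2, 5, 9)), 5.5)
  expect_equal(chao1(c(3, 4, 5)), 3)           # no singletons
  expect_equal(shannon(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(pielou(rep(0.25, 4)), 1, tolerance = 1e-12)
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(pielou(c(7)), 1)
  expect_error(chao1(numeric(0)), "empty")
  expect_error(chao1(c(1.5, 2)), "integers")
  expect_error(shannon(c(0, 0)), "empty")
})

test_that("Shannon is maximal at uniform and Pielou stays in [0,1]", {
  set.seed(3)
  for (r in 1:20) {
    p <- as.vector(stats::rmultinom(1, 500, runif(6))) / 500
    p <- p[p > 0]
    expect_lte(shannon(p), log(length(p)) + 1e-12)
    expect_gte(pielou(p), 0)
    expect_lte(pielou(p), 1 + 1e-12)
  }
})

test_that("Bray-Curtis respects its bounds and metric structure", {
  m <- rbind(a = c(5, 5, 0), b = c(5, 5, 0), c = c(0, 0, 7))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)       # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_error(bray_curtis(rbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("PCoA preserves the distances of an exactly embeddable configuration", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  d <- dist(pts)
  fit <- pcoa(d)
  rec <- dist(fit$points)
  expect_equal(as.vector(rec), as.vector(d), tolerance = 1e-8)
  expect_true(all(fit$eig[1:2] > 0))
})

test_that("ANOSIM separates tight clusters with R = 1 and is seeded", {
  set.seed(10)
  a <- matrix(rep(c(10, 0, 5), each = 4), 4) + matrix(runif(12, 0, 0.1), 4)
  b <- matrix(rep(c(0, 10, 5), each = 4), 4) + matrix(runif(12, 0, 0.1), 4)
  m <- rbind(a, b)
  res <- anosim_test(bray_curtis(m), rep(c("A", "B"), each = 4),
                     n_perm = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_lt(res$p, 0.05)
  res2 <- anosim_test(bray_curtis(m), rep(c("A", "B"), each = 4),
                      n_perm = 199, seed = 1)
  expect_identical(res, res2)
})

test_that("ANOSIM permutation p matches exact enumeration on few samples", {
  # 3 + 3 samples: only 20 distinct group relabelings
  set.seed(4)
  m <- matrix(rexp(6 * 5), 6)
  d <- bray_curtis(m)
  groups <- rep(c("g1", "g2"), each = 3)
  res <- anosim_test(d, groups, n_perm = 999, seed = 2)
  # exact: enumerate all label assignments of 3 samples to group 1
  dm <- as.matrix(d)
  rank_d <- matrix(0, 6, 6)
  rank_d[lower.tri(rank_d)] <- rank(dm[lower.tri(dm)])
  rank_d <- rank_d + t(rank_d)
  r_stat <- function(g) {
    within <- outer(g, g, "==") & lower.tri(dm)
    between <- outer(g, g, "!=") & lower.tri(dm)
    (mean(rank_d[between]) - mean(rank_d[within])) / (6 * 5 / 4)
  }
  combos <- utils::combn(6, 3)
  stats <- apply(combos, 2, function(ix) {
    g <- rep("g2", 6); g[ix] <- "g1"; r_stat(g)
  })
  exact_p <- mean(stats >= r_stat(groups) - 1e-12)
  expect_lt(abs(res$p - exact_p), 0.1)
})

test_that("Kruskal-Wallis H matches the hand rank computation", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
  expect_equal(res$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-10)
  expect_equal(res$H, 3.857, tolerance = 1e-3)
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "empty group")
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
})

test_that("Kruskal-Wallis p is roughly uniform under the null", {
  set.seed(6)
  ps <- replicate(200, {
    x <- rnorm(12)
    kruskal_wallis(split(x, rep(1:2, each = 6)))$p
  })
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("partition test reproduces the printed Venn contingency result", {
  res <- partition_test(492, 58, 34, 26)
  expect_equal(unname(res$table["yes", "yes"]), 26)
  expect_equal(unname(res$table["yes", "no"]), 32)
  expect_equal(unname(res$table["no", "yes"]), 8)
  expect_equal(unname(res$table["no", "no"]), 426)
  expect_equal(res$chi2, hand_chisq(res$table), tolerance = 1e-10)
  expect_equal(res$chi2, 147, tolerance = 0.01)
  expect_lt(res$p, 1e-10)
  expect_equal(res$df, 1)
})

test_that("partition test obeys chi-square scale and independence properties", {
  # independence-exact table: chi2 = 0
  expect_equal(partition_test(100, 20, 10, 2)$chi2, 0, tolerance = 1e-12)
  # doubling all cells doubles the statistic
  a <- partition_test(200, 50, 40, 25)
  b <- partition_test(400, 100, 80, 50)
  expect_equal(b$chi2, 2 * a$chi2, tolerance = 1e-10)
  expect_error(partition_test(100, 20, 10, 15), "margin")
  expect_error(partition_test(20, 15, 10, 2), "negative")
})

test_that("partition test agrees with a generic contingency implementation", {
  set.seed(8)
  for (r in 1:100) {
    n <- sample(50:500, 1)
    n_a <- sample(5:(n / 2), 1)
    n_b <- sample(5:(n / 2), 1)
    n_both <- sample(0:min(n_a, n_b), 1)
    if (n - n_a - n_b + n_both < 0) next
    res <- partition_test(n, n_a, n_b, n_both)
    expect_equal(res$chi2, hand_chisq(res$table), tolerance = 1e-8)
  }
})

test_that("goodness-of-fit variant uses the four cells with df = 3", {
  res <- partition_test(492, 58, 34, 26, variant = "gof")
  expect_equal(res$df, 3)
  expect_lt(res$p, 0.001)
})
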