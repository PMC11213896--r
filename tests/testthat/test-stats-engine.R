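# Differential/association machinery against frozen examples and slow oracles.

test_that("bh_adjust matches the hand-worked example and edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("bh_adjust equals the brute-force step-up oracle", {
  withr::with_seed(8, {
    for (i in 1:100) {
      p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
      expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
    }
  })
})

test_that("fisher_exact matches enumeration on frozen and random tables", {
  r <- fisher_exact(matrix(c(3, 1, 1, 3), 2, 2))
  expect_equal(r$p.value, 34 / 70, tolerance = 1e-12)
  expect_equal(r$odds_ratio, 9)
  r2 <- fisher_exact(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(r2$p.value, 2 / 252, tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(2, 0, 3, 0), 2, 2)), "margins")
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2, 2)), "non-negative")
  withr::with_seed(9, {
    for (i in 1:50) {
      tb <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
      if (min(rowSums(tb)) == 0 || min(colSums(tb)) == 0) next
      got <- fisher_exact(tb)$p.value
      expect_equal(got, oracle_fisher(tb), tolerance = 1e-9)
      expect_equal(got, stats::fisher.test(tb)$p.value, tolerance = 1e-7)
    }
  })
})

test_that("wilcoxon_rank_sum: exact enumeration, ties, and approximation", {
  r <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(r$p.value, 0.1)                 # 2/20 most extreme
  expect_equal(r$statistic, 0)
  expect_warning(r2 <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2)), "tied")
  expect_equal(r2$p.value, 1)
  withr::with_seed(10, {
    for (i in 1:20) {
      nx <- sample(2:8, 1); ny <- sample(2:8, 1)
      x <- stats::rnorm(nx); y <- stats::rnorm(ny)
      expect_equal(wilcoxon_rank_sum(x, y)$p.value,
                   oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
    }
    # approximation close to exact at n = 8/8
    for (i in 1:10) {
      x <- stats::rnorm(8); y <- stats::rnorm(8, 0.5)
      pe <- wilcoxon_rank_sum(x, y)$p.value
      pa <- wilcoxon_rank_sum(x, y, exact_max = 0)$p.value
      expect_lt(abs(pe - pa), 0.011)
    }
  })
})

test_that("linear_diff recovers planted effects exactly in the noise-free limit", {
  n <- 12
  s <- data.frame(group = rep(c("A", "B"), each = n / 2),
                  age = stats::runif(n, 20, 50))
  m <- matrix(rep(5, n), 1, n,
              dimnames = list("f1", paste0("s", 1:n)))
  m[1, s$group == "B"] <- 6
  d <- linear_diff(m, s, "group", c("A", "B"))
  expect_equal(d$log2FC, 1, tolerance = 1e-12)
  expect_lt(d$p, 1e-12)
  expect_equal(d$n_used, n)
  expect_equal(attr(d, "contrast"), "B vs A")

  # sign convention: level order flips the sign
  d2 <- linear_diff(m, s, "group", c("B", "A"))
  expect_equal(d2$log2FC, -1, tolerance = 1e-12)

  # covariate fully confounded with the contrast: rank error
  s$src <- s$group
  expect_error(linear_diff(m, s, "group", c("A", "B"), covariates = "src"),
               "rank-deficient")

  # masked entries: dropped per feature, n_used recorded
  m2 <- rbind(m, f2 = m[1, ] + 1)
  m2[2, 1] <- NA
  d3 <- suppressMessages(linear_diff(m2, s, "group", c("A", "B")))
  expect_equal(d3$n_used, c(n, n - 1L))
  expect_equal(d3$log2FC, c(1, 1), tolerance = 1e-10)
})

test_that("linear_diff is calibrated under the null", {
  withr::with_seed(14, {
    n <- 60; nf <- 1000
    s <- data.frame(group = sample(rep(c("A", "B"), each = n / 2)),
                    age = stats::runif(n, 10, 60),
                    sex = sample(c("F", "M"), n, TRUE))
    m <- matrix(stats::rnorm(nf * n), nf, n,
                dimnames = list(paste0("f", 1:nf), paste0("s", 1:n)))
    d <- linear_diff(m, s, "group", c("A", "B"), covariates = c("age", "sex"))
    for (alpha in c(0.01, 0.05)) {
      frac <- mean(d$p < alpha)
      expect_lt(abs(frac - alpha), 3.5 * sqrt(alpha * (1 - alpha) / nf))
    }
    # q-values never below p
    expect_true(all(d$q >= d$p - 1e-12))
  })
})

test_that("correlation screens are consistent and behave under the null", {
  x <- c(1, 2, 3, 4, 5)
  layer <- rbind(up = x^3, down = -x, flat = rep(1, 5))
  colnames(layer) <- paste0("s", 1:5)
  r <- correlate_feature_vs_layer(stats::setNames(x, colnames(layer)), layer)
  expect_equal(r$rho[r$feature == "up"], 1)
  expect_equal(r$rho[r$feature == "down"], -1)
  expect_true(is.na(r$rho[r$feature == "flat"]))

  withr::with_seed(15, {
    f <- stats::rnorm(300)
    layer2 <- matrix(stats::rnorm(300 * 5), 5, 300,
                     dimnames = list(paste0("g", 1:5), paste0("s", 1:300)))
    r2 <- correlate_feature_vs_layer(stats::setNames(f, colnames(layer2)),
                                     layer2)
    expect_lt(max(abs(r2$rho)), 0.2)
    expect_gt(min(r2$q), 0.2)   # no spurious association at n = 300
  })

  # agreement with correlation_matrix on identical inputs
  m <- rbind(a = c(3, 1, 4, 1, 5, 9, 2, 6), b = c(2, 7, 1, 8, 2, 8, 1, 8))
  colnames(m) <- paste0("s", 1:8)
  cm <- correlation_matrix(m)
  r3 <- correlate_feature_vs_layer(stats::setNames(m["a", ], colnames(m)), m)
  expect_equal(r3$rho[r3$feature == "b"], cm$rho["a", "b"], tolerance = 1e-12)
})

test_that("longitudinal_stability ranks per-analyte correlations", {
  v1 <- matrix(stats::rnorm(40), 4, 10,
               dimnames = list(paste0("a", 1:4), paste0("s", 1:10)))
  st <- longitudinal_stability(v1, v1)
  expect_equal(st$rho, rep(1, 4))
  expect_error(longitudinal_stability(v1, v1[, 1:2]), "shared samples")
  v2 <- v1; rownames(v2) <- paste0("zz", 1:4)
  expect_error(longitudinal_stability(v1, v2), "shared features")
})

test_that("gsea_preranked: frozen walk, degenerate sets, slow-oracle agreement", {
  ranking <- stats::setNames(c(4, 3, 2, 1) * 1.0, c("g1", "g2", "g3", "g4"))
  # universe of 4 is below the minimum; embed in a 12-gene universe
  ranking <- stats::setNames(seq(12, 1), paste0("g", 1:12))
  res <- gsea_preranked(ranking, list(top = c("g1", "g2")), n_perm = 50,
                        seed = 1)
  expect_equal(res$ES, 1, tolerance = 1e-12)   # all hits at the very top
  expect_warning(
    res2 <- gsea_preranked(ranking, list(all = names(ranking)), n_perm = 10,
                           seed = 1),
    "whole universe")
  expect_equal(nrow(res2), 0L)

  withr::with_seed(16, {
    for (i in 1:10) {
      scores <- stats::setNames(stats::rnorm(20), paste0("g", 1:20))
      set <- sample(names(scores), sample(2:8, 1))
      got <- gsea_preranked(scores, list(s = set), n_perm = 5, seed = i)
      expect_equal(got$ES, oracle_gsea_es(scores, set), tolerance = 1e-12)
    }
    # uniformly scattered set in a long ranking: |NES| ~ 1, q large
    long <- stats::setNames(stats::rnorm(200), paste0("g", 1:200))
    spread <- paste0("g", seq(5, 200, by = 10))
    r <- gsea_preranked(long, list(s = spread), n_perm = 400, seed = 3)
    expect_lt(abs(abs(r$NES) - 1), 0.8)
    expect_gt(r$q, 0.05)
  })
})
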