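# Normalization, filtering, adjustment, z-scoring.

mk <- function(vals, nr, nc, fprefix = "f", sprefix = "s") {
  matrix(vals, nr, nc,
         dimnames = list(paste0(fprefix, seq_len(nr)),
                         paste0(sprefix, seq_len(nc))))
}

test_that("replace_zeros honours the Uniform(0, 0.5*min-nonzero) contract", {
  m <- mk(c(0, 1, 4, 2, 8, 3), 2, 3)  # rows: (0,4,8) and (1,2,3)
  out <- replace_zeros(m, seed = 1L)
  expect_gt(out[1, 1], 0)
  expect_lte(out[1, 1], 2)                      # 0.5 * min nonzero (4)
  expect_identical(out[1, 2:3], m[1, 2:3])
  expect_identical(out[2, ], m[2, ])            # feature without zeros

  m2 <- mk(c(0, 5, 0, 6, 0, 7), 2, 3)           # row 1 all zero
  expect_warning(out2 <- replace_zeros(m2, seed = 2L), "all-zero")
  expect_equal(nrow(out2), 1L)
  expect_identical(rownames(out2), "f2")

  # determinism under seed
  expect_identical(replace_zeros(m, seed = 5L), replace_zeros(m, seed = 5L))
})

test_that("median_normalize matches the hand-computed example and is idempotent", {
  strip <- function(x) { attr(x, "factors") <- NULL; unname(x) }
  m <- mk(c(1, 3, 2, 6), 2, 2)                  # columns (1,3) and (2,6)
  out <- median_normalize(m)
  expect_equal(strip(out), matrix(c(1.25, 3.75, 1.25, 3.75), 2, 2))
  expect_equal(unname(attr(out, "factors")), c(1.25, 0.625))

  # all columns identical: unchanged up to a global factor of 1
  m2 <- mk(rep(c(1, 2, 5), 4), 3, 4)
  expect_equal(strip(median_normalize(m2)), unname(m2))

  # single sample: unchanged
  m3 <- mk(c(2, 4, 9), 3, 1)
  expect_equal(strip(median_normalize(m3)), unname(m3))

  # idempotence on random positive matrices
  withr::with_seed(42, {
    for (i in 1:20) {
      r <- mk(stats::rexp(12 * 7) + 0.1, 12, 7)
      once <- median_normalize(r)
      twice <- median_normalize(once)
      expect_equal(strip(twice), strip(once), tolerance = 1e-12)
    }
  })

  m4 <- mk(c(-1, -2, 3, 4), 2, 2)
  expect_error(median_normalize(m4), "non-positive median")
})

test_that("mask_outliers_iqr implements the 3*IQR rule", {
  m <- mk(c(1:9, 1000), 1, 10)
  out <- suppressMessages(mask_outliers_iqr(m, rep("g", 10)))
  expect_true(is.na(out[1, 10]))
  expect_equal(sum(is.na(out)), 1L)

  cst <- mk(rep(5, 8), 1, 8)
  expect_equal(sum(is.na(suppressMessages(
    mask_outliers_iqr(cst, rep("g", 8))))), 0L)

  sym <- mk(c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2), 1, 10)
  expect_equal(sum(is.na(suppressMessages(
    mask_outliers_iqr(sym, rep("g", 10))))), 0L)
})

test_that("mask_outliers_iqr agrees with the brute-force oracle", {
  withr::with_seed(7, {
    for (i in 1:25) {
      nr <- sample(2:6, 1); nc <- sample(8:20, 1)
      m <- mk(stats::rt(nr * nc, df = 3), nr, nc)
      m[sample(length(m), 2)] <- NA
      groups <- sample(c("A", "B"), nc, replace = TRUE)
      got <- suppressMessages(mask_outliers_iqr(m, groups))
      attr(got, "n_masked") <- NULL
      expect_equal(got, oracle_iqr_mask(m, groups))
    }
  })
})

test_that("adjust_covariates removes planted covariate structure exactly", {
  s <- data.frame(age = c(20, 30, 40, 50, 25, 35),
                  sex = c("F", "M", "F", "M", "F", "M"),
                  source = c("A", "A", "B", "B", "A", "B"))
  # pure source offset: adjusted values constant
  y <- mk(3 + 5 * (s$source == "B"), 1, 6)
  adj <- adjust_covariates(y, s, "source")
  expect_equal(unname(diff(range(adj))), 0, tolerance = 1e-12)
  expect_equal(mean(adj), mean(y))              # grand mean retained

  # empty covariate list: identity
  expect_identical(adjust_covariates(y, s, character(0)), y)

  # planted age slope, noise-free: post-adjustment slope 0 to machine precision
  y2 <- mk(1 + 0.1 * s$age, 1, 6)
  adj2 <- adjust_covariates(y2, s, "age")
  refit <- stats::lm(as.numeric(adj2) ~ s$age)
  expect_equal(unname(stats::coef(refit)[2]), 0, tolerance = 1e-12)

  # feature orthogonal to the design is unchanged
  withr::with_seed(3, {
    raw <- stats::rnorm(6)
    ortho <- stats::resid(stats::lm(raw ~ s$age + s$sex + s$source))
    y3 <- mk(ortho + 2, 1, 6)
    adj3 <- adjust_covariates(y3, s, c("age", "sex", "source"))
    expect_equal(unname(adj3), unname(y3), tolerance = 1e-10)
  })

  # rank-deficient design errors with the aliased column named
  s_bad <- s; s_bad$dup <- s$source
  expect_error(adjust_covariates(y, s_bad, c("source", "dup")),
               "rank-deficient.*dup", ignore.case = TRUE)

  # missing entries: per-feature fallback agrees with the fast path elsewhere
  y4 <- rbind(f1 = 3 + 5 * (s$source == "B"), f2 = 1 + 0.1 * s$age)
  colnames(y4) <- paste0("s", 1:6)
  y4[2, 3] <- NA
  adj4 <- adjust_covariates(y4, s, "source")
  expect_equal(unname(diff(range(adj4[1, ]))), 0, tolerance = 1e-12)
  expect_true(is.na(adj4[2, 3]))
})

test_that("zscore_vs_controls matches hand computation and its invariant", {
  m <- mk(c(1, 2, 3, 4), 1, 4)
  z <- zscore_vs_controls(m, c("s1", "s2", "s3"))   # ref mean 2, sd 1
  expect_equal(unname(z$z[1, "s4"]), 2)
  expect_equal(unname(z$z[1, "s2"]), 0)

  cst <- mk(c(5, 5, 5, 9), 1, 4)
  expect_warning(zc <- zscore_vs_controls(cst, c("s1", "s2", "s3")),
                 "zero reference SD")
  expect_equal(nrow(zc$z), 0L)

  withr::with_seed(11, {
    r <- mk(stats::rnorm(8 * 10), 8, 10)
    ref <- paste0("s", 1:6)
    zz <- zscore_vs_controls(r, ref)$z[, ref]
    expect_equal(unname(rowMeans(zz)), rep(0, 8), tolerance = 1e-12)
    expect_equal(unname(apply(zz, 1, stats::sd)), rep(1, 8),
                 tolerance = 1e-12)
  })
  expect_error(zscore_vs_controls(m, character(0)), "empty reference")
})

test_that("log2_transform trivials and error branch", {
  m <- mk(c(4, 0, 7), 1, 3)
  expect_error(log2_transform(m), "non-positive")
  out <- log2_transform(m, pseudocount = 1)
  expect_equal(unname(out[1, ]), c(log2(5), 0, 3))
  expect_equal(unname(log2_transform(mk(4, 1, 1))[1, 1]), 2)
})
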