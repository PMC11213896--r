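# Normalization, filtering, covariate adjustment, and z-scoring.

#' Replace zero intensities with small random draws
#'
#' For each feature containing zeros, zeros are replaced by draws from
#' `Uniform(0, 0.5 * min nonzero)` of that feature; non-zero values are left
#' untouched. Features that are entirely zero are dropped with a warning.
#'
#' @param m Feature x sample matrix of non-negative intensities.
#' @param seed Optional seed for the replacement draws.
#' @return The matrix with zeros replaced (possibly fewer rows).
#' @export
replace_zeros <- function(m, seed = NULL) {
  check_omics_matrix(m)
  run <- function() {
    all_zero <- apply(m, 1L, function(x) all(x == 0, na.rm = TRUE))
    if (any(all_zero)) {
      warning("dropping ", sum(all_zero), " all-zero feature(s): ",
              paste(utils::head(rownames(m)[all_zero], 5L), collapse = ", "),
              call. = FALSE)
      m <- m[!all_zero, , drop = FALSE]
    }
    for (i in seq_len(nrow(m))) {
      x <- m[i, ]
      zi <- which(!is.na(x) & x == 0)
      if (length(zi) > 0L) {
        mn <- min(x[!is.na(x) & x > 0])
        m[i, zi] <- stats::runif(length(zi), 0, 0.5 * mn)
      }
    }
    m
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Median normalization across samples
#'
#' Each sample is rescaled by `global_median / sample_median`, where the
#' global median is taken over all finite entries of the matrix. After
#' normalization every sample has the same median intensity.
#'
#' @param m Feature x sample matrix of positive intensities.
#' @return The normalized matrix; scaling factors in attribute `"factors"`.
#' @export
median_normalize <- function(m) {
  check_omics_matrix(m)
  global <- stats::median(m[is.finite(m)])
  med <- apply(m, 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(med)) || any(med <= 0)) {
    bad <- colnames(m)[!is.finite(med) | med <= 0][1L]
    stop("sample '", bad, "' has non-positive median; cannot median-normalize",
         call. = FALSE)
  }
  factors <- global / med
  out <- sweep(m, 2L, factors, "*")
  attr(out, "factors") <- factors
  out
}

#' Mask extreme outliers by the 3-IQR rule, per karyotype group
#'
#' Within each group and feature, values below `Q1 - 3*IQR` or above
#' `Q3 + 3*IQR` (quartiles by type-7 linear interpolation) are set to `NA`.
#' Feature/group combinations with fewer than `min_n` non-missing values are
#' skipped.
#'
#' @param m Feature x sample matrix.
#' @param groups Character/factor vector of per-sample group labels
#'   (e.g. karyotype), aligned with `colnames(m)`.
#' @param k Multiplier of the IQR; default 3 (extreme outliers).
#' @param min_n Minimum non-missing values per feature/group; default 4.
#' @return The matrix with outliers masked; the number of masked entries is
#'   stored in attribute `"n_masked"` and reported via `message()`.
#' @export
mask_outliers_iqr <- function(m, groups, k = 3, min_n = 4L) {
  check_omics_matrix(m)
  stopifnot(length(groups) == ncol(m))
  n_masked <- 0L
  for (g in unique(groups)) {
    cols <- which(groups == g)
    for (i in seq_len(nrow(m))) {
      x <- m[i, cols]
      ok <- !is.na(x)
      if (sum(ok) < min_n) next
      q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2L] - q[1L]
      out <- ok & (x < q[1L] - k * iqr | x > q[2L] + k * iqr)
      if (any(out)) {
        m[i, cols[out]] <- NA_real_
        n_masked <- n_masked + sum(out)
      }
    }
  }
  message("mask_outliers_iqr: masked ", n_masked, " value(s)")
  attr(m, "n_masked") <- n_masked
  m
}

# Build the covariate design (without intercept): age numeric centered,
# categorical covariates one-hot with the first level as reference.
covariate_design <- function(samples, covariates) {
  if (length(covariates) == 0L) return(NULL)
  missing_cov <- setdiff(covariates, colnames(samples))
  if (length(missing_cov) > 0L) {
    stop("covariate(s) not in sample table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(covariates, function(v) {
    x <- samples[[v]]
    if (is.numeric(x)) {
      out <- matrix(x - mean(x), ncol = 1L, dimnames = list(NULL, v))
    } else {
      f <- factor(x)
      if (nlevels(f) < 2L) {
        stop("covariate '", v, "' is constant", call. = FALSE)
      }
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(v, levels(f)[-1L])
      out <- mm
    }
    out
  })
  do.call(cbind, cols)
}

#' Remove covariate effects from a log2-scale matrix
#'
#' Per feature, ordinary least squares of the value on the covariates
#' (categorical covariates one-hot coded against a reference level, numeric
#' covariates centered); the fitted covariate contributions are subtracted
#' while the grand mean is retained (covariate columns are mean-centered
#' before subtraction). Analogous to batch-effect removal prior to
#' visualization or correlation analysis.
#'
#' @param m Feature x sample matrix (log2 scale).
#' @param samples Sample table with one row per column of `m`.
#' @param covariates Character vector of covariate column names; empty vector
#'   returns `m` unchanged.
#' @return The adjusted matrix.
#' @export
adjust_covariates <- function(m, samples, covariates = c("age", "sex", "source")) {
  check_omics_matrix(m)
  stopifnot(nrow(samples) == ncol(m))
  C <- covariate_design(samples, covariates)
  if (is.null(C)) return(m)
  X <- cbind(`(Intercept)` = 1, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient covariate design; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  Cc <- sweep(C, 2L, colMeans(C))   # centered: subtracting keeps grand mean
  complete <- !anyNA(m)
  if (complete) {
    beta <- t(qr.coef(qrX, t(m)))          # features x coefficients
    m - beta[, colnames(C), drop = FALSE] %*% t(Cc)
  } else {
    out <- m
    for (i in seq_len(nrow(m))) {
      y <- m[i, ]
      ok <- !is.na(y)
      fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
      b <- fit$coefficients[colnames(C)]
      b[is.na(b)] <- 0
      out[i, ok] <- y[ok] - drop(Cc[ok, , drop = FALSE] %*% b)
    }
    out
  }
}

#' Z-scores relative to a reference group
#'
#' `z = (x - mean_ref) / sd_ref` per feature, with the sample SD (n-1
#' denominator) computed over the reference columns. Features whose reference
#' SD is zero (or not estimable) are dropped with a warning.
#'
#' @param m Feature x sample matrix.
#' @param reference Character vector of reference sample ids (e.g. euploid
#'   controls), a subset of `colnames(m)`.
#' @return An object of class `zscore_matrix`: list with `z`, `ref_mean`,
#'   `ref_sd`, `reference`.
#' @export
zscore_vs_controls <- function(m, reference) {
  check_omics_matrix(m)
  if (length(reference) == 0L) stop("empty reference group", call. = FALSE)
  if (!all(reference %in% colnames(m))) {
    stop("reference ids not in matrix: ",
         paste(utils::head(setdiff(reference, colnames(m)), 5L),
               collapse = ", "), call. = FALSE)
  }
  ref <- m[, reference, drop = FALSE]
  mu <- rowMeans(ref, na.rm = TRUE)
  sd_ <- apply(ref, 1L, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sd_) | sd_ <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " feature(s) with zero reference SD: ",
            paste(utils::head(rownames(m)[bad], 5L), collapse = ", "),
            call. = FALSE)
  }
  keep <- !bad
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  structure(list(z = z, ref_mean = mu[keep], ref_sd = sd_[keep],
                 reference = reference),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat("zscore_matrix:", nrow(x$z), "features x", ncol(x$z), "samples; ",
      length(x$reference), "reference samples\n")
  invisible(x)
}

#' Elementwise log2 transform with pseudocount
#'
#' @param m Feature x sample matrix.
#' @param pseudocount Added before taking log2; default 0.
#' @return `log2(m + pseudocount)`.
#' @export
log2_transform <- function(m, pseudocount = 0) {
  check_omics_matrix(m)
  shifted <- m + pseudocount
  if (any(shifted <= 0, na.rm = TRUE)) {
    stop("non-positive value(s) after pseudocount shift", call. = FALSE)
  }
  log2(shifted)
}
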