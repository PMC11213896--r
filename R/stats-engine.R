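# Generic differential-abundance and association machinery: per-feature
# linear models, rank tests, Fisher's exact test, BH adjustment, correlation
# screens, longitudinal stability, and preranked GSEA.

#' Benjamini-Hochberg adjustment
#'
#' Step-up rule: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned
#' in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] and non-missing", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1L)))[ro]
}

#' Per-feature linear-model differential abundance
#'
#' Ordinary least squares per feature of the (log2-scale) outcome on a group
#' contrast plus covariates. The reported `log2FC` is the coefficient of group
#' level B versus level A (positive = higher in B); two-sided p-values come
#' from the t statistic and q-values from BH across all tested features of the
#' layer. Masked (`NA`) entries are dropped per feature, with the used sample
#' count recorded.
#'
#' @param m Feature x sample matrix on the log2 scale.
#' @param samples Sample table aligned with `colnames(m)`; must contain
#'   `group_var` and the covariates.
#' @param group_var Name of the grouping column.
#' @param levels Character vector `c(A, B)`: reference level and test level.
#' @param covariates Covariate column names (age numeric centered,
#'   categoricals one-hot with reference level).
#' @param min_n Features with fewer complete observations than
#'   `ncol(design) + 1` (or `min_n` if larger) are skipped with a log message.
#' @return data.frame of class `differential_result`: feature, log2FC, se,
#'   p, q, n_used. Attribute `"contrast"` records the comparison.
#' @export
linear_diff <- function(m, samples, group_var, levels,
                        covariates = character(), min_n = 3L) {
  check_omics_matrix(m)
  stopifnot(nrow(samples) == ncol(m), length(levels) == 2L)
  g <- samples[[group_var]]
  if (is.null(g)) stop("group variable '", group_var, "' not found",
                       call. = FALSE)
  keep <- !is.na(g) & g %in% levels
  if (sum(g[keep] == levels[1L]) < 3L || sum(g[keep] == levels[2L]) < 3L) {
    stop("need >= 3 samples in both contrast levels", call. = FALSE)
  }
  m <- m[, keep, drop = FALSE]
  samples <- samples[keep, , drop = FALSE]
  grp <- as.numeric(samples[[group_var]] == levels[2L])
  C <- covariate_design(samples, covariates)
  X <- cbind(`(Intercept)` = 1, group = grp, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  p_design <- ncol(X)
  need <- max(min_n, p_design + 1L)
  nf <- nrow(m)
  est <- se <- pv <- rep(NA_real_, nf)
  n_used <- integer(nf)
  complete <- !anyNA(m)

  fit_block <- function(Xb, Yb) {
    # Yb: samples x features (complete); returns list(beta, se, df)
    qrb <- qr(Xb)
    coefs <- qr.coef(qrb, Yb)
    res <- Yb - Xb %*% coefs
    df <- nrow(Xb) - ncol(Xb)
    s2 <- colSums(res^2) / df
    gi <- which(colnames(Xb) == "group")
    xtx_inv_g <- chol2inv(qr.R(qrb))[gi, gi]
    list(beta = coefs["group", ], se = sqrt(s2 * xtx_inv_g), df = df)
  }

  if (complete) {
    fb <- fit_block(X, t(m))
    est <- fb$beta
    se <- fb$se
    pv <- 2 * stats::pt(-abs(est / se), df = fb$df)
    n_used <- rep(ncol(m), nf)
  } else {
    skipped <- character(0)
    for (i in seq_len(nf)) {
      y <- m[i, ]
      ok <- !is.na(y)
      n_used[i] <- sum(ok)
      if (n_used[i] < need ||
          length(unique(grp[ok])) < 2L) {
        skipped <- c(skipped, rownames(m)[i])
        n_used[i] <- sum(ok)
        next
      }
      fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
      if (fit$rank < p_design) {
        skipped <- c(skipped, rownames(m)[i])
        next
      }
      b <- fit$coefficients["group"]
      df <- n_used[i] - p_design
      s2 <- sum(fit$residuals^2) / df
      R <- qr.R(fit$qr)
      xtx_inv <- chol2inv(R)
      gi <- which(colnames(X) == "group")
      est[i] <- b
      se[i] <- sqrt(s2 * xtx_inv[gi, gi])
      pv[i] <- 2 * stats::pt(-abs(b / se[i]), df = df)
    }
    if (length(skipped) > 0L) {
      message("linear_diff: skipped ", length(skipped),
              " feature(s) with insufficient data")
    }
  }
  q <- rep(NA_real_, nf)
  tested <- !is.na(pv)
  q[tested] <- bh_adjust(pv[tested])
  out <- data.frame(feature = rownames(m), log2FC = est, se = se, p = pv,
                    q = q, n_used = n_used, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- paste(levels[2L], "vs", levels[1L])
  class(out) <- c("differential_result", class(out))
  out
}

#' Wilcoxon rank-sum test
#'
#' Mann-Whitney U statistic with average ranks for ties. Exact two-sided
#' p-value by enumeration of the rank-sum distribution when both groups have
#' at most `exact_max` observations and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_max Largest per-group n for the exact branch; default 10.
#' @return List with `statistic` (U) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  ties <- table(r)
  has_ties <- any(ties > 1L)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both groups; p = 1", call. = FALSE)
    return(list(statistic = U, p.value = 1))
  }
  if (!has_ties && nx <= exact_max && ny <= exact_max) {
    pl <- stats::pwilcox(U, nx, ny)
    pu <- stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(pl, pu))
  } else {
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))
    sigma <- sqrt(nx * ny / 12 * (nx + ny + 1 - tie_term))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sigma   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = U, p.value = p)
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric test: the two-sided p-value is the sum of the
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table. The odds ratio reported is the
#' sample (unconditional MLE) odds ratio.
#'
#' @param table2x2 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with `odds_ratio` and `p.value`.
#' @export
fisher_exact <- function(table2x2) {
  tb <- as.matrix(table2x2)
  if (!all(dim(tb) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tb < 0) || any(tb != round(tb))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  r1 <- sum(tb[1L, ]); r2 <- sum(tb[2L, ])
  c1 <- sum(tb[, 1L]); c2 <- sum(tb[, 2L])
  if (min(r1, r2, c1, c2) == 0L) {
    stop("all margins must be positive", call. = FALSE)
  }
  n <- sum(tb)
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tb[1L, 1L], r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tb[1L, 1L] * tb[2L, 2L]) / (tb[1L, 2L] * tb[2L, 1L])
  list(odds_ratio = or, p.value = min(1, p))
}

# Spearman rho with two-sided p via the t approximation, pairwise complete.
spearman_test <- function(x, y, min_n = 3L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_n) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Correlate one feature against every feature of a layer
#'
#' Spearman rho, two-sided p (t approximation) and BH q across the layer, for
#' one feature vector (e.g. an HSA21 gene's expression, or a composite score)
#' against each row of an omics layer. Degenerate (constant) features are
#' masked.
#'
#' @param f Named numeric vector (names = sample ids), or unnamed vector
#'   aligned with `colnames(layer)`.
#' @param layer Feature x sample matrix.
#' @param min_n Minimum pairwise-complete n; default 3.
#' @return data.frame: feature, rho, p, q, n.
#' @export
correlate_feature_vs_layer <- function(f, layer, min_n = 3L) {
  check_omics_matrix(layer)
  if (!is.null(names(f))) {
    common <- intersect(names(f), colnames(layer))
    if (length(common) < min_n) stop("too few shared samples", call. = FALSE)
    layer <- layer[, common, drop = FALSE]
    f <- f[common]
  } else {
    stopifnot(length(f) == ncol(layer))
  }
  res <- lapply(seq_len(nrow(layer)), function(i) {
    spearman_test(f, layer[i, ], min_n = min_n)
  })
  rho <- vapply(res, `[[`, 0, "rho")
  p <- vapply(res, `[[`, 0, "p")
  n <- vapply(res, `[[`, 0L, "n")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_adjust(p[ok])
  data.frame(feature = rownames(layer), rho = rho, p = p, q = q, n = n,
             stringsAsFactors = FALSE)
}

#' Longitudinal stability of analytes across two visits
#'
#' Per-analyte Spearman correlation across samples measured at both visits,
#' BH-adjusted, returned ranked by descending rho.
#'
#' @param visit1,visit2 Feature x sample matrices sharing feature ids and at
#'   least 3 sample ids.
#' @return data.frame: feature, rho, p, q, n, ordered by descending rho.
#' @export
longitudinal_stability <- function(visit1, visit2) {
  check_omics_matrix(visit1); check_omics_matrix(visit2)
  shared_s <- intersect(colnames(visit1), colnames(visit2))
  if (length(shared_s) < 3L) {
    stop("need >= 3 shared samples across visits", call. = FALSE)
  }
  shared_f <- intersect(rownames(visit1), rownames(visit2))
  if (length(shared_f) == 0L) stop("no shared features", call. = FALSE)
  res <- lapply(shared_f, function(fid) {
    spearman_test(visit1[fid, shared_s], visit2[fid, shared_s])
  })
  rho <- vapply(res, `[[`, 0, "rho")
  p <- vapply(res, `[[`, 0, "p")
  n <- vapply(res, `[[`, 0L, "n")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_adjust(p[ok])
  out <- data.frame(feature = shared_f, rho = rho, p = p, q = q, n = n,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rho, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Weighted Kolmogorov-Smirnov-style enrichment score (weight exponent 1):
# hits advance by |score|/sum(|score| of hits), misses decrement uniformly;
# ES is the maximum-magnitude deviation of the running sum.
gsea_es <- function(scores_sorted, hit) {
  nh <- sum(hit)
  n <- length(hit)
  w <- abs(scores_sorted) * hit
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else hit / nh   # all-zero scores: uniform hits
  dec <- (1 - hit) / (n - nh)
  dev <- cumsum(inc - dec)
  dev[which.max(abs(dev))]
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov-style enrichment (weight exponent 1: hit steps
#' proportional to |score|, uniform miss decrements) over a ranking of the
#' gene universe. The null is generated by permuting gene labels within the
#' ranked list; `NES = ES / mean(|null ES| of the matching sign)`; empirical
#' p-values use +1 smoothing; BH q across the tested sets. Sets with fewer
#' than `min_size` members in the universe, or spanning the whole universe,
#' are skipped with a message.
#'
#' @param ranking Named numeric vector: gene id -> ranking score (e.g. log2
#'   fold change or Spearman rho). Sorted internally in decreasing order with
#'   deterministic tie-breaks by gene id.
#' @param sets List of gene sets as returned by [read_gmt()], or a named list
#'   of character vectors.
#' @param n_perm Number of gene-label permutations; default 1000.
#' @param seed RNG seed for the permutations.
#' @param min_size Minimum set size within the universe; default 2.
#' @return data.frame of class `gsea_result`: set, size, ES, NES, p, q,
#'   leading_edge (comma-joined ids).
#' @export
gsea_preranked <- function(ranking, sets, n_perm = 1000L, seed = NULL,
                           min_size = 2L) {
  if (is.null(names(ranking))) stop("ranking must be named", call. = FALSE)
  if (length(ranking) < 10L) stop("ranked universe too small", call. = FALSE)
  members_of <- lapply(sets, function(s) if (is.list(s)) s$members else s)
  set_names <- names(sets) %||% vapply(sets, `[[`, "", "name")
  ord <- order(-ranking, names(ranking))
  scores <- ranking[ord]
  genes <- names(scores)
  n <- length(genes)
  run <- function() {
    out <- list()
    for (si in seq_along(members_of)) {
      mem <- intersect(members_of[[si]], genes)
      if (length(mem) < min_size) {
        message("gsea_preranked: skipping '", set_names[si],
                "' (", length(mem), " members in universe)")
        next
      }
      if (length(mem) >= n) {
        warning("set '", set_names[si], "' spans the whole universe; skipped",
                call. = FALSE)
        next
      }
      hit <- as.numeric(genes %in% mem)
      es <- gsea_es(scores, hit)
      null_es <- vapply(seq_len(n_perm), function(b) {
        gsea_es(scores, sample(hit))
      }, 0)
      same_sign <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same_sign) > 0L) es / mean(abs(same_sign)) else NA_real_
      p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
      # leading edge: hits at or before the extreme of the running sum
      w <- abs(scores) * hit
      inc <- if (sum(w) > 0) w / sum(w) else hit / sum(hit)
      dev <- cumsum(inc - (1 - hit) / (n - sum(hit)))
      peak <- which.max(abs(dev))
      le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)] == 1] else
        genes[seq(peak, n)][hit[seq(peak, n)] == 1]
      out[[length(out) + 1L]] <- data.frame(
        set = set_names[si], size = length(mem), ES = es, NES = nes, p = p,
        leading_edge = paste(le, collapse = ","), stringsAsFactors = FALSE)
    }
    out
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  if (length(out) == 0L) {
    return(structure(data.frame(set = character(0), size = integer(0),
                                ES = numeric(0), NES = numeric(0),
                                p = numeric(0), q = numeric(0),
                                leading_edge = character(0)),
                     class = c("gsea_result", "data.frame")))
  }
  res <- do.call(rbind, out)
  res$q <- bh_adjust(res$p)
  res <- res[, c("set", "size", "ES", "NES", "p", "q", "leading_edge")]
  class(res) <- c("gsea_result", class(res))
  res
}
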