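# Shared fixtures and independent oracles. Oracles are deliberately slow,
# literal transcriptions of definitions, kept independent of the package's
# fast paths.

small_config <- function(seed = 7L, ...) {
  sim_config(n_controls = 30L, subtype_sizes = c(40L, 35L, 38L),
             n_hsa21_coding = 30L, gene_cluster_sizes = c(20L, 10L),
             n_background_genes = 50L, seed = seed, ...)
}

.fixture_env <- new.env()
get_small_cohort <- function() {
  if (is.null(.fixture_env$coh)) {
    .fixture_env$coh <- simulate_cohort(small_config())
  }
  .fixture_env$coh
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2)); n2 <- choose(sum(tab), 2)
  e <- si * sj / n2
  (sij - e) / ((si + sj) / 2 - e)
}

# BH step-up by the definition: q_i = min over thresholds t >= p_i of
# t * m / rank(t), computed by an O(m^2) scan.
oracle_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    cands <- vapply(seq_len(m), function(j) {
      if (sp[j] >= pi) sp[j] * m / j else Inf
    }, 0)
    min(1, min(cands))
  }, 0)
}

# Spearman rho via the 6*sum(d^2) formula (tie-free data only).
oracle_spearman_6d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Fisher two-sided p by full enumeration of tables with the observed margins,
# probabilities from factorials directly.
oracle_fisher <- function(tb) {
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ])
  c1 <- sum(tb[, 1]); n <- sum(tb)
  lprob <- function(a) {
    b <- r1 - a; c_ <- c1 - a; d <- r2 - c_
    if (b < 0 || c_ < 0 || d < 0) return(-Inf)
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(n - c1 + 1) -
      lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(c_ + 1) -
      lgamma(d + 1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(support, lprob, 0)
  p_obs <- lp[support == tb[1, 1]]
  sum(exp(lp[lp <= p_obs + 1e-7]))
}

# Exact two-sided Wilcoxon p by enumeration of all assignments of ranks.
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# 3*IQR outlier mask by explicit per-group, per-feature enumeration.
oracle_iqr_mask <- function(m, groups, k = 3, min_n = 4L) {
  for (g in unique(groups)) {
    cols <- which(groups == g)
    for (i in seq_len(nrow(m))) {
      x <- m[i, cols]
      if (sum(!is.na(x)) < min_n) next
      q1 <- stats::quantile(x, 0.25, na.rm = TRUE, type = 7, names = FALSE)
      q3 <- stats::quantile(x, 0.75, na.rm = TRUE, type = 7, names = FALSE)
      lo <- q1 - k * (q3 - q1); hi <- q3 + k * (q3 - q1)
      for (j in seq_along(cols)) {
        v <- m[i, cols[j]]
        if (!is.na(v) && (v < lo || v > hi)) m[i, cols[j]] <- NA_real_
      }
    }
  }
  m
}

# Slow reference GSEA enrichment score: literal running-sum walk.
oracle_gsea_es <- function(ranking, set) {
  ord <- order(-ranking, names(ranking))
  genes <- names(ranking)[ord]
  scores <- unname(ranking[ord])
  hits <- genes %in% set
  nr <- sum(abs(scores[hits]))
  n <- length(genes); nh <- sum(hits)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- if (hits[i]) run + abs(scores[i]) / nr else run - 1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}
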