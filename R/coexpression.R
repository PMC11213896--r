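# Gene-gene Spearman correlation structure of HSA21 genes and the two-cluster
# partition.

# Spearman rho/p for all row pairs of a matrix, pairwise-complete.
# p-values from the t approximation with n-2 degrees of freedom.
spearman_matrix <- function(x) {
  n_pairs <- crossprod(t(!is.na(x)))
  ranks <- t(apply(x, 1L, function(v) {
    r <- v
    ok <- !is.na(v)
    r[ok] <- rank(v[ok])
    r
  }))
  rho <- suppressWarnings(
    stats::cor(t(ranks), method = "pearson", use = "pairwise.complete.obs"))
  # pairwise-complete ranks are only exact when missingness is aligned;
  # recompute cells with any missing data from scratch
  if (anyNA(x)) {
    miss <- which(is.na(x), arr.ind = TRUE)
    bad_rows <- unique(miss[, 1L])
    for (i in bad_rows) {
      for (j in seq_len(nrow(x))) {
        if (i == j) next
        ok <- !is.na(x[i, ]) & !is.na(x[j, ])
        rho[i, j] <- rho[j, i] <- if (sum(ok) >= 3L) {
          suppressWarnings(stats::cor(rank(x[i, ok]), rank(x[j, ok])))
        } else {
          NA_real_
        }
      }
    }
  }
  rho[n_pairs < 3L] <- NA_real_
  diag(rho) <- 1
  tt <- rho * sqrt(pmax(n_pairs - 2L, 0L) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = pmax(n_pairs - 2L, 1L))
  p[abs(rho) >= 1] <- 0
  diag(p) <- NA_real_
  list(rho = rho, p = p, n_pairs = n_pairs)
}

#' Pairwise Spearman correlation matrix of genes
#'
#' Computes all pairwise Spearman correlations (average ranks for ties) among
#' the requested genes across samples, two-sided p-values via the
#' t-approximation, and Benjamini-Hochberg q-values over the upper triangle
#' (diagonal excluded). Cells with fewer than 3 complete pairs are masked.
#'
#' @param z A `zscore_matrix` (typically restricted to T21 samples) or plain
#'   feature x sample matrix.
#' @param genes Gene ids (rows) to correlate; defaults to all rows.
#' @return Object of class `correlation_matrix`: list with `rho`, `p`, `q`,
#'   `n_pairs` (all gene x gene matrices).
#' @export
correlation_matrix <- function(z, genes = NULL) {
  x <- as_z_matrix(z)
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(x))
    if (length(missing_g) > 0L) {
      stop("gene(s) not present: ",
           paste(utils::head(missing_g, 5L), collapse = ", "), call. = FALSE)
    }
    x <- x[genes, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 genes", call. = FALSE)
  sm <- spearman_matrix(x)
  ut <- upper.tri(sm$p)
  q <- matrix(NA_real_, nrow(sm$p), ncol(sm$p), dimnames = dimnames(sm$p))
  pv <- sm$p[ut]
  qv <- rep(NA_real_, length(pv))
  qv[!is.na(pv)] <- bh_adjust(pv[!is.na(pv)])
  q[ut] <- qv
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(list(rho = sm$rho, p = sm$p, q = q, n_pairs = sm$n_pairs),
            class = "correlation_matrix")
}

#' Partition genes into co-expression clusters
#'
#' Agglomerative hierarchical clustering of genes with distance `1 - rho`
#' (sign-preserving, so anti-correlated gene groups are separated) and average
#' linkage; the tree is cut at `k` clusters. Genes are put in a canonical
#' (alphabetical) order before linkage, making the result invariant to input
#' order. Cluster 1 is the larger cluster (ties broken by the lexicographically
#' smallest member id).
#'
#' @param c A `correlation_matrix`.
#' @param k Number of clusters; default 2.
#' @return List with `assignment` (named integer vector of cluster labels),
#'   `sizes`, and the `hclust` tree.
#' @export
cluster_genes <- function(c, k = 2L) {
  stopifnot(inherits(c, "correlation_matrix"))
  rho <- c$rho
  masked <- rowSums(is.na(rho)) >= (ncol(rho) - 1L)
  if (any(masked)) {
    stop("fully-masked correlation rows for gene(s): ",
         paste(utils::head(rownames(rho)[masked], 5L), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(rownames(rho))
  rho <- rho[ord, ord]
  d <- stats::as.dist(1 - rho)
  tree <- stats::hclust(d, method = "average")
  raw <- stats::cutree(tree, k = k)
  # relabel: cluster 1 = largest; ties -> cluster containing the smallest id
  sizes <- table(raw)
  min_id <- vapply(seq_len(k), function(cl) min(names(raw)[raw == cl]), "")
  new_order <- order(-as.integer(sizes), min_id)
  relabel <- integer(k)
  relabel[new_order] <- seq_len(k)
  assignment <- relabel[raw]
  names(assignment) <- names(raw)
  list(assignment = assignment,
       sizes = as.integer(table(assignment)),
       tree = tree)
}

#' Strongest positive and negative correlation partners per gene cluster
#'
#' For each cluster, returns the `n` largest positive and `n` most negative
#' correlation pairs involving at least one gene of that cluster; symmetric
#' duplicates are never repeated and ties are broken deterministically by
#' gene id.
#'
#' @param c A `correlation_matrix`.
#' @param a A cluster assignment from [cluster_genes()].
#' @param n Number of pairs per direction per cluster (must be >= 1).
#' @return data.frame: cluster, direction, gene_a, gene_b, rho, q.
#' @export
top_partner_table <- function(c, a, n = 5L) {
  stopifnot(inherits(c, "correlation_matrix"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  assignment <- a$assignment
  g <- rownames(c$rho)
  ut <- which(upper.tri(c$rho), arr.ind = TRUE)
  pairs <- data.frame(gene_a = g[ut[, 1L]], gene_b = g[ut[, 2L]],
                      rho = c$rho[ut], q = c$q[ut],
                      stringsAsFactors = FALSE)
  pairs <- pairs[!is.na(pairs$rho), , drop = FALSE]
  out <- list()
  for (cl in sort(unique(assignment))) {
    members <- names(assignment)[assignment == cl]
    sub <- pairs[pairs$gene_a %in% members | pairs$gene_b %in% members, ,
                 drop = FALSE]
    for (dir in c("positive", "negative")) {
      cand <- if (dir == "positive") {
        sub[sub$rho > 0, , drop = FALSE]
      } else {
        sub[sub$rho < 0, , drop = FALSE]
      }
      cand <- cand[order(-abs(cand$rho), cand$gene_a, cand$gene_b), ,
                   drop = FALSE]
      if (nrow(cand) < n) {
        warning("cluster ", cl, ": only ", nrow(cand), " ", dir,
                " pair(s) available", call. = FALSE)
      }
      top <- utils::head(cand, n)
      if (nrow(top) > 0L) {
        top$cluster <- cl
        top$direction <- dir
        out[[length(out) + 1L]] <- top
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("cluster", "direction", "gene_a", "gene_b", "rho", "q")]
}
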