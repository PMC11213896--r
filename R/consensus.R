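# Resampling-based consensus clustering of samples, with CDF/delta-area
# k-selection (Monti-style), implemented from scratch.

#' Resampling consensus clustering of samples
#'
#' For each of `n_iter` iterations, `ceiling(p_item * n)` samples are drawn
#' without replacement; sample-sample distances are `1 - Spearman rho` over
#' features; the average-linkage tree is cut at each `k` in `2..maxK`. The
#' consensus index of a sample pair at a given `k` is the number of times the
#' pair co-clustered divided by the number of times it was co-drawn. Because
#' per-sample feature ranks do not depend on which other samples are drawn,
#' the full sample-sample Spearman matrix is computed once and subset per
#' iteration.
#'
#' @param z A `zscore_matrix` (features x samples; typically HSA21 gene
#'   z-scores of T21 samples) or a plain matrix.
#' @param maxK Largest number of clusters to evaluate (k = 2..maxK).
#' @param n_iter Number of subsampling iterations; default 100.
#' @param p_item Fraction of samples drawn per iteration, in (0, 1];
#'   default 0.8. All features are retained in every iteration.
#' @param seed RNG seed for the subsampling stream.
#' @return Object of class `consensus_result`: list with `consensus` (list of
#'   per-k sample x sample matrices, entries in `[0,1]`, unit diagonal),
#'   `draw_counts`, and the run parameters.
#' @export
run_consensus <- function(z, maxK = 6L, n_iter = 100L, p_item = 0.8,
                          seed = NULL) {
  x <- as_z_matrix(z)
  n <- ncol(x)
  if (nrow(x) < 2L) stop("need at least 2 features", call. = FALSE)
  if (n < 2L * maxK) stop("need at least 2*maxK samples", call. = FALSE)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (p_item <= 0 || p_item > 1) stop("p_item must be in (0, 1]", call. = FALSE)
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  if (anyNA(rho)) stop("sample-sample correlations contain NA", call. = FALSE)
  n_sub <- ceiling(p_item * n)
  draw <- matrix(0L, n, n)
  conn <- lapply(2:maxK, function(k) matrix(0L, n, n))
  names(conn) <- as.character(2:maxK)
  run <- function() {
    for (it in seq_len(n_iter)) {
      idx <- sort(sample.int(n, n_sub))
      draw[idx, idx] <<- draw[idx, idx] + 1L
      h <- stats::hclust(stats::as.dist(1 - rho[idx, idx]), method = "average")
      cuts <- stats::cutree(h, k = 2:maxK)
      for (k in 2:maxK) {
        cl <- cuts[, as.character(k)]
        for (c_ in unique(cl)) {
          mem <- idx[cl == c_]
          conn[[as.character(k)]][mem, mem] <<-
            conn[[as.character(k)]][mem, mem] + 1L
        }
      }
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  never <- draw == 0 & upper.tri(draw)
  if (any(never)) {
    warning(sum(never), " sample pair(s) never co-drawn; consensus set to 0",
            call. = FALSE)
  }
  consensus <- lapply(conn, function(co) {
    m <- ifelse(draw > 0, co / draw, 0)
    diag(m) <- 1
    dimnames(m) <- list(colnames(x), colnames(x))
    m
  })
  structure(list(consensus = consensus, draw_counts = draw, maxK = maxK,
                 n_iter = n_iter, p_item = p_item, seed = seed,
                 sample_ids = colnames(x)),
            class = "consensus_result")
}

#' Consensus CDFs, areas, and delta-area curve
#'
#' The empirical CDF of the upper-triangle consensus values is integrated
#' exactly over `[0, 1]` (the CDF is a step function). `A(k)` is that area;
#' `delta(2) = A(2)` and `delta(k) = (A(k) - A(k-1)) / A(k-1)` for `k > 2`
#' (relative change in the area under the CDF).
#'
#' @param cr A `consensus_result`.
#' @return List with `cdf` (per-k list of `stats::ecdf` functions), `area`
#'   (named numeric `A(k)`), and `delta` (named numeric `delta(k)`).
#' @export
consensus_cdf_and_area <- function(cr) {
  stopifnot(inherits(cr, "consensus_result"))
  ks <- as.integer(names(cr$consensus))
  area <- numeric(length(ks))
  cdf <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    v <- cr$consensus[[i]][upper.tri(cr$consensus[[i]])]
    Fn <- stats::ecdf(v)
    xs <- sort(unique(c(0, v, 1)))
    # exact integral of the right-continuous step CDF over [0, 1]
    area[i] <- sum(diff(xs) * Fn(xs[-length(xs)]))
    cdf[[i]] <- Fn
  }
  names(area) <- names(cdf) <- as.character(ks)
  delta <- numeric(length(ks))
  delta[1L] <- area[1L]
  if (length(ks) > 1L) {
    delta[-1L] <- diff(area) / area[-length(area)]
  }
  names(delta) <- as.character(ks)
  list(cdf = cdf, area = area, delta = delta)
}

#' Select the number of clusters by the delta-area rule
#'
#' Returns the `k >= k_min` maximizing the relative change in area under the
#' consensus CDF; ties go to the smaller `k`. `delta(2) = A(2)` lives on a
#' different scale than the relative changes, hence the default `k_min = 3`.
#' A manual override is supported via `k`.
#'
#' @param cr A `consensus_result` (or the list from
#'   [consensus_cdf_and_area()]).
#' @param k_min Smallest k considered; default 3.
#' @param k Optional manual override; returned as-is after range checking.
#' @return Selected number of clusters (integer).
#' @export
select_k <- function(cr, k_min = 3L, k = NULL) {
  ca <- if (inherits(cr, "consensus_result")) consensus_cdf_and_area(cr) else cr
  ks <- as.integer(names(ca$delta))
  if (!is.null(k)) {
    if (!(k %in% ks)) stop("override k outside evaluated range", call. = FALSE)
    return(as.integer(k))
  }
  if (max(ks) < k_min) stop("maxK < k_min; widen the consensus run",
                            call. = FALSE)
  cand <- ks[ks >= k_min]
  d <- ca$delta[as.character(cand)]
  cand[which.max(d)]   # which.max takes the first (smallest k) on ties
}

#' Assign samples to molecular subtypes from the consensus matrix
#'
#' Cuts the average-linkage tree of the `1 - consensus` distance at `k`.
#' Cluster labels are anchored by phenotype: when `anchor_scores` (per-sample
#' cluster-1 polygenic scores) are supplied, labels are ordered by descending
#' group mean score, so MS1 has the highest cluster-1 expression. Without
#' scores, labels are ordered by descending cluster size.
#'
#' @param cr A `consensus_result`.
#' @param k Number of subtypes (e.g. from [select_k()]).
#' @param anchor_scores Optional named numeric vector of per-sample scores
#'   used to order the subtype labels.
#' @return Named character vector: sample id -> subtype label (`"MS1"`..).
#' @export
assign_subtypes <- function(cr, k, anchor_scores = NULL) {
  stopifnot(inherits(cr, "consensus_result"))
  cons <- cr$consensus[[as.character(k)]]
  if (is.null(cons)) stop("k = ", k, " was not evaluated", call. = FALSE)
  h <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  cl <- stats::cutree(h, k = k)
  if (length(unique(cl)) < k) {
    stop("empty cluster after cut; consider a smaller k", call. = FALSE)
  }
  ids <- cr$sample_ids
  names(cl) <- ids
  key <- if (!is.null(anchor_scores)) {
    if (!all(ids %in% names(anchor_scores))) {
      stop("anchor_scores missing for some samples", call. = FALSE)
    }
    -vapply(seq_len(k), function(c_) mean(anchor_scores[ids[cl == c_]]), 0)
  } else {
    -as.numeric(table(cl))
  }
  relabel <- integer(k)
  relabel[order(key)] <- seq_len(k)
  labels <- paste0("MS", relabel[cl])
  names(labels) <- ids
  labels
}

#' Principal-component projection of samples
#'
#' Singular value decomposition of the feature-centered data; sample scores
#' for the leading components with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive). If the matrix
#' rank is below `n_components`, fewer components are returned with a warning.
#'
#' @param z A `zscore_matrix` or plain feature x sample matrix.
#' @param n_components Number of components requested; default 2.
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components), and `sdev` (component standard deviations).
#' @export
pca_project <- function(z, n_components = 2L) {
  x <- as_z_matrix(z)
  if (nrow(x) < n_components) stop("fewer features than components",
                                   call. = FALSE)
  xc <- x - rowMeans(x)
  sv <- svd(t(xc))                      # samples x features
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1L]
  rank_ <- sum(sv$d > tol)
  nc <- min(n_components, rank_)
  if (nc < n_components) {
    warning("rank ", rank_, " < requested components; returning ", nc,
            call. = FALSE)
  }
  scores <- sv$u[, seq_len(nc), drop = FALSE] %*%
    diag(sv$d[seq_len(nc)], nc, nc)
  loadings <- sv$v[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(nc)))
  dimnames(loadings) <- list(rownames(x), paste0("PC", seq_len(nc)))
  list(scores = scores, loadings = loadings,
       sdev = sv$d[seq_len(nc)] / sqrt(max(ncol(x) - 1L, 1L)))
}
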