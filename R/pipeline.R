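# End-to-end orchestration: simulate (or load) -> preprocess -> gene clusters
# -> consensus subtypes -> composite scores -> differential contrasts ->
# classifier -> longitudinal stability, plus a small CLI wrapper.

#' Run the full subtype-discovery analysis on a cohort
#'
#' Reproduces the analysis chain on an in-memory cohort: covariate-adjusted
#' log2 expression; Spearman co-expression clustering of HSA21 genes (k = 2);
#' consensus clustering of T21 samples on HSA21 z-scores with delta-area
#' k-selection; subtype assignment anchored by the cluster-1 polygenic score;
#' polygenic and cytokine composite scores; differential contrasts (cytokine
#' panel MS3 vs controls/MS1, metabolome and transporter panel MS3 vs MS1);
#' the ratio classifier; and longitudinal stability of the cytokine panel.
#'
#' @param cohort A `t21_cohort` from [simulate_cohort()] (or an equivalent
#'   list with `layers`, `samples`, `config`).
#' @param maxK,n_iter,p_item Consensus-clustering parameters.
#' @param k Optional manual override of the selected number of subtypes.
#' @param seed Seed for the consensus subsampling stream; defaults to a
#'   substream of the cohort's master seed.
#' @return A list of stage results (see components in the source); of class
#'   `t21_analysis`.
#' @export
analyze_cohort <- function(cohort, maxK = 6L, n_iter = 100L, p_item = 0.8,
                           k = NULL, seed = NULL) {
  samples <- cohort$samples
  controls <- samples$sample_id[samples$karyotype == "D21"]
  t21 <- samples$sample_id[samples$karyotype == "T21"]
  if (is.null(seed)) seed <- substream_seed(cohort$config$seed, "consensus")

  ## ---- expression preprocessing ----
  log_expr <- log2_transform(cohort$layers$expression, pseudocount = 1)
  adj_expr <- adjust_covariates(log_expr, samples,
                                covariates = c("age", "sex", "source"))
  hsa21 <- cohort$feature_truth$genes$gene_id[
    cohort$feature_truth$genes$chromosome == "chr21"]

  ## ---- HSA21 gene co-expression clusters (T21 samples) ----
  z_t21 <- zscore_vs_controls(adj_expr[hsa21, t21, drop = FALSE], t21)
  cmat <- correlation_matrix(z_t21)
  gene_clusters <- cluster_genes(cmat, k = 2L)
  cl1_genes <- names(gene_clusters$assignment)[gene_clusters$assignment == 1L]
  cl2_genes <- names(gene_clusters$assignment)[gene_clusters$assignment == 2L]

  ## ---- consensus subtypes ----
  consensus <- run_consensus(z_t21, maxK = maxK, n_iter = n_iter,
                             p_item = p_item, seed = seed)
  cdf_area <- consensus_cdf_and_area(consensus)
  k_sel <- select_k(cdf_area, k_min = 3L, k = k)
  z_vs_d21 <- zscore_vs_controls(adj_expr[hsa21, , drop = FALSE], controls)
  score_c1 <- polygenic_score(z_vs_d21, cl1_genes, name = "hsa21_cluster1")
  score_c2 <- polygenic_score(z_vs_d21, cl2_genes, name = "hsa21_cluster2")
  anchor <- stats::setNames(score_c1$value, score_c1$sample_id)
  subtypes <- assign_subtypes(consensus, k_sel, anchor_scores = anchor)
  samples$subtype <- unname(subtypes[samples$sample_id])
  samples$group <- ifelse(samples$karyotype == "D21", "D21", samples$subtype)

  ## ---- cytokine panel contrasts and score ----
  log_msd <- mask_outliers_iqr(log2_transform(cohort$layers$msd_panel),
                               samples$karyotype)
  msd_vs_d21 <- linear_diff(log_msd, samples, "group", c("D21", "MS3"),
                            covariates = c("age", "sex", "source"))
  msd_vs_ms1 <- linear_diff(log_msd, samples, "group", c("MS1", "MS3"),
                            covariates = c("age", "sex", "source"))
  score_analytes <- select_score_analytes(msd_vs_d21, msd_vs_ms1)
  adj_msd <- adjust_covariates(log_msd, samples,
                               covariates = c("age", "sex", "source"))
  z_msd <- zscore_vs_controls(adj_msd, controls)
  cyt_score <- cytokine_score(z_msd, score_analytes)

  ## ---- metabolome contrast (MS3 vs MS1) ----
  metab <- replace_zeros(cohort$layers$metabolome,
                         seed = substream_seed(cohort$config$seed,
                                               "zero_replacement"))
  metab <- median_normalize(metab)
  log_metab <- mask_outliers_iqr(log2_transform(metab), samples$karyotype)
  metab_ms3_ms1 <- linear_diff(log_metab, samples, "group", c("MS1", "MS3"),
                               covariates = c("age", "sex", "source"))

  ## ---- transporter panel contrast ----
  tc <- cohort$config$transporter_config
  transporters <- c(tc$up, tc$down, tc$null)
  trans_ms3_ms1 <- linear_diff(log_expr[transporters, , drop = FALSE],
                               samples, "group", c("MS1", "MS3"),
                               covariates = c("age", "sex", "source"))

  ## ---- dosage contrast (T21 vs D21, HSA21 genes) ----
  expr_t21_d21 <- linear_diff(log_expr, samples, "karyotype",
                              c("D21", "T21"),
                              covariates = c("age", "sex", "source"))

  ## ---- ratio classifier (inferred subtype truth) ----
  truth <- stats::setNames(samples$subtype[samples$karyotype == "T21"],
                           samples$sample_id[samples$karyotype == "T21"])
  classifier <- classifier_report(cohort$layers, truth, controls)

  ## ---- longitudinal stability ----
  stability <- if (!is.null(cohort$visit2)) {
    longitudinal_stability(cohort$layers$msd_panel[, t21, drop = FALSE],
                           cohort$visit2$msd_panel[, t21, drop = FALSE])
  }

  structure(list(
    samples = samples,
    gene_clusters = gene_clusters,
    correlation = cmat,
    consensus = consensus,
    cdf_area = cdf_area,
    selected_k = k_sel,
    subtypes = subtypes,
    scores = list(cluster1 = score_c1, cluster2 = score_c2,
                  cytokine = cyt_score, analytes = score_analytes),
    contrasts = list(expression_t21_vs_d21 = expr_t21_d21,
                     msd_ms3_vs_d21 = msd_vs_d21,
                     msd_ms3_vs_ms1 = msd_vs_ms1,
                     metabolome_ms3_vs_ms1 = metab_ms3_ms1,
                     transporters_ms3_vs_ms1 = trans_ms3_ms1),
    classifier = classifier,
    stability = stability
  ), class = "t21_analysis")
}

#' @export
print.t21_analysis <- function(x, ...) {
  cat("t21_analysis\n")
  cat("  gene clusters (k=2):", paste(x$gene_clusters$sizes, collapse = "/"),
      "\n")
  cat("  selected k:", x$selected_k, "; subtype sizes:",
      paste(sort(table(x$subtypes), decreasing = TRUE), collapse = "/"), "\n")
  cat("  cytokine-score analytes:",
      paste(x$scores$analytes, collapse = ", "), "\n")
  cat("  classifier:\n")
  print(x$classifier$summary, row.names = FALSE)
  invisible(x)
}

#' Run the pipeline end to end and write artifacts to a directory
#'
#' Simulates a cohort (unless one is supplied), runs [analyze_cohort()], and
#' writes all tables (TSV), the classifier report (JSON), and a manifest
#' recording seeds, per-stage dimensions and file hashes.
#'
#' @param out_dir Output directory.
#' @param config A [sim_config()]; ignored when `cohort` is given.
#' @param cohort Optional pre-built `t21_cohort`.
#' @param ... Passed to [analyze_cohort()].
#' @return The `t21_analysis`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), cohort = NULL, ...) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cohort$config$seed
  write_cohort(cohort, file.path(out_dir, "cohort"))
  res <- analyze_cohort(cohort, ...)

  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(data.frame(gene_id = names(res$gene_clusters$assignment),
                cluster = res$gene_clusters$assignment), "gene_clusters.tsv")
  write_matrix(res$correlation$rho, file.path(out_dir, "hsa21_spearman.tsv"),
               stage = "genecluster", seed = seed)
  for (kk in names(res$consensus$consensus)) {
    write_matrix(res$consensus$consensus[[kk]],
                 file.path(out_dir, sprintf("consensus_k%s.tsv", kk)),
                 stage = "subtype", seed = seed)
  }
  wt(data.frame(k = as.integer(names(res$cdf_area$area)),
                area = res$cdf_area$area, delta = res$cdf_area$delta),
     "consensus_area.tsv")
  wt(data.frame(sample_id = names(res$subtypes), subtype = res$subtypes),
     "subtype_assignments.tsv")
  wt(do.call(rbind, res$scores[c("cluster1", "cluster2", "cytokine")]),
     "composite_scores.tsv")
  for (nm in names(res$contrasts)) {
    wt(res$contrasts[[nm]], paste0("diff_", nm, ".tsv"))
  }
  wt(res$classifier$summary, "classifier_summary.tsv")
  if (!is.null(res$stability)) wt(res$stability, "stability_msd.tsv")
  jsonlite::write_json(
    list(package = "t21subtypes",
         version = as.character(utils::packageVersion("t21subtypes")),
         seed = seed,
         selected_k = res$selected_k,
         n_samples = nrow(cohort$samples),
         layer_dims = lapply(cohort$layers, dim),
         file_md5 = as.list(tools::md5sum(
           list.files(out_dir, full.names = TRUE, pattern = "\\.tsv$")))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

# Minimal flat "key: value" config reader for the CLI (subset of sim_config
# scalar fields; vectors comma-separated).
read_config_kv <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- list()
  for (f in kv) {
    key <- trimws(f[1L])
    val <- trimws(paste(f[-1L], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort) and `run-all` (full
#' pipeline). Options: `--config FILE` (flat key: value overrides for
#' [sim_config()] scalar fields), `--out DIR`, `--seed N`, `--max-k`,
#' `--iters`, `--p-item`, `--k`.
#'
#' @param args Character vector of CLI arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 invisibly.
#' @export
t21subtypes_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: t21subtypes <simulate|run-all> --out DIR [--seed N] [--config FILE] [--max-k K] [--iters N] [--p-item P] [--k K]"
  if (length(args) < 1L) stop(usage, call. = FALSE)
  cmd <- args[1L]
  opt <- list(out = NULL, seed = 1L, config = NULL, `max-k` = 6L,
              iters = 100L, `p-item` = 0.8, k = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i], call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(opt$out)) stop(usage, call. = FALSE)
  overrides <- if (!is.null(opt$config)) read_config_kv(opt$config) else list()
  overrides$seed <- as.integer(opt$seed)
  cfg_args <- overrides[names(overrides) %in% names(formals(sim_config))]
  config <- do.call(sim_config, cfg_args)
  if (cmd == "simulate") {
    write_cohort(simulate_cohort(config), opt$out)
  } else if (cmd == "run-all") {
    run_pipeline(opt$out, config = config,
                 maxK = as.integer(opt$`max-k`),
                 n_iter = as.integer(opt$iters),
                 p_item = as.numeric(opt$`p-item`),
                 k = if (!is.null(opt$k)) as.integer(opt$k))
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}
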