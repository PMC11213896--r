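# Synthetic multiomics cohort generator.
#
# The generator plants, in a fully specified way, the statistical structure the
# downstream analysis assumes: a 1.5x chromosome-21 dosage effect with
# per-gene/per-individual variegation, two anti-correlated HSA21 co-expression
# clusters (97 + 29 genes), three latent molecular subtypes (107/95/102) with
# graded cluster-1/cluster-2 expression, an MS3-specific acute-phase/cytokine
# elevation, graded amino-acid depletion with exactly nine MS3-vs-MS1 depleted
# metabolites, an amino-acid transporter panel with 18 up / 12 down planted
# effects, MS3 neutrophilia with lymphopenia, covariate effects, and
# analyte-specific longitudinal stability.

SUBTYPES <- c("MS1", "MS2", "MS3")

# ---- default sub-configurations ---------------------------------------------

#' @rdname sim_config
#' @export
default_panel_config <- function() {
  score7 <- c("IL-6", "CRP", "SAA", "IL-22", "MIP-3alpha", "IL-15", "IL-1RN")
  msd_common <- c("IL-10", "TSLP", "TNF-alpha")
  msd_ms1 <- c("IL-8", "Eotaxin", "FGF-basic")
  msd_null <- c("IL12/23p40", "IP-10", "IL-31", "IL-17B", "IL-4", "IL-27",
                "MIP-1beta", "VEGF-A", "IL-13", "IL-2", "IL-5", "IL-7",
                "IL-16", "IL-12p70", "TARC", "MDC", "MCP-1", "MCP-4",
                "TNF-beta", "IFN-gamma")
  msd_shifts <- rbind(
    matrix(rep(c(0.4, 0.4, 2.2), each = length(score7)), ncol = 3,
           dimnames = list(score7, SUBTYPES)),
    matrix(1, length(msd_common), 3, dimnames = list(msd_common, SUBTYPES)),
    matrix(rep(c(1, 0, 0), each = length(msd_ms1)), ncol = 3,
           dimnames = list(msd_ms1, SUBTYPES)),
    matrix(0, length(msd_null), 3, dimnames = list(msd_null, SUBTYPES))
  )
  soma_classifier <- c("CRP", "IL-6", "SAA1")
  soma_ms3 <- c("SAA2", "IL-1RN", "LCN2", "PROK2", "BPI", "MPO", "PRTN3")
  soma_null <- sprintf("SOMA.P%02d", 1:30)
  soma_shifts <- rbind(
    matrix(rep(c(0.4, 0.4, 3.6), each = 3), ncol = 3,
           dimnames = list(soma_classifier, SUBTYPES)),
    matrix(rep(c(0.3, 0.3, 1.5), each = length(soma_ms3)), ncol = 3,
           dimnames = list(soma_ms3, SUBTYPES)),
    matrix(0, length(soma_null), 3, dimnames = list(soma_null, SUBTYPES))
  )
  list(score_analytes = score7,
       msd = list(shifts = msd_shifts, noise_sd = 0.5),
       soma = list(shifts = soma_shifts, noise_sd = 0.5))
}

#' @rdname sim_config
#' @export
default_metab_config <- function() {
  planted <- c("asparagine", "serine", "proline", "alanine", "threonine",
               "histidine", "L-citrulline", "gamma-L-glutamyl-D-alanine",
               "glycine")
  other_aa <- c("glutamine", "valine", "leucine", "isoleucine", "lysine",
                "methionine", "phenylalanine", "tryptophan", "tyrosine",
                "arginine", "aspartate")
  list(planted = planted,
       n_planted = length(planted),
       other_amino_acids = other_aa,
       n_other_features = 80L,
       t21_log2fc = -0.3,             # shared amino-acid depletion in all T21
       planted_gradient = c(0, -0.3, -0.7),  # extra shift per subtype
       noise_sd = 0.3,
       zero_rate = 0.005)
}

#' @rdname sim_config
#' @export
default_transporter_config <- function() {
  up <- c("SLC15A3", "SLC15A4", "SLC66A1", "SLC1A5", "SLC38A10", "SLC1A4",
          "SLC7A5", "SLC38A1", "SLC38A2", "SLC43A1", "SLC6A14", "SLC7A8",
          "SLC36A1", "SLC36A4", "SLC38A5", "SLC38A7", "SLC7A7", "SLC3A2")
  down <- c("SLC7A6", "SLC43A2", "SLC38A3", "SLC6A19", "SLC16A10", "SLC7A11",
            "SLC25A13", "SLC38A4", "SLC36A2", "SLC6A15", "SLC7A9", "SLC38A9")
  list(up = up, down = down, null = "SLC38A6", effect_log2fc = 0.4)
}

#' @rdname sim_config
#' @export
default_cell_config <- function() {
  base <- c(Neutrophils = 0.50, Lymphocytes_T = 0.20, Lymphocytes_B = 0.08,
            NK = 0.06, Monocytes_classical = 0.08,
            Monocytes_inflammatory = 0.02, Eosinophils = 0.04,
            Basophils = 0.02)
  shifts <- matrix(0, length(base), 3, dimnames = list(names(base), SUBTYPES))
  shifts["Basophils", ] <- 0.5          # elevated in all subtypes
  shifts["Eosinophils", ] <- -0.4       # depleted in all subtypes
  shifts["Neutrophils", "MS3"] <- 1.5   # MS3 neutrophilia
  shifts["Lymphocytes_T", "MS3"] <- -0.7
  shifts["Lymphocytes_B", "MS3"] <- -0.7
  shifts["Monocytes_inflammatory", "MS3"] <- 0.8
  list(base = base, shifts = shifts, noise_sd = 0.3)
}

#' @rdname sim_config
#' @export
default_cbc_config <- function() {
  baseline <- c(WBC = 6, RBC = 4.5, Hgb = 13.5, Hct = 40, MCV = 90, MCH = 30,
                MCHC = 33, Platelets = 250, Lymphocytes_abs = 2.2,
                Lymphocytes_pct = 32, Neutrophils_abs = 3.5,
                Neutrophils_pct = 55)
  shifts <- matrix(0, length(baseline), 3,
                   dimnames = list(names(baseline), SUBTYPES))
  shifts["MCV", ] <- 1.5                # macrocytosis in all subtypes
  shifts["MCH", ] <- 1.5
  shifts["RBC", ] <- c(-0.5, 0, -0.5)
  shifts["WBC", ] <- c(-0.5, -0.5, 0)
  shifts["Lymphocytes_abs", ] <- c(-0.3, -0.3, -1.2)
  shifts["Lymphocytes_pct", ] <- c(-0.3, -0.3, -1.2)
  shifts["Neutrophils_abs", ] <- c(0, 0, 0.8)
  shifts["Neutrophils_pct", ] <- c(0, 0, 0.8)
  list(baseline_log2 = log2(baseline), shifts = shifts, noise_sd = 0.3)
}

#' @rdname sim_config
#' @export
default_stability_rho <- function() {
  pc <- default_panel_config()
  msd <- structure(rep(0.6, nrow(pc$msd$shifts)),
                   names = rownames(pc$msd$shifts))
  msd[pc$score_analytes] <- 0.85
  msd[c("IP-10", "IL12/23p40", "IL-31")] <- 0.85
  msd[c("FGF-basic", "IL-17B", "IL-4")] <- 0.2
  cbc <- structure(rep(0.6, 12),
                   names = names(default_cbc_config()$baseline_log2))
  cbc[c("Platelets", "MCV", "Lymphocytes_abs", "Lymphocytes_pct", "WBC")] <- 0.8
  list(msd_panel = msd, cbc = cbc)
}

# ---- configuration -----------------------------------------------------------

#' Configuration for the synthetic multiomics cohort generator
#'
#' Returns a validated configuration object consumed by [simulate_cohort()] and
#' the individual `simulate_*()` layer generators. Defaults encode the cohort
#' structure the pipeline is designed around: 96 euploid (D21) controls, three
#' trisomic (T21) molecular subtypes of sizes 107/95/102, 126 HSA21
#' protein-coding genes split into co-expression clusters of 97 and 29 genes,
#' a chromosome dosage effect of log2(1.5), and per-layer planted subtype
#' effects (see `default_panel_config()` and friends).
#'
#' @param n_controls Number of euploid control samples.
#' @param subtype_sizes Integer vector of length 3: samples per molecular
#'   subtype MS1..MS3.
#' @param n_hsa21_coding Number of HSA21 protein-coding genes simulated.
#' @param gene_cluster_sizes Sizes of HSA21 co-expression clusters 1 and 2;
#'   their sum must not exceed `n_hsa21_coding` (remaining genes are
#'   unassigned).
#' @param n_background_genes Number of non-HSA21 background genes.
#' @param dosage_log2fc Log2 fold change of HSA21 genes in T21 vs D21.
#' @param cluster_effects 3 x 2 numeric matrix (subtypes x gene clusters) of
#'   log2 expression modifiers, or a single number recycled. Rows MS1..MS3.
#' @param subtype_gene_sd SD of the per-gene, per-subtype deviation around the
#'   cluster-level modifier (drawn once per cohort). This is the variegation
#'   term: it gives every subtype its own high-dimensional HSA21 signature
#'   rather than a rank-one gradient, which is what makes the intermediate
#'   subtype identifiable by profile correlation.
#' @param latent_loading Strength in `[0, 1]` of the shared per-individual
#'   latent factor that loads positively on cluster 1 and negatively on
#'   cluster 2 genes.
#' @param noise_sd Residual log2 SD of expression noise.
#' @param covariate_effects Named list of per-layer coefficient SDs for age,
#'   sex, and sample source effects.
#' @param panel_config,metab_config,transporter_config,cell_config,cbc_config
#'   Layer-specific planted-effect configurations; see the corresponding
#'   `default_*_config()` functions.
#' @param stability_rho Per-analyte longitudinal correlation targets for the
#'   revisit generator, as a list of named vectors per layer.
#' @param seed Master RNG seed. Each layer draws from an independently derived
#'   substream, so adding a layer never perturbs the others.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_controls = 96L,
                       subtype_sizes = c(107L, 95L, 102L),
                       n_hsa21_coding = 126L,
                       gene_cluster_sizes = c(97L, 29L),
                       n_background_genes = 2000L,
                       dosage_log2fc = log2(1.5),
                       cluster_effects = rbind(c(0.45, -0.2),
                                               c(0.00, -0.2),
                                               c(-0.45, 0.45)),
                       subtype_gene_sd = 0.2,
                       latent_loading = 0.1,
                       noise_sd = 0.25,
                       covariate_effects = list(
                         expression = c(age = 0.003, sex = 0.08, source = 0.12),
                         panels     = c(age = 0.002, sex = 0.05, source = 0.10),
                         metabolome = c(age = 0.002, sex = 0.05, source = 0.10),
                         cbc        = c(age = 0.002, sex = 0.05, source = 0.08)),
                       panel_config = default_panel_config(),
                       metab_config = default_metab_config(),
                       transporter_config = default_transporter_config(),
                       cell_config = default_cell_config(),
                       cbc_config = default_cbc_config(),
                       stability_rho = default_stability_rho(),
                       seed = 1L) {
  if (length(cluster_effects) == 1L) {
    cluster_effects <- matrix(cluster_effects, 3, 2)
  }
  cluster_effects <- as.matrix(cluster_effects)
  dimnames(cluster_effects) <- list(SUBTYPES, c("cluster1", "cluster2"))
  stopifnot(length(subtype_sizes) == 3L)
  counts <- c(n_controls, subtype_sizes, n_hsa21_coding, gene_cluster_sizes,
              n_background_genes)
  if (any(counts <= 0)) stop("all counts must be > 0", call. = FALSE)
  if (sum(gene_cluster_sizes) > n_hsa21_coding) {
    stop("gene_cluster_sizes exceed n_hsa21_coding", call. = FALSE)
  }
  if (latent_loading < 0 || latent_loading > 1) {
    stop("latent_loading must be in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (subtype_gene_sd < 0) stop("subtype_gene_sd must be >= 0", call. = FALSE)
  for (layer in c("msd", "soma")) {
    an <- rownames(panel_config[[layer]]$shifts)
    if (anyDuplicated(an)) {
      stop("duplicate analyte names in panel_config$", layer, call. = FALSE)
    }
  }
  n_aa <- length(metab_config$planted) + length(metab_config$other_amino_acids)
  if (metab_config$n_planted > n_aa) {
    stop("metab_config n_planted exceeds number of amino-acid features",
         call. = FALSE)
  }
  if (length(cell_config$base) < 2L) {
    stop("cell composition needs >= 2 categories", call. = FALSE)
  }
  structure(list(
    n_controls = as.integer(n_controls),
    subtype_sizes = as.integer(subtype_sizes),
    n_hsa21_coding = as.integer(n_hsa21_coding),
    gene_cluster_sizes = as.integer(gene_cluster_sizes),
    n_background_genes = as.integer(n_background_genes),
    dosage_log2fc = dosage_log2fc,
    cluster_effects = cluster_effects,
    subtype_gene_sd = subtype_gene_sd,
    latent_loading = latent_loading,
    noise_sd = noise_sd,
    covariate_effects = covariate_effects,
    panel_config = panel_config,
    metab_config = metab_config,
    transporter_config = transporter_config,
    cell_config = cell_config,
    cbc_config = cbc_config,
    stability_rho = stability_rho,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_controls, "controls +",
      paste(x$subtype_sizes, collapse = "/"),
      "T21 subtype samples;", x$n_hsa21_coding, "HSA21 genes (clusters",
      paste(x$gene_cluster_sizes, collapse = "/"), ") +",
      x$n_background_genes, "background genes; seed", x$seed, "\n")
  invisible(x)
}

# ---- samples -----------------------------------------------------------------

#' Simulate the sample metadata table
#'
#' Karyotype, ground-truth subtype, age (Uniform 6-57 years), sex (balanced),
#' and sample source (two sites, A/B). Sample order is shuffled so no method
#' can exploit block ordering.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `sample_id`, `karyotype`, `subtype_truth`,
#'   `age`, `sex`, `source`, `visit`.
#' @export
simulate_samples <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "samples"), {
    n_t21 <- sum(config$subtype_sizes)
    n <- config$n_controls + n_t21
    karyotype <- c(rep("D21", config$n_controls), rep("T21", n_t21))
    subtype <- c(rep(NA_character_, config$n_controls),
                 rep(SUBTYPES, times = config$subtype_sizes))
    perm <- sample.int(n)
    data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      karyotype = karyotype[perm],
      subtype_truth = subtype[perm],
      age = round(stats::runif(n, 6, 57), 1),
      sex = sample(c("Female", "Male"), n, replace = TRUE),
      source = sample(c("A", "B"), n, replace = TRUE),
      visit = 1L,
      stringsAsFactors = FALSE
    )
  })
}

# Named gene ids for the two HSA21 clusters; synthetic ids beyond the named set.
hsa21_gene_ids <- function(config) {
  c1_named <- c("PAXBP1", "BRWD1", "N6AMT1", "ATP5PF", "GABPA", "TTC3",
                "PRDM15", "EVA1C", "PSMG1", "NDUFV3")
  c2_named <- c("IFNGR2", "IL10RB", "KCNJ15", "IFNAR1", "ITGB2", "MX2",
                "SLC19A1", "PTTG1IP")
  take <- function(n, named, prefix) {
    k <- min(n, length(named))
    c(named[seq_len(k)],
      if (n > k) sprintf("%s.%03d", prefix, seq_len(n - k) + k))
  }
  sizes <- config$gene_cluster_sizes
  n_un <- config$n_hsa21_coding - sum(sizes)
  list(cluster1 = take(sizes[1L], c1_named, "C1"),
       cluster2 = take(sizes[2L], c2_named, "C2"),
       unassigned = if (n_un > 0) sprintf("C0.%03d", seq_len(n_un)))
}

# Per-feature covariate coefficient draws and their sample-level contribution.
covariate_contribution <- function(n_features, samples, sds) {
  beta_age <- stats::rnorm(n_features, 0, sds[["age"]])
  beta_sex <- stats::rnorm(n_features, 0, sds[["sex"]])
  beta_src <- stats::rnorm(n_features, 0, sds[["source"]])
  outer(beta_age, samples$age - 31.5) +
    outer(beta_sex, as.numeric(samples$sex == "Male")) +
    outer(beta_src, as.numeric(samples$source == "B"))
}

# ---- expression --------------------------------------------------------------

#' Simulate the whole-blood expression layer
#'
#' Expression is modelled in log2 space as baseline + chromosome dosage (T21
#' samples, HSA21 genes) + subtype-by-cluster modifier + a shared latent factor
#' loading positively on cluster-1 and negatively on cluster-2 genes +
#' covariate effects + Gaussian noise, then returned on a positive linear
#' (RPKM-like) scale. The amino-acid transporter panel and background genes are
#' appended as non-HSA21 features; transporter genes carry the configured
#' MS3-vs-MS1 effects.
#'
#' @param config A [sim_config()].
#' @param samples Sample table from [simulate_samples()]; defaults to
#'   regenerating it from `config` (deterministic).
#' @return A list with `values` (genes x samples linear-scale matrix) and
#'   `truth` (data.frame: gene_id, chromosome, cluster, dosage_log2fc,
#'   transporter_log2fc).
#' @export
simulate_expression <- function(config, samples = simulate_samples(config)) {
  stopifnot(inherits(config, "sim_config"))
  ids <- hsa21_gene_ids(config)
  tc <- config$transporter_config
  transporters <- c(tc$up, tc$down, tc$null)
  genes <- c(ids$cluster1, ids$cluster2, ids$unassigned, transporters,
             sprintf("BG.%04d", seq_len(config$n_background_genes)))
  if (anyDuplicated(genes)) stop("duplicated gene ids", call. = FALSE)
  G <- length(genes)
  N <- nrow(samples)
  is_h21 <- genes %in% c(ids$cluster1, ids$cluster2, ids$unassigned)
  cluster <- ifelse(genes %in% ids$cluster1, 1L,
                    ifelse(genes %in% ids$cluster2, 2L, NA_integer_))
  transporter_fc <- ifelse(genes %in% tc$up, tc$effect_log2fc,
                           ifelse(genes %in% tc$down, -tc$effect_log2fc, 0))

  with_seed(substream_seed(config$seed, "expression"), {
    baseline <- stats::runif(G, 2, 8)
    # HSA21 genes sit above the pseudocount regime (detected, moderately to
    # highly expressed in whole blood) so log2(x + 1) barely attenuates the
    # dosage ratio
    baseline[is_h21] <- stats::runif(sum(is_h21), 4, 9)
    logx <- matrix(baseline, G, N)
    t21 <- samples$karyotype == "T21"
    # chromosome dosage
    logx[is_h21, t21] <- logx[is_h21, t21] + config$dosage_log2fc
    # per-gene, per-subtype deviation around the cluster-level modifier
    # (drawn once per cohort; the variegation term)
    eta <- matrix(stats::rnorm(sum(is_h21) * 3L, 0, config$subtype_gene_sd),
                  sum(is_h21), 3L, dimnames = list(genes[is_h21], SUBTYPES))
    # subtype x gene-cluster modifiers, and transporter MS3 effects
    for (s in seq_along(SUBTYPES)) {
      cols <- which(!is.na(samples$subtype_truth) &
                      samples$subtype_truth == SUBTYPES[s])
      for (cl in 1:2) {
        rows <- which(!is.na(cluster) & cluster == cl)
        logx[rows, cols] <- logx[rows, cols] + config$cluster_effects[s, cl]
      }
      logx[is_h21, cols] <- logx[is_h21, cols] + eta[, s]
      if (SUBTYPES[s] == "MS3") {
        rows <- which(transporter_fc != 0)
        logx[rows, cols] <- logx[rows, cols] + transporter_fc[rows]
      }
    }
    # shared latent factor (per-gene magnitude drawn once per cohort)
    lam <- numeric(G)
    draw <- stats::runif(G, 0.5, 1)   # consumed for all genes to keep streams stable
    lam[!is.na(cluster) & cluster == 1L] <-
      config$latent_loading * draw[!is.na(cluster) & cluster == 1L]
    lam[!is.na(cluster) & cluster == 2L] <-
      -config$latent_loading * draw[!is.na(cluster) & cluster == 2L]
    f <- ifelse(t21, stats::rnorm(N), 0)
    logx <- logx + lam %o% f
    logx <- logx + covariate_contribution(G, samples,
                                          config$covariate_effects$expression)
    logx <- logx + matrix(stats::rnorm(G * N, 0, config$noise_sd), G, N)
    dimnames(logx) <- list(genes, samples$sample_id)
    list(values = 2^logx,
         truth = data.frame(
           gene_id = genes,
           chromosome = ifelse(is_h21, "chr21", "other"),
           cluster = cluster,
           dosage_log2fc = ifelse(is_h21, config$dosage_log2fc, 0),
           transporter_log2fc = transporter_fc,
           stringsAsFactors = FALSE))
  })
}

# ---- analyte panels ----------------------------------------------------------

# Shared machinery for log-normal analyte layers with planted per-subtype
# z-shifts (shift expressed in units of the layer's noise SD).
simulate_analyte_layer <- function(shifts, noise_sd, samples, cov_sds, seed,
                                   baseline_range = c(2, 10)) {
  analytes <- rownames(shifts)
  A <- length(analytes)
  N <- nrow(samples)
  with_seed(seed, {
    logx <- matrix(stats::runif(A, baseline_range[1L], baseline_range[2L]),
                   A, N)
    for (s in seq_along(SUBTYPES)) {
      cols <- which(!is.na(samples$subtype_truth) &
                      samples$subtype_truth == SUBTYPES[s])
      logx[, cols] <- logx[, cols] + shifts[, s] * noise_sd
    }
    logx <- logx + covariate_contribution(A, samples, cov_sds)
    logx <- logx + matrix(stats::rnorm(A * N, 0, noise_sd), A, N)
    dimnames(logx) <- list(analytes, samples$sample_id)
    2^logx
  })
}

#' Simulate the targeted cytokine (MSD-like) and broad proteomic layers
#'
#' Both layers are log-normal analyte panels with per-subtype planted shifts
#' (in units of the layer noise SD). Under the default calibration the seven
#' cytokine-score analytes are centred at z >= +2 versus controls in MS3 and
#' z <= +0.5 in MS1/MS2, and the three classifier analytes of the broad
#' proteomic panel (CRP, IL-6, SAA1) carry a stronger MS3 elevation.
#'
#' @inheritParams simulate_expression
#' @return A list with `msd_panel` and `somalike_proteome` matrices plus
#'   `truth` (per-layer planted shift tables).
#' @export
simulate_panels <- function(config, samples = simulate_samples(config)) {
  stopifnot(inherits(config, "sim_config"))
  pc <- config$panel_config
  msd <- simulate_analyte_layer(pc$msd$shifts, pc$msd$noise_sd, samples,
                                config$covariate_effects$panels,
                                substream_seed(config$seed, "msd_panel"))
  soma <- simulate_analyte_layer(pc$soma$shifts, pc$soma$noise_sd, samples,
                                 config$covariate_effects$panels,
                                 substream_seed(config$seed, "somalike"))
  list(msd_panel = msd, somalike_proteome = soma,
       truth = list(msd = pc$msd$shifts, soma = pc$soma$shifts,
                    score_analytes = pc$score_analytes))
}

# ---- metabolome --------------------------------------------------------------

#' Simulate the plasma metabolome layer
#'
#' All amino acids carry a shared T21 depletion; exactly
#' `metab_config$n_planted` analytes additionally carry a graded subtype
#' depletion (strongest in MS3), giving a planted MS3-vs-MS1 contrast for
#' exactly those analytes. A configurable fraction of intensities is zeroed
#' to exercise downstream zero replacement.
#'
#' @inheritParams simulate_expression
#' @return A list with `values` (features x samples, linear intensity scale,
#'   may contain zeros) and `truth` (feature table with the planted
#'   MS3-vs-MS1 log2 effect).
#' @export
simulate_metabolome <- function(config, samples = simulate_samples(config)) {
  stopifnot(inherits(config, "sim_config"))
  mc <- config$metab_config
  aa <- c(mc$planted, mc$other_amino_acids)
  planted <- mc$planted[seq_len(mc$n_planted)]
  feats <- c(aa, sprintf("MET.%03d", seq_len(mc$n_other_features)))
  FN <- length(feats)
  N <- nrow(samples)
  with_seed(substream_seed(config$seed, "metabolome"), {
    logx <- matrix(stats::runif(FN, 10, 20), FN, N)
    t21 <- samples$karyotype == "T21"
    is_aa <- feats %in% aa
    logx[is_aa, t21] <- logx[is_aa, t21] + mc$t21_log2fc
    for (s in seq_along(SUBTYPES)) {
      cols <- which(!is.na(samples$subtype_truth) &
                      samples$subtype_truth == SUBTYPES[s])
      rows <- which(feats %in% planted)
      logx[rows, cols] <- logx[rows, cols] + mc$planted_gradient[s]
    }
    logx <- logx + covariate_contribution(FN, samples,
                                          config$covariate_effects$metabolome)
    logx <- logx + matrix(stats::rnorm(FN * N, 0, mc$noise_sd), FN, N)
    vals <- 2^logx
    if (mc$zero_rate > 0) {
      zero <- matrix(stats::runif(FN * N) < mc$zero_rate, FN, N)
      vals[zero] <- 0
    }
    dimnames(vals) <- list(feats, samples$sample_id)
    list(values = vals,
         truth = data.frame(
           feature_id = feats,
           class = ifelse(feats %in% aa, "amino_acid", "other"),
           ms3_vs_ms1_log2fc = ifelse(
             feats %in% planted,
             mc$planted_gradient[3L] - mc$planted_gradient[1L], 0),
           stringsAsFactors = FALSE))
  })
}

# ---- immune cells and CBC ----------------------------------------------------

#' Simulate immune-cell composition and complete blood count layers
#'
#' Cell fractions follow a logistic-normal model: per-sample log-weights are
#' base log-frequencies plus planted subtype shifts plus Gaussian noise,
#' normalized with softmax so each sample's fractions sum to one exactly.
#' The CBC layer is log-normal with planted subtype shifts rank-consistent
#' with the composition shifts (MS3 lymphopenia and neutrophilia).
#'
#' @inheritParams simulate_expression
#' @return A list with `cell_fractions`, `cbc` and `truth`.
#' @export
simulate_cells_and_cbc <- function(config, samples = simulate_samples(config)) {
  stopifnot(inherits(config, "sim_config"))
  cc <- config$cell_config
  types <- names(cc$base)
  K <- length(types)
  N <- nrow(samples)
  cells <- with_seed(substream_seed(config$seed, "cell_fractions"), {
    y <- matrix(log(cc$base), K, N)
    for (s in seq_along(SUBTYPES)) {
      cols <- which(!is.na(samples$subtype_truth) &
                      samples$subtype_truth == SUBTYPES[s])
      y[, cols] <- y[, cols] + cc$shifts[, s]
    }
    y <- y + matrix(stats::rnorm(K * N, 0, cc$noise_sd), K, N)
    w <- exp(y)
    p <- sweep(w, 2L, colSums(w), "/")
    dimnames(p) <- list(types, samples$sample_id)
    p
  })
  bc <- config$cbc_config
  cbc <- simulate_analyte_layer(bc$shifts, bc$noise_sd, samples,
                                config$covariate_effects$cbc,
                                substream_seed(config$seed, "cbc"))
  # rebase CBC features onto their clinical baselines
  cbc <- cbc / 2^rowMeans(log2(cbc)) * 2^(bc$baseline_log2 + 0)
  list(cell_fractions = cells, cbc = cbc,
       truth = list(cell_shifts = cc$shifts, cbc_shifts = bc$shifts))
}

# ---- longitudinal revisit ----------------------------------------------------

#' Simulate a second visit for selected layers
#'
#' For each analyte, the visit-2 value is generated as
#' `rho * z1 + sqrt(1 - rho^2) * e` on the standardized log2 scale and
#' back-transformed, so the expected inter-visit correlation approximates the
#' per-analyte stability target `rho`.
#'
#' @param cohort A `t21_cohort` from [simulate_cohort()], or a named list of
#'   layer matrices.
#' @param stability_rho Named list (per layer) of named per-analyte rho
#'   targets; defaults to the cohort's configuration.
#' @param layers Which layers to revisit.
#' @param seed RNG seed; defaults to a substream of the cohort's master seed.
#' @return Named list of visit-2 matrices with the same dimnames as visit 1.
#' @export
simulate_revisit <- function(cohort, stability_rho = NULL,
                             layers = c("msd_panel", "cbc"), seed = NULL) {
  lyr <- if (inherits(cohort, "t21_cohort")) cohort$layers else cohort
  if (is.null(stability_rho) && inherits(cohort, "t21_cohort")) {
    stability_rho <- cohort$config$stability_rho
  }
  if (is.null(seed)) {
    seed <- if (inherits(cohort, "t21_cohort")) {
      substream_seed(cohort$config$seed, "revisit")
    } else {
      stop("seed required when cohort carries no configuration", call. = FALSE)
    }
  }
  bad <- unlist(lapply(stability_rho, function(r) r[abs(r) > 1]))
  if (length(bad) > 0) stop("|stability rho| > 1", call. = FALSE)
  with_seed(seed, {
    out <- list()
    for (layer in layers) {
      v1 <- lyr[[layer]]
      if (is.null(v1)) stop("layer not found: ", layer, call. = FALSE)
      rho <- stability_rho[[layer]]
      l1 <- log2(v1)
      mu <- rowMeans(l1)
      sd1 <- apply(l1, 1L, stats::sd)
      z1 <- (l1 - mu) / sd1
      r <- rho[rownames(v1)]
      r[is.na(r)] <- 0.6
      eps <- matrix(stats::rnorm(length(v1)), nrow(v1), ncol(v1))
      z2 <- r * z1 + sqrt(1 - r^2) * eps
      out[[layer]] <- 2^(mu + sd1 * z2)
      dimnames(out[[layer]]) <- dimnames(v1)
    }
    out
  })
}

# ---- orchestration -----------------------------------------------------------

#' Simulate a full synthetic multiomics cohort
#'
#' Orchestrates all layer generators under one master seed (independent
#' substreams per layer) and bundles the layers, sample table, ground truth,
#' and second-visit layers into a `t21_cohort` object.
#'
#' @param config A [sim_config()].
#' @return A `t21_cohort`: list with `layers` (expression,
#'   somalike_proteome, msd_panel, metabolome, cell_fractions, cbc),
#'   `samples`, `feature_truth`, `visit2`, and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  samples <- simulate_samples(config)
  expr <- simulate_expression(config, samples)
  panels <- simulate_panels(config, samples)
  metab <- simulate_metabolome(config, samples)
  cells <- simulate_cells_and_cbc(config, samples)
  cohort <- structure(list(
    layers = list(expression = expr$values,
                  somalike_proteome = panels$somalike_proteome,
                  msd_panel = panels$msd_panel,
                  metabolome = metab$values,
                  cell_fractions = cells$cell_fractions,
                  cbc = cells$cbc),
    samples = samples,
    feature_truth = list(genes = expr$truth,
                         panels = panels$truth,
                         metabolome = metab$truth,
                         cells = cells$truth),
    visit2 = NULL,
    config = config
  ), class = "t21_cohort")
  cohort$visit2 <- simulate_revisit(cohort)
  cohort
}

#' @export
print.t21_cohort <- function(x, ...) {
  cat("t21_cohort:", nrow(x$samples), "samples (",
      sum(x$samples$karyotype == "D21"), "D21 /",
      sum(x$samples$karyotype == "T21"), "T21 )\n")
  for (nm in names(x$layers)) {
    cat(sprintf("  %-18s %5d features\n", nm, nrow(x$layers[[nm]])))
  }
  invisible(x)
}

#' Write a cohort to a directory of TSV/JSON files
#'
#' @param cohort A `t21_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "t21_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cohort$config$seed
  for (nm in names(cohort$layers)) {
    write_matrix(cohort$layers[[nm]], file.path(dir, paste0(nm, ".tsv")),
                 stage = "simulate", seed = seed)
  }
  if (!is.null(cohort$visit2)) {
    for (nm in names(cohort$visit2)) {
      write_matrix(cohort$visit2[[nm]],
                   file.path(dir, paste0(nm, "_visit2.tsv")),
                   stage = "simulate_revisit", seed = seed)
    }
  }
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$feature_truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA)
  invisible(dir)
}
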