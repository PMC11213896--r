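# Synthetic cohort generator: determinism, planted structure, error handling.

test_that("identical config gives bit-identical cohorts; seeds differ", {
  c1 <- simulate_cohort(small_config(seed = 11L))
  c2 <- simulate_cohort(small_config(seed = 11L))
  c3 <- simulate_cohort(small_config(seed = 12L))
  for (nm in names(c1$layers)) {
    expect_identical(c1$layers[[nm]], c2$layers[[nm]])
    expect_identical(dim(c1$layers[[nm]]), dim(c3$layers[[nm]]))
  }
  expect_identical(c1$samples, c2$samples)
  expect_false(identical(c1$layers$expression, c3$layers$expression))
  expect_identical(c1$visit2$msd_panel, c2$visit2$msd_panel)
})

test_that("cohort echoes the configured composition", {
  coh <- get_small_cohort()
  expect_equal(sum(coh$samples$karyotype == "D21"), 30L)
  expect_equal(sum(coh$samples$karyotype == "T21"), 113L)
  expect_setequal(unique(stats::na.omit(coh$samples$subtype_truth)),
                  c("MS1", "MS2", "MS3"))
  expect_equal(as.integer(table(coh$samples$subtype_truth)[c("MS1", "MS2", "MS3")]),
               c(40L, 35L, 38L))
})

test_that("noise-free limit recovers the dosage ratio exactly", {
  cfg <- small_config(
    seed = 3L, cluster_effects = 0, subtype_gene_sd = 0, latent_loading = 0,
    noise_sd = 0,
    covariate_effects = list(expression = c(age = 0, sex = 0, source = 0),
                             panels = c(age = 0, sex = 0, source = 0),
                             metabolome = c(age = 0, sex = 0, source = 0),
                             cbc = c(age = 0, sex = 0, source = 0)))
  ex <- simulate_expression(cfg)
  s <- simulate_samples(cfg)
  t21 <- s$sample_id[s$karyotype == "T21"]
  d21 <- s$sample_id[s$karyotype == "D21"]
  h21 <- ex$truth$gene_id[ex$truth$chromosome == "chr21"]
  ratio <- rowMeans(ex$values[h21, t21]) / rowMeans(ex$values[h21, d21])
  expect_equal(unname(ratio), rep(1.5, length(h21)), tolerance = 1e-12)
  bg <- setdiff(ex$truth$gene_id[ex$truth$transporter_log2fc == 0], h21)
  ratio_bg <- rowMeans(ex$values[bg, t21]) / rowMeans(ex$values[bg, d21])
  expect_equal(unname(ratio_bg), rep(1, length(bg)), tolerance = 1e-12)
})

test_that("latent factor and subtype gradient give the planted sign structure", {
  cfg <- small_config(seed = 5L, latent_loading = 0.5)
  ex <- simulate_expression(cfg)
  s <- simulate_samples(cfg)
  t21 <- s$sample_id[s$karyotype == "T21"]
  lx <- log2(ex$values[, t21])
  c1 <- ex$truth$gene_id[!is.na(ex$truth$cluster) & ex$truth$cluster == 1]
  c2 <- ex$truth$gene_id[!is.na(ex$truth$cluster) & ex$truth$cluster == 2]
  rho <- stats::cor(t(lx[c(c1, c2), ]), method = "spearman")
  within1 <- rho[c1, c1][upper.tri(rho[c1, c1])]
  cross <- rho[c1, c2]
  expect_gt(stats::median(within1), 0.3)
  expect_lt(stats::median(cross), -0.1)
  # two specific pairs, as a direct spot check
  expect_gt(rho[c1[1], c1[2]], 0)
  expect_lt(rho[c1[1], c2[1]], 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(subtype_sizes = c(0L, 95L, 102L)), "counts")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(subtype_gene_sd = -1), "subtype_gene_sd")
  expect_error(sim_config(latent_loading = 1.5), "latent_loading")
  expect_error(sim_config(gene_cluster_sizes = c(120L, 29L)),
               "exceed")
  pc <- default_panel_config()
  rownames(pc$msd$shifts)[2] <- rownames(pc$msd$shifts)[1]
  expect_error(sim_config(panel_config = pc), "duplicate analyte")
  mc <- default_metab_config()
  mc$n_planted <- 99L
  expect_error(sim_config(metab_config = mc), "n_planted")
})

test_that("panel shifts land where planted", {
  # all shifts zero: group means agree within Monte-Carlo error
  pc0 <- default_panel_config()
  pc0$msd$shifts[] <- 0
  pc0$soma$shifts[] <- 0
  cfg0 <- small_config(seed = 21L, panel_config = pc0)
  p0 <- simulate_panels(cfg0)
  s0 <- simulate_samples(cfg0)
  lm0 <- log2(p0$msd_panel)
  ms3 <- s0$sample_id[!is.na(s0$subtype_truth) & s0$subtype_truth == "MS3"]
  d21 <- s0$sample_id[s0$karyotype == "D21"]
  diffs <- rowMeans(lm0[, ms3]) - rowMeans(lm0[, d21])
  expect_lt(max(abs(diffs)), 0.5)   # 0 +/- MC error at noise_sd 0.5

  # +2 SD shift with unit-SD noise: ~98% of MS3 above the control mean
  pc2 <- default_panel_config()
  pc2$msd$shifts[] <- 0
  pc2$msd$shifts["IL-6", "MS3"] <- 2
  pc2$msd$noise_sd <- 1
  cfg2 <- sim_config(n_controls = 30L, subtype_sizes = c(40L, 35L, 150L),
                     n_hsa21_coding = 30L, gene_cluster_sizes = c(20L, 10L),
                     n_background_genes = 50L, panel_config = pc2, seed = 22L)
  p2 <- simulate_panels(cfg2)
  s2 <- simulate_samples(cfg2)
  ms3 <- s2$sample_id[!is.na(s2$subtype_truth) & s2$subtype_truth == "MS3"]
  d21 <- s2$sample_id[s2$karyotype == "D21"]
  frac <- mean(log2(p2$msd_panel["IL-6", ms3]) >
                 mean(log2(p2$msd_panel["IL-6", d21])))
  expect_gt(frac, 0.90)   # Phi(2) ~ 0.977

  # defaults: the 7 score analytes are higher in MS3 than MS1
  coh <- get_small_cohort()
  sc <- coh$feature_truth$panels$score_analytes
  s <- coh$samples
  ms3 <- s$sample_id[!is.na(s$subtype_truth) & s$subtype_truth == "MS3"]
  ms1 <- s$sample_id[!is.na(s$subtype_truth) & s$subtype_truth == "MS1"]
  lmsd <- log2(coh$layers$msd_panel)
  expect_true(all(rowMeans(lmsd[sc, ms3]) > rowMeans(lmsd[sc, ms1])))
})

test_that("metabolome plants exactly the configured depleted analytes", {
  coh <- get_small_cohort()
  tr <- coh$feature_truth$metabolome
  expect_equal(sum(tr$ms3_vs_ms1_log2fc != 0), 9L)
  expect_setequal(tr$feature_id[tr$ms3_vs_ms1_log2fc != 0],
                  coh$config$metab_config$planted)
  expect_true(all(tr$ms3_vs_ms1_log2fc <= 0))

  mc <- default_metab_config()
  mc$n_planted <- 0L
  m0 <- simulate_metabolome(small_config(seed = 9L, metab_config = mc))
  expect_equal(sum(m0$truth$ms3_vs_ms1_log2fc != 0), 0L)

  # zero-injection rate: binomial expectation
  mc2 <- default_metab_config()
  mc2$zero_rate <- 0.1
  m2 <- simulate_metabolome(small_config(seed = 10L, metab_config = mc2))
  n_cells <- length(m2$values)
  n_zero <- sum(m2$values == 0)
  expect_lt(abs(n_zero - 0.1 * n_cells), 4 * sqrt(n_cells * 0.1 * 0.9))
})

test_that("cell fractions close to one and follow planted composition shifts", {
  coh <- get_small_cohort()
  cf <- coh$layers$cell_fractions
  expect_true(all(abs(colSums(cf) - 1) < 1e-9))
  s <- coh$samples
  ms3 <- s$sample_id[!is.na(s$subtype_truth) & s$subtype_truth == "MS3"]
  d21 <- s$sample_id[s$karyotype == "D21"]
  expect_gt(mean(cf["Neutrophils", ms3]), mean(cf["Neutrophils", d21]))
  expect_lt(mean(cf["Lymphocytes_T", ms3]), mean(cf["Lymphocytes_T", d21]))
  # CBC rank-consistency with composition shifts
  cbc <- coh$layers$cbc
  expect_lt(mean(log2(cbc["Lymphocytes_abs", ms3])),
            mean(log2(cbc["Lymphocytes_abs", d21])))
  expect_gt(mean(log2(cbc["Neutrophils_pct", ms3])),
            mean(log2(cbc["Neutrophils_pct", d21])))

  # zero shifts: compositions match across groups
  cc0 <- default_cell_config()
  cc0$shifts[] <- 0
  cfg0 <- small_config(seed = 31L, cell_config = cc0)
  cl0 <- simulate_cells_and_cbc(cfg0)
  s0 <- simulate_samples(cfg0)
  g1 <- s0$sample_id[s0$karyotype == "D21"]
  g2 <- s0$sample_id[!is.na(s0$subtype_truth) & s0$subtype_truth == "MS3"]
  expect_lt(max(abs(rowMeans(cl0$cell_fractions[, g1]) -
                      rowMeans(cl0$cell_fractions[, g2]))), 0.05)
})

test_that("revisit layers honour the stability targets", {
  coh <- get_small_cohort()
  # rho = 1: visit 2 equals visit 1 after scale restoration
  r1 <- simulate_revisit(coh$layers["msd_panel"],
                         stability_rho = list(msd_panel = structure(
                           rep(1, nrow(coh$layers$msd_panel)),
                           names = rownames(coh$layers$msd_panel))),
                         layers = "msd_panel", seed = 99L)
  expect_equal(r1$msd_panel, coh$layers$msd_panel, tolerance = 1e-9)

  # rho = 0: near-zero inter-visit correlation; rho = 0.8 recovered +/- 0.1
  rho_tgt <- structure(rep(0, nrow(coh$layers$msd_panel)),
                       names = rownames(coh$layers$msd_panel))
  rho_tgt[1:10] <- 0.8
  r2 <- simulate_revisit(coh$layers["msd_panel"],
                         stability_rho = list(msd_panel = rho_tgt),
                         layers = "msd_panel", seed = 100L)
  obs <- vapply(rownames(coh$layers$msd_panel), function(a) {
    stats::cor(coh$layers$msd_panel[a, ], r2$msd_panel[a, ],
               method = "spearman")
  }, 0)
  expect_lt(max(abs(obs[11:length(obs)])), 0.25)
  expect_lt(max(abs(obs[1:10] - 0.8)), 0.1)

  expect_error(simulate_revisit(coh, stability_rho = list(msd_panel = c(x = 1.2)),
                                layers = "msd_panel", seed = 1L),
               "rho")
})
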