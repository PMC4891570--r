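# The synthetic Cq generator: determinism, noise accounting, ground truth,
# and the full study-design bookkeeping.

test_that("the generator is deterministic given its seed", {
  cfg <- sim_config(n_genes = 5, n_samples = 8, seed = 77)
  a <- simulate_cq(cfg)
  b <- simulate_cq(cfg)
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth$sample_effects, b$truth$sample_effects)
  c <- simulate_cq(sim_config(n_genes = 5, n_samples = 8, seed = 78))
  expect_false(identical(a$dataset$cq, c$dataset$cq))
})

test_that("the noiseless limit is constant per gene with zero stability values", {
  cfg <- sim_config(n_genes = 4, n_samples = 6, n_tech_replicates = 2,
                    sample_effect_sd = 0, gene_noise_sd = rep(0, 4),
                    replicate_sd = 0, seed = 1)
  sim <- simulate_cq(cfg)
  m <- aggregate_replicates(sim$dataset)
  expect_equal(unname(apply(m$cq, 1, function(x) diff(range(x)))), rep(0, 4))
  qm <- relative_quantities(m)
  expect_equal(unname(genorm_m(qm)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(normfinder_stability(log_quantities(qm))$stability),
               rep(0, 4), tolerance = 1e-12)
})

test_that("aggregated per-gene Cq dispersion matches the configured components", {
  cfg <- sim_config(n_genes = 3, n_samples = 3000, n_tech_replicates = 3,
                    baseline_cq = c(18, 22, 26), sample_effect_sd = 0.8,
                    gene_noise_sd = c(0.1, 0.3, 0.6), replicate_sd = 0.3,
                    seed = 404)
  sim <- simulate_cq(cfg)
  m <- aggregate_replicates(sim$dataset)
  expected <- sqrt(0.8^2 + c(0.1, 0.3, 0.6)^2 + 0.3^2 / 3)
  observed <- apply(m$cq, 1, sd)
  expect_equal(unname(observed), expected, tolerance = 0.05)
})

test_that("the loading effect cancels in both stability measures", {
  base <- sim_config(n_genes = 6, n_samples = 24, seed = 55,
                     sample_effect_sd = 0.5)
  doubled <- sim_config(n_genes = 6, n_samples = 24, seed = 55,
                        sample_effect_sd = 1.0)
  # same seed: identical gene/technical noise, only the shared per-sample
  # effect differs, and it cancels exactly in ratios and in the model fit
  qm1 <- relative_quantities(aggregate_replicates(simulate_cq(base)$dataset))
  qm2 <- relative_quantities(aggregate_replicates(simulate_cq(doubled)$dataset))
  expect_equal(genorm_m(qm1), genorm_m(qm2), tolerance = 1e-9)
  expect_equal(normfinder_stability(log_quantities(qm1))$stability,
               normfinder_stability(log_quantities(qm2))$stability,
               tolerance = 1e-9)
})

test_that("estimated stability tracks the true noise grading", {
  rho <- numeric(20)
  for (i in seq_len(20)) {
    cfg <- sim_config(n_genes = 8, n_samples = 50,
                      gene_noise_sd = seq(0.05, 0.6, length.out = 8),
                      seed = 2100 + i)
    sim <- simulate_cq(cfg)
    qm <- relative_quantities(aggregate_replicates(sim$dataset))
    m <- genorm_m(qm)
    rho[i] <- cor(m[cfg$gene_ids], cfg$gene_noise_sd, method = "spearman")
  }
  expect_gte(mean(rho), 0.8)
})

test_that("a spiked target shifts Cq by -log2(fold)/log2(E) per condition", {
  cfg <- sim_config(n_genes = 3, n_samples = 6, n_tech_replicates = 1,
                    sample_effect_sd = 0, gene_noise_sd = rep(0, 3),
                    replicate_sd = 0, seed = 9,
                    group_labels = rep(c("ctl", "trt"), each = 3))
  sim <- spike_target(cfg, fold_profile = c(ctl = 1, trt = 4),
                      target_noise_sd = 0, target_baseline = 24,
                      target_efficiency = 2)
  m <- aggregate_replicates(sim$dataset)
  expect_equal(unname(m$cq["TARGET", 1:3]), rep(24, 3))
  expect_equal(unname(m$cq["TARGET", 4:6]), rep(22, 3))  # log2(4) = 2 cycles

  # fold 1 everywhere: the target is an ordinary flat gene
  flat <- spike_target(cfg, fold_profile = c(ctl = 1, trt = 1),
                       target_noise_sd = 0)
  mf <- aggregate_replicates(flat$dataset)
  expect_equal(unname(diff(range(mf$cq["TARGET", ]))), 0)

  expect_error(spike_target(cfg, fold_profile = c(ctl = 1, trt = -2)),
               "positive")
})

test_that("the study design reproduces the sampling bookkeeping", {
  pd <- longan_study_design(seed = 1)
  expect_equal(length(unique(pd$dataset$sample_id)), 150)
  expect_equal(nrow(pd$meta), 150)
  counts <- table(pd$meta$experimental_set)
  expect_equal(as.integer(counts[c("different_varieties", "developmental_stages",
                                   "different_organs", "NAA", "2,4-D", "ethephon",
                                   "bagging", "temperature",
                                   "girdling_defoliation")]),
               c(36L, 36L, 18L, 9L, 9L, 9L, 9L, 12L, 12L))
  expect_equal(length(unique(pd$dataset$gene_id)), 12)
  expect_equal(sort(unique(pd$dataset$replicate)), 1:3)
  expect_equal(length(pd$set_filters), 13)
  # every panel filter selects a valid analysis set
  m <- aggregate_replicates(pd$dataset, meta = pd$meta)
  sizes <- vapply(pd$set_filters, function(f) {
    length(subset_by_experiment(m, f)$samples)
  }, integer(1))
  expect_equal(sum(sizes), 150L)
  expect_true(all(sizes >= 6))
  # assay table mirrors the measured panel characteristics
  assays <- longan_assays()
  expect_equal(assays$efficiency[assays$gene_id == "CYP"], 2.072)
  expect_true(all(assays$efficiency > 1.9 & assays$efficiency < 2.1))
  # baselines lie in the observed Cq range
  expect_true(all(pd$truth$config$baseline_cq > 11 &
                    pd$truth$config$baseline_cq < 35))
})
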