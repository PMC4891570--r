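# Efficiency-corrected relative quantification of a target gene.

test_that("a target identical to the normalization factor gives a flat profile", {
  set.seed(2)
  q <- rand_q(2, 8)
  qm <- as_quantity_matrix(q)
  nf <- normalization_factor(qm, c("G01", "G02"))
  # target whose quantity equals NF exactly: Cq_t = -log2(NF) + const
  target_cq <- 25 - log2(nf$nf)
  rel <- normalize_target(target_cq, nf, calibrator = names(target_cq)[1])
  expect_equal(unname(rel$values), rep(1, 8), tolerance = 1e-12)
})

test_that("with base-2 efficiencies and one reference the model is 2^-ddCq", {
  set.seed(12)
  cq <- matrix(runif(2 * 10, 18, 28), 2, 10,
               dimnames = list(c("REF", "TGT"), sprintf("S%02d", 1:10)))
  qm <- relative_quantities(make_cq_matrix(cq["REF", , drop = FALSE]))
  nf <- normalization_factor(qm, "REF")
  cal <- "S01"
  rel <- normalize_target(cq["TGT", ], nf, target_efficiency = 2,
                          calibrator = cal)
  dcq <- (cq["TGT", ] - cq["REF", ])
  ddcq <- dcq - dcq[cal]
  expect_equal(unname(rel$values), unname(2 ^ -ddcq), tolerance = 1e-12)
})

test_that("k copies of one gene normalize like the gene itself; scaling is idempotent", {
  set.seed(3)
  qm <- rand_qm(3, 6)
  target_cq <- setNames(runif(6, 20, 24), qm$samples)
  one <- normalize_target(target_cq, normalization_factor(qm, "G01"),
                          calibrator = qm$samples[1])
  nf3 <- normalization_factor(qm, c("G01", "G01", "G01"))
  three <- normalize_target(target_cq, nf3, calibrator = qm$samples[1])
  expect_equal(one$values, three$values, tolerance = 1e-12)

  # rescaling an already-calibrated profile changes nothing
  again <- normalize_target(setNames(-log2(one$values * 2^-20), names(one$values)),
                            setNames(rep(1, 6), names(one$values)),
                            calibrator = qm$samples[1])
  expect_equal(unname(again$values), unname(one$values / one$values[1]),
               tolerance = 1e-12)
})

test_that("a spiked fold change is recovered under stable references", {
  folds <- numeric(30)
  for (i in seq_len(30)) {
    cfg <- sim_config(n_genes = 4, n_samples = 12, n_tech_replicates = 1,
                      gene_noise_sd = rep(0.05, 4), sample_effect_sd = 1,
                      replicate_sd = 0.1, seed = 4000 + i,
                      group_labels = rep(c("ctl", "trt"), each = 6))
    sim <- spike_target(cfg, fold_profile = c(ctl = 1, trt = 4))
    m <- aggregate_replicates(sim$dataset)
    target_cq <- m$cq["TARGET", ]
    refs <- make_cq_matrix(m$cq[cfg$gene_ids, ])
    qm <- relative_quantities(refs)
    conds <- sim$truth$target$conditions
    rel <- normalize_target(target_cq, normalization_factor(qm, cfg$gene_ids),
                            calibrator = "ctl", conditions = conds)
    folds[i] <- rel$aggregated$mean[rel$aggregated$condition == "trt"]
  }
  expect_gt(mean(folds), 3.6)
  expect_lt(mean(folds), 4.4)
})

test_that("a drifting reference inflates an otherwise flat target profile", {
  over <- logical(20)
  for (i in seq_len(20)) {
    shift <- matrix(c(0, 1.5), 1, 2, dimnames = list("G04", c("ctl", "trt")))
    cfg <- sim_config(n_genes = 4, n_samples = 12, n_tech_replicates = 1,
                      gene_noise_sd = rep(0.05, 4), sample_effect_sd = 1,
                      replicate_sd = 0.1, seed = 5000 + i,
                      group_labels = rep(c("ctl", "trt"), each = 6),
                      group_shift = shift)  # +Cq in trt: falling quantity
    sim <- spike_target(cfg, fold_profile = c(ctl = 1, trt = 1))  # flat truth
    m <- aggregate_replicates(sim$dataset)
    qm <- relative_quantities(make_cq_matrix(m$cq[cfg$gene_ids, ]))
    conds <- sim$truth$target$conditions
    tabs <- compare_normalizers(m$cq["TARGET", ],
                                list(stable = c("G01", "G02"),
                                     drifting = "G04"),
                                qm, calibrator = "ctl", conditions = conds)
    est <- function(t) t$aggregated$mean[t$aggregated$condition == "trt"]
    over[i] <- est(tabs$drifting) > est(tabs$stable)
  }
  expect_gte(mean(over), 0.95)
})

test_that("normalizer comparison handles duplicates, empties and bad sets", {
  set.seed(6)
  qm <- rand_qm(3, 6)
  target_cq <- setNames(runif(6, 20, 24), qm$samples)
  tabs <- compare_normalizers(target_cq, list(a = "G01", b = "G01"), qm,
                              calibrator = qm$samples[1])
  expect_equal(tabs$a$values, tabs$b$values)
  expect_equal(length(compare_normalizers(target_cq, list(), qm,
                                          calibrator = qm$samples[1])), 0)
  bad <- compare_normalizers(target_cq, list(x = "NOPE"), qm,
                             calibrator = qm$samples[1])
  expect_match(bad$x$error, "unknown gene")
  # missing calibrator is an error
  expect_error(normalize_target(target_cq, normalization_factor(qm, "G01"),
                                calibrator = "S999"),
               "calibrator")
})
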