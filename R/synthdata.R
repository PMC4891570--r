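# Synthetic replicate-level Cq generator with known ground truth. The noise
# model is additive normal on the Cq scale (log-scale fluorescence-cycle
# space, where technical variation is approximately homoscedastic):
#
#   Cq[g,s,r] = baseline[g] + sample_effect[s] + group_shift[g, group(s)]
#               + gene_noise[g,s] + tech_noise[g,s,r]
#
# The shared sample effect emulates loading/RT variation and cancels in
# both stability algorithms; the per-gene noise SD is the instability the
# algorithms must recover; group shifts model treatment-responsive
# (unsuitable) reference genes.

#' Simulation configuration
#'
#' @param n_genes,n_samples,n_tech_replicates Dataset dimensions (3
#'   technical replicates by default, as is standard bench practice).
#' @param baseline_cq Per-gene baseline Cq (default: evenly spread over
#'   15-30 cycles, within the 11-35 range typical of reference-gene
#'   panels).
#' @param sample_effect_sd SD (cycles) of the shared per-sample loading/RT
#'   effect (default 1.0).
#' @param gene_noise_sd Per-gene instability SD in cycles (default: graded
#'   0.05-0.6, well-separated so the true stability order is meaningful).
#' @param group_labels Optional per-sample group/condition labels.
#' @param group_shift Optional genes x groups matrix of Cq shifts
#'   (dimnames required), modelling treatment-responsive genes.
#' @param replicate_sd Technical (well-to-well) noise SD in cycles
#'   (default 0.15).
#' @param seed Integer seed; one seed drives the whole generator stream.
#' @param gene_ids,sample_ids Optional identifier vectors.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 12, n_samples = 36, n_tech_replicates = 3,
                       baseline_cq = NULL, sample_effect_sd = 1.0,
                       gene_noise_sd = NULL, group_labels = NULL,
                       group_shift = NULL, replicate_sd = 0.15,
                       seed = 1L, gene_ids = NULL, sample_ids = NULL) {
  if (n_genes < 1 || n_samples < 1 || n_tech_replicates < 1) {
    stop("dimensions must be positive", call. = FALSE)
  }
  gene_ids <- gene_ids %||% sprintf("G%02d", seq_len(n_genes))
  sample_ids <- sample_ids %||% sprintf("S%03d", seq_len(n_samples))
  baseline_cq <- baseline_cq %||% seq(15, 30, length.out = n_genes)
  gene_noise_sd <- gene_noise_sd %||% seq(0.05, 0.6, length.out = n_genes)
  if (length(gene_ids) != n_genes || length(baseline_cq) != n_genes ||
      length(gene_noise_sd) != n_genes) {
    stop("per-gene parameters must have length n_genes", call. = FALSE)
  }
  if (length(sample_ids) != n_samples) {
    stop("sample_ids must have length n_samples", call. = FALSE)
  }
  if (sample_effect_sd < 0 || replicate_sd < 0 || any(gene_noise_sd < 0)) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (!is.null(group_labels) && length(group_labels) != n_samples) {
    stop("group_labels must have length n_samples", call. = FALSE)
  }
  if (!is.null(group_shift)) {
    if (is.null(group_labels)) {
      stop("group_shift requires group_labels", call. = FALSE)
    }
    if (!is.matrix(group_shift) || is.null(rownames(group_shift)) ||
        is.null(colnames(group_shift))) {
      stop("group_shift must be a genes x groups matrix with dimnames",
           call. = FALSE)
    }
    if (!all(rownames(group_shift) %in% gene_ids) ||
        !all(unique(group_labels) %in% colnames(group_shift))) {
      stop("group_shift dimnames must match gene_ids and group_labels",
           call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 n_tech_replicates = n_tech_replicates,
                 baseline_cq = stats::setNames(baseline_cq, gene_ids),
                 sample_effect_sd = sample_effect_sd,
                 gene_noise_sd = stats::setNames(gene_noise_sd, gene_ids),
                 group_labels = group_labels, group_shift = group_shift,
                 replicate_sd = replicate_sd, seed = as.integer(seed),
                 gene_ids = gene_ids, sample_ids = sample_ids),
            class = "sim_config")
}

# Draws the cell-level (pre-technical-replicate) Cq matrix; assumes the RNG
# stream is already seeded. Returns the matrix plus realized effects.
draw_cells <- function(cfg) {
  g <- cfg$n_genes; n <- cfg$n_samples
  se <- stats::rnorm(n, 0, cfg$sample_effect_sd)
  names(se) <- cfg$sample_ids
  gn <- matrix(stats::rnorm(g * n), g, n) * cfg$gene_noise_sd
  shift <- matrix(0, g, n)
  if (!is.null(cfg$group_shift)) {
    sh <- matrix(0, g, n, dimnames = list(cfg$gene_ids, cfg$sample_ids))
    sh[rownames(cfg$group_shift), ] <-
      cfg$group_shift[, cfg$group_labels, drop = FALSE]
    shift <- sh
  }
  cells <- cfg$baseline_cq + matrix(se, g, n, byrow = TRUE) + shift + gn
  dimnames(cells) <- list(cfg$gene_ids, cfg$sample_ids)
  list(cells = cells, sample_effects = se)
}

cells_to_long <- function(cells, cfg) {
  g <- nrow(cells); n <- ncol(cells); reps <- cfg$n_tech_replicates
  tech <- array(stats::rnorm(g * n * reps, 0, cfg$replicate_sd), c(g, n, reps))
  long <- expand.grid(gene_id = rownames(cells), sample_id = colnames(cells),
                      replicate = seq_len(reps), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$cq <- as.vector(cells[cbind(match(long$gene_id, rownames(cells)),
                                   match(long$sample_id, colnames(cells)))]) +
    tech[cbind(match(long$gene_id, rownames(cells)),
               match(long$sample_id, colnames(cells)),
               long$replicate)]
  as_cq_dataset(long[, c("sample_id", "gene_id", "replicate", "cq")])
}

#' Simulate a replicate-level Cq dataset
#'
#' Deterministic given the config seed: the same config reproduces the same
#' dataset exactly.
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (a `cq_dataset`) and `truth` (config echo,
#'   realized sample effects, and the true stability order — genes sorted
#'   by increasing instability SD).
#' @export
simulate_cq <- function(cfg) {
  stop_if_not_matrix_obj(cfg, "sim_config", "cfg")
  set.seed(cfg$seed)
  drawn <- draw_cells(cfg)
  ds <- cells_to_long(drawn$cells, cfg)
  truth <- list(config = cfg,
                sample_effects = drawn$sample_effects,
                gene_noise_sd = cfg$gene_noise_sd,
                true_order = names(sort(cfg$gene_noise_sd)))
  list(dataset = ds, truth = truth)
}

#' Simulate a dataset with a spiked target gene
#'
#' Adds one target gene whose true expression follows a per-condition fold
#' profile: a fold change F at a condition shifts the target's Cq there by
#' `-log2(F)/log2(E)` cycles (a 4-fold rise at E = 2 is a 2-cycle drop).
#' The reference genes are generated exactly as in [simulate_cq()].
#'
#' @param cfg A [sim_config()]; `group_labels` (or `conditions`) define the
#'   per-sample conditions.
#' @param fold_profile Named positive vector: true fold change per
#'   condition (relative to the target baseline).
#' @param conditions Per-sample condition labels; defaults to
#'   `cfg$group_labels`.
#' @param target_id,target_baseline,target_efficiency,target_noise_sd
#'   Target gene identity, baseline Cq, amplification efficiency and
#'   biological noise SD.
#' @return List with `dataset` (reference genes plus the target) and
#'   `truth` (including the spiked profile).
#' @export
spike_target <- function(cfg, fold_profile, conditions = NULL,
                         target_id = "TARGET", target_baseline = 24,
                         target_efficiency = 2, target_noise_sd = 0.05) {
  stop_if_not_matrix_obj(cfg, "sim_config", "cfg")
  conditions <- conditions %||% cfg$group_labels
  if (is.null(conditions)) stop("per-sample conditions are required", call. = FALSE)
  if (length(conditions) != cfg$n_samples) {
    stop("conditions must have length n_samples", call. = FALSE)
  }
  if (any(fold_profile <= 0)) stop("fold_profile must be positive", call. = FALSE)
  if (!all(unique(conditions) %in% names(fold_profile))) {
    stop("fold_profile must name every condition", call. = FALSE)
  }
  if (target_id %in% cfg$gene_ids) {
    stop("target_id collides with a reference gene", call. = FALSE)
  }
  set.seed(cfg$seed)
  drawn <- draw_cells(cfg)
  shift <- -log2(fold_profile[conditions]) / log2(target_efficiency)
  t_cells <- target_baseline + shift + drawn$sample_effects +
    stats::rnorm(cfg$n_samples, 0, target_noise_sd)
  cells <- rbind(drawn$cells,
                 matrix(t_cells, 1, dimnames = list(target_id, cfg$sample_ids)))
  ds <- cells_to_long(cells, cfg)
  truth <- list(config = cfg,
                sample_effects = drawn$sample_effects,
                gene_noise_sd = cfg$gene_noise_sd,
                true_order = names(sort(cfg$gene_noise_sd)),
                target = list(id = target_id, baseline = target_baseline,
                              efficiency = target_efficiency,
                              fold_profile = fold_profile,
                              conditions = stats::setNames(conditions,
                                                           cfg$sample_ids)))
  list(dataset = ds, truth = truth)
}

#' Assay characteristics of the 12-gene longan reference panel
#'
#' Measured standard-curve amplification efficiencies, amplicon lengths and
#' melting temperatures for the twelve candidate reference genes of the
#' longan fruit panel (CYP, RPL, GAPDH, TUA, TUB, Fe-SOD, Mn-SOD,
#' Cu/Zn-SOD, 18SrRNA, Actin, HistoneH3, EF-1a).
#'
#' @return Data frame with columns `gene_id`, `efficiency`,
#'   `amplicon_length`, `tm`.
#' @export
longan_assays <- function() {
  data.frame(
    gene_id = c("CYP", "RPL", "GAPDH", "TUA", "TUB", "Fe-SOD",
                "Mn-SOD", "Cu/Zn-SOD", "18SrRNA", "Actin", "HistoneH3",
                "EF-1a"),
    efficiency = c(2.072, 1.914, 1.962, 1.986, 1.977, 1.917,
                   1.949, 1.992, 1.931, 1.984, 2.002, 2.072),
    amplicon_length = c(213L, 246L, 204L, 175L, 86L, 114L,
                        184L, 207L, 171L, 93L, 155L, 129L),
    tm = c(83.37, 80.87, 81.79, 81.09, 83.43, 80.80,
           81.44, 82.46, 83.93, 81.77, 85.71, 84.57),
    stringsAsFactors = FALSE)
}

longan_study_meta <- function() {
  row <- function(set, panel, tissue, cultivar, treatment, timepoint, rep) {
    data.frame(experimental_set = set, analysis_set = panel, tissue = tissue,
               cultivar = cultivar, treatment = treatment,
               timepoint = timepoint, biological_replicate = rep,
               stringsAsFactors = FALSE)
  }
  reps <- 1:3
  blocks <- list()
  # Different varieties: pericarp + aril of 6 cultivars at 110 DAA (36)
  cultivars <- c("Shixia", "Chuliang", "Linglong", "Gushan", "Caopushi",
                 "Benzhan")
  for (tis in c("pericarp", "aril")) {
    blocks[[length(blocks) + 1]] <- row(
      "different_varieties", paste0("varieties_", tis),
      tis, rep(cultivars, each = 3), "none", "110DAA", rep(reps, 6))
  }
  # Developmental stages: pericarp + aril of Shixia at 6 stages (36)
  stages <- c("62DAA", "76DAA", "83DAA", "89DAA", "103DAA", "110DAA")
  for (tis in c("pericarp", "aril")) {
    blocks[[length(blocks) + 1]] <- row(
      "developmental_stages", paste0("stages_", tis),
      tis, "Shixia", "none", rep(stages, each = 3), rep(reps, 6))
  }
  # Different organs: 6 tissues of Shixia (18)
  organs <- c("root", "shoot", "leaf", "flower", "fruitlets", "seed")
  organ_tp <- ifelse(organs == "fruitlets", "40DAA", "110DAA")
  blocks[[length(blocks) + 1]] <- row(
    "different_organs", "organs", rep(organs, each = 3), "Shixia", "none",
    rep(organ_tp, each = 3), rep(reps, 6))
  # Hormone / bagging treatments: pericarp at 0, 2, 3 DAT (9 each)
  trt_panels <- c(NAA = "naa", `2,4-D` = "d24", ethephon = "ethephon",
                  bagging = "bagging")
  for (trt in names(trt_panels)) {
    blocks[[length(blocks) + 1]] <- row(
      trt, trt_panels[[trt]], "pericarp", "Shixia", trt,
      rep(c("0DAT", "2DAT", "3DAT"), each = 3), rep(reps, 3))
  }
  # Temperature: aril at 4C / 22C, 2 and 3 DAT (12)
  for (tmp in c("4C", "22C")) {
    blocks[[length(blocks) + 1]] <- row(
      "temperature", paste0("temp_", tmp), "aril", "Shixia", tmp,
      rep(c("2DAT", "3DAT"), each = 3), rep(reps, 2))
  }
  # Girdling with defoliation: fruitlets + abscission zone, 4 and 5 DAT (12)
  for (tis in c("abscission_zone", "fruitlets")) {
    blocks[[length(blocks) + 1]] <- row(
      "girdling_defoliation",
      if (tis == "fruitlets") "girdling_fruitlets" else "girdling_az",
      tis, "Shixia", "girdling_defoliation",
      rep(c("4DAT", "5DAT"), each = 3), rep(reps, 2))
  }
  meta <- do.call(rbind, blocks)
  meta <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(meta))), meta,
                stringsAsFactors = FALSE)
  meta$group <- meta$timepoint
  meta
}

#' Sample-set filters for the thirteen study analysis panels
#'
#' The nine experimental sets expand to thirteen analysis panels (pericarp
#' and aril analysed separately for varieties and developmental stages;
#' the two temperatures and the two girdling tissues analysed separately).
#'
#' @return Named list of filters for [subset_by_experiment()] /
#'   [run_all_sets()].
#' @export
longan_set_filters <- function() {
  panels <- c("varieties_pericarp", "varieties_aril", "stages_pericarp",
              "stages_aril", "organs", "naa", "d24", "ethephon", "bagging",
              "temp_4C", "temp_22C", "girdling_az", "girdling_fruitlets")
  stats::setNames(lapply(panels, function(p) list(analysis_set = p)), panels)
}

#' Simulate the full longan study design
#'
#' A 12-gene, 150-sample, 3-technical-replicate dataset with the sample
#' bookkeeping of the longan reference-gene study: nine experimental sets
#' (36 + 36 + 18 + 9 + 9 + 9 + 9 + 12 + 12 samples) covering varieties,
#' developmental stages, organs, hormone stimuli, bagging, storage
#' temperature and girdling with defoliation, expandable to thirteen
#' analysis panels. Gene baselines span the observed Cq range (18SrRNA
#' most abundant at ~17 cycles, Fe-SOD least at ~29) and instability SDs
#' are graded with the tubulins (TUA, TUB) noisiest and GAPDH/EF-1a most
#' stable, echoing the panel's qualitative behaviour.
#'
#' @param seed Integer seed.
#' @return List with `dataset`, `meta`, `assays` ([longan_assays()]),
#'   `truth` and `set_filters` ([longan_set_filters()]).
#' @export
longan_study_design <- function(seed = 1L) {
  meta <- longan_study_meta()
  assays <- longan_assays()
  baseline <- c(CYP = 22, RPL = 23.5, GAPDH = 21, TUA = 24, TUB = 25,
                `Fe-SOD` = 29, `Mn-SOD` = 26, `Cu/Zn-SOD` = 28,
                `18SrRNA` = 17.4, Actin = 22.5, HistoneH3 = 23,
                `EF-1a` = 21.5)
  noise <- c(CYP = 0.28, RPL = 0.40, GAPDH = 0.12, TUA = 0.70, TUB = 0.65,
             `Fe-SOD` = 0.18, `Mn-SOD` = 0.20, `Cu/Zn-SOD` = 0.35,
             `18SrRNA` = 0.45, Actin = 0.30, HistoneH3 = 0.25,
             `EF-1a` = 0.15)
  genes <- assays$gene_id
  cfg <- sim_config(n_genes = length(genes), n_samples = nrow(meta),
                    n_tech_replicates = 3,
                    baseline_cq = unname(baseline[genes]),
                    sample_effect_sd = 1.0,
                    gene_noise_sd = unname(noise[genes]),
                    replicate_sd = 0.15, seed = seed,
                    gene_ids = genes, sample_ids = meta$sample_id)
  sim <- simulate_cq(cfg)
  list(dataset = sim$dataset, meta = meta, assays = assays,
       truth = sim$truth, set_filters = longan_set_filters())
}
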