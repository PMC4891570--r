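# Pipeline drivers tying the modules together: simulate a dataset to disk,
# run the ranking analysis over sample sets, and quantify a target gene.
# Each writes machine-readable JSON alongside human-readable CSV. A thin
# command-line wrapper over these functions ships in inst/cli/refstab.R.

read_table_auto <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = detect_sep(path, NULL),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Parse a sample-set filter expression
#'
#' Expressions of the form `"column=value"` or
#' `"column=value1,value2;column2=value"` become named-list filters for
#' [subset_by_experiment()].
#'
#' @param expr Filter expression string.
#' @return Named list filter.
#' @export
parse_set_filter <- function(expr) {
  parts <- strsplit(expr, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) {
    stop("malformed filter expression: '", expr,
         "' (expected column=value[;column=value])", call. = FALSE)
  }
  stats::setNames(lapply(kv, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]]),
                  vapply(kv, `[`, character(1), 1))
}

#' Simulate a Cq dataset and write it to disk
#'
#' Writes the long-format Cq CSV that [cmd_rank()] reads, the ground-truth
#' JSON, and (for the study design) the sample metadata and assay tables.
#' Re-running with the same seed reproduces the numeric content exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param design `"longan"` for the full 150-sample longan study design,
#'   `"custom"` for `config`.
#' @param config A [sim_config()] for the custom design.
#' @param seed Overrides the config seed when given.
#' @return Invisibly, the named list of file paths written.
#' @export
cmd_simulate <- function(out_dir, design = c("longan", "custom"),
                         config = NULL, seed = NULL) {
  design <- match.arg(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(cq = file.path(out_dir, "cq.csv"),
                truth = file.path(out_dir, "truth.json"))
  if (design == "longan") {
    pd <- longan_study_design(seed = seed %||% 1L)
    write_cq_long(pd$dataset, paths$cq)
    paths$meta <- file.path(out_dir, "meta.csv")
    paths$assays <- file.path(out_dir, "assays.csv")
    utils::write.csv(pd$meta, paths$meta, row.names = FALSE)
    utils::write.csv(pd$assays, paths$assays, row.names = FALSE)
    truth <- pd$truth
  } else {
    config <- config %||% sim_config()
    if (!is.null(seed)) config$seed <- as.integer(seed)
    sim <- simulate_cq(config)
    write_cq_long(sim$dataset, paths$cq)
    truth <- sim$truth
  }
  truth$config$group_shift <- if (!is.null(truth$config$group_shift)) {
    as.data.frame(truth$config$group_shift)
  }
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(paths)
}

bundle_to_json <- function(b) {
  if (!is.null(b$error)) return(list(set = b$set, error = b$error))
  list(set = b$set, n_samples = b$n_samples,
       genorm = list(per_gene_m = as.list(b$genorm$per_gene_value),
                     ranking = b$genorm$ranking,
                     final_pair = b$genorm$final_pair,
                     final_pair_m = b$genorm$final_pair_m),
       vcurve = list(v = as.list(b$vcurve$v), cutoff = b$vcurve$cutoff,
                     optimal_n = if (is.na(b$vcurve$optimal_n)) "none"
                                 else b$vcurve$optimal_n),
       normfinder = list(stability = as.list(b$normfinder$stability),
                         ranking = b$normfinder_ranking),
       consensus = list(k = b$consensus$k,
                        top_k_overlap = b$consensus$top_k_overlap,
                        top_k_genes = b$consensus$top_k_genes,
                        least_stable_agreement = b$consensus$least_stable_agreement,
                        best_of_b_in_top_k_of_a = b$consensus$best_of_b_in_top_k_of_a))
}

#' Rank reference genes across sample sets and write reports
#'
#' Reads the Cq, metadata and assay files, aggregates technical
#' replicates, runs geNorm and NormFinder per sample set, and writes per
#' analysis a JSON bundle plus CSV tables of M values, the V curve and the
#' consensus summary.
#'
#' @param cq Path to the long-format Cq CSV.
#' @param meta,assays Optional paths to the metadata / assay CSVs.
#' @param out_dir Output directory.
#' @param sets Named list of filters, or character vector of
#'   `"column=value"` expressions; `set_col` instead splits by the unique
#'   values of one metadata column. With neither, all samples form one set.
#' @param set_col Metadata column defining the sample sets.
#' @param v_cutoff,top_k,efficiency_mode,base,group_col,method Analysis
#'   options (see [run_all_sets()] and [aggregate_replicates()]).
#' @return Invisibly, the list of per-set bundles.
#' @export
cmd_rank <- function(cq, meta = NULL, assays = NULL, out_dir,
                     sets = NULL, set_col = NULL, v_cutoff = 0.15,
                     top_k = NULL, efficiency_mode = "fixed_base", base = 2,
                     group_col = NULL, method = "mean") {
  ds <- read_cq_long(cq)
  meta_df <- if (!is.null(meta)) read_table_auto(meta, "metadata")
  assay_df <- if (!is.null(assays)) read_table_auto(assays, "assay")
  m <- aggregate_replicates(ds, method = method, meta = meta_df,
                            assays = assay_df)
  set_definitions <- if (!is.null(sets)) {
    if (is.character(sets)) {
      stats::setNames(lapply(sets, parse_set_filter), sets)
    } else sets
  } else if (!is.null(set_col)) {
    if (is.null(meta_df) || !set_col %in% names(meta_df)) {
      stop("metadata has no column '", set_col, "'", call. = FALSE)
    }
    vals <- unique(m$meta[[set_col]])
    stats::setNames(lapply(vals, function(v) {
      stats::setNames(list(v), set_col)
    }), vals)
  } else {
    list(all = function(meta) rep(TRUE, nrow(meta)))
  }
  if (is.null(m$meta)) {
    m$meta <- data.frame(sample_id = m$samples, stringsAsFactors = FALSE)
  }
  bundles <- run_all_sets(m, set_definitions,
                          efficiency_mode = efficiency_mode, base = base,
                          v_cutoff = v_cutoff, top_k = top_k,
                          group_col = group_col)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    if (is.null(b$error)) {
      utils::write.csv(data.frame(gene_id = names(b$genorm$per_gene_value),
                                  genorm_m = unname(b$genorm$per_gene_value),
                                  genorm_rank = match(names(b$genorm$per_gene_value),
                                                      b$genorm$ranking),
                                  normfinder_stability =
                                    unname(b$normfinder$stability[names(b$genorm$per_gene_value)]),
                                  normfinder_rank =
                                    match(names(b$genorm$per_gene_value),
                                          b$normfinder_ranking)),
                       file.path(out_dir, paste0(safe, "_stability.csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(n = b$vcurve$n, v = unname(b$vcurve$v)),
                       file.path(out_dir, paste0(safe, "_vcurve.csv")),
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(bundle_to_json(b),
                         file.path(out_dir, paste0(safe, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(lapply(bundles, bundle_to_json),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundles)
}

#' Quantify a target gene against one or more reference sets
#'
#' Reads the same inputs as [cmd_rank()], quantifies `target` against each
#' candidate reference set with identical calibrator scaling, and writes a
#' plot-ready long CSV plus a JSON summary.
#'
#' @inheritParams cmd_rank
#' @param target Target gene identifier (must be present in the Cq input).
#' @param refs List of reference-gene character vectors (the target itself
#'   is not allowed as a reference).
#' @param calibrator Calibrator sample(s) or condition label.
#' @param condition_col Metadata column holding the condition labels used
#'   for calibrator lookup and biological-replicate aggregation.
#' @param target_efficiency Amplification efficiency of the target assay.
#' @param efficiency_mode,base Efficiency handling for the reference genes.
#' @return Invisibly, the list of `rel_expression` tables.
#' @export
cmd_relquant <- function(cq, meta = NULL, target, refs, calibrator,
                         out_dir, condition_col = NULL,
                         target_efficiency = 2,
                         efficiency_mode = "fixed_base", base = 2,
                         method = "mean") {
  if (!is.list(refs)) refs <- list(refs)
  if (target %in% unlist(refs)) {
    stop("target gene cannot be used as its own reference", call. = FALSE)
  }
  ds <- read_cq_long(cq)
  meta_df <- if (!is.null(meta)) read_table_auto(meta, "metadata")
  m <- aggregate_replicates(ds, method = method, meta = meta_df)
  if (!target %in% m$genes) {
    stop("unknown target gene: ", target, call. = FALSE)
  }
  target_cq <- m$cq[target, ]
  ref_m <- m
  ref_m$cq <- m$cq[setdiff(m$genes, target), , drop = FALSE]
  ref_m$genes <- setdiff(m$genes, target)
  qm <- relative_quantities(ref_m, mode = efficiency_mode, base = base)
  conditions <- if (!is.null(condition_col)) {
    if (is.null(m$meta) || !condition_col %in% names(m$meta)) {
      stop("metadata has no column '", condition_col, "'", call. = FALSE)
    }
    stats::setNames(m$meta[[condition_col]], m$samples)
  }
  tables <- compare_normalizers(target_cq, refs, qm,
                                target_efficiency = target_efficiency,
                                calibrator = calibrator,
                                conditions = conditions)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  long <- rel_expression_table(tables, conditions)
  utils::write.csv(long, file.path(out_dir, "relquant.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(tables, function(t) {
    if (!inherits(t, "rel_expression")) return(t)
    list(normalizer = t$normalizer, calibrator = t$calibrator,
         values = as.list(t$values),
         aggregated = t$aggregated)
  }), file.path(out_dir, "relquant.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tables)
}
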