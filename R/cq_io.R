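# Reading, validating, aggregating and subsetting Cq (quantification-cycle)
# data. Long format carries one row per technical replicate; the wide format
# is a gene x (sample.replicate) table. Both readers produce the same
# replicate-level dataset, which is aggregated to a complete gene x sample
# matrix before any stability analysis.

#' Construct a replicate-level Cq dataset
#'
#' Validates and classes a data frame of replicate-level Cq measurements.
#' Each row is one technical replicate of one gene in one sample.
#'
#' @param df Data frame with columns `sample_id`, `gene_id`, `replicate`
#'   (positive integer) and `cq` (numeric, finite and positive, or `NA` for a
#'   failed well).
#' @return A data frame of class `cq_dataset`.
#' @export
as_cq_dataset <- function(df) {
  required <- c("sample_id", "gene_id", "replicate", "cq")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[, required]
  df$sample_id <- as.character(df$sample_id)
  df$gene_id <- as.character(df$gene_id)
  df$replicate <- as.integer(df$replicate)
  df$cq <- as.numeric(df$cq)
  if (nrow(df)) {
    if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
      stop("`replicate` must be a positive integer index", call. = FALSE)
    }
    ok <- is.na(df$cq) | (is.finite(df$cq) & df$cq > 0)
    if (!all(ok)) {
      stop("Cq values must be finite and > 0 (or NA); offending row ",
           which(!ok)[1], call. = FALSE)
    }
    key <- paste(df$sample_id, df$gene_id, df$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[which(duplicated(key))[1], ]
      stop("duplicate (sample_id, gene_id, replicate) record: (",
           d$sample_id, ", ", d$gene_id, ", ", d$replicate, ")", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("cq_dataset", "data.frame")
  df
}

detect_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  first <- readLines(path, n = 1L)
  if (length(first) && grepl("\t", first)) "\t" else ","
}

#' Read long-format Cq data
#'
#' Expects a delimited text file (comma or tab, auto-detected) with header
#' columns `sample_id,gene_id,replicate,cq`. A Cq of `NA` or an empty field
#' marks a failed well and is kept as missing for [validate_dataset()] to
#' report.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @return A `cq_dataset`.
#' @export
read_cq_long <- function(path, sep = NULL) {
  sep <- detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  required <- c("sample_id", "gene_id", "replicate", "cq")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cq <- suppressWarnings(as.numeric(df$cq))
  bad <- which(!is.na(df$cq) & is.na(cq))
  if (length(bad)) {
    stop("non-numeric Cq value at data row ", bad[1], ": '", df$cq[bad[1]], "'",
         call. = FALSE)
  }
  rep_i <- suppressWarnings(as.integer(df$replicate))
  bad <- which(!is.na(df$replicate) & is.na(rep_i))
  if (length(bad)) {
    stop("non-integer replicate index at data row ", bad[1], call. = FALSE)
  }
  as_cq_dataset(data.frame(sample_id = df$sample_id, gene_id = df$gene_id,
                           replicate = rep_i, cq = cq,
                           stringsAsFactors = FALSE))
}

#' Read wide-format Cq data
#'
#' First column holds gene identifiers; every remaining column is labelled
#' `sample.replicate` (e.g. `S01.1`, `S01.2`). Blank cells become missing Cq.
#'
#' @inheritParams read_cq_long
#' @return A `cq_dataset` equivalent to the long reader on the same content.
#' @export
read_cq_wide <- function(path, sep = NULL) {
  sep <- detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("wide table needs a gene_id column plus sample columns",
                         call. = FALSE)
  if (anyDuplicated(names(df))) {
    stop("duplicate column label: ", names(df)[duplicated(names(df))][1],
         call. = FALSE)
  }
  cols <- names(df)[-1]
  no_rep <- !grepl("\\.", cols)
  if (any(no_rep)) {
    stop("column '", cols[no_rep][1],
         "' is not of the form sample.replicate", call. = FALSE)
  }
  samples <- sub("\\.[^.]*$", "", cols)
  reps <- suppressWarnings(as.integer(sub(".*\\.", "", cols)))
  if (any(is.na(reps))) {
    stop("column '", cols[is.na(reps)][1],
         "' has a non-integer replicate suffix", call. = FALSE)
  }
  genes <- as.character(df[[1]])
  long <- do.call(rbind, lapply(seq_along(cols), function(j) {
    cq <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(!is.na(df[[j + 1]]) & is.na(cq))
    if (length(bad)) {
      stop("non-numeric Cq in column '", cols[j], "', row ", bad[1], call. = FALSE)
    }
    data.frame(sample_id = samples[j], gene_id = genes, replicate = reps[j],
               cq = cq, stringsAsFactors = FALSE)
  }))
  as_cq_dataset(long)
}

#' Write a Cq dataset as long-format CSV
#'
#' @param ds A `cq_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cq_long <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality-control report for a Cq dataset
#'
#' Report-only checks: technical-replicate dispersion, empty gene x sample
#' cells, and the samples/genes that replicate aggregation would drop under
#' the complete-matrix policy.
#'
#' @param ds A `cq_dataset`.
#' @param max_replicate_sd Flag replicate groups whose sample SD exceeds this
#'   many cycles (default 0.5, a common lab heuristic).
#' @param max_missing_fraction Genes missing in more than this fraction of
#'   samples are listed for removal (default 0.2).
#' @return A list of class `qc_report` with elements `missing_cells`,
#'   `replicate_sd_flags`, `dropped_samples`, `dropped_genes`.
#' @export
validate_dataset <- function(ds, max_replicate_sd = 0.5,
                             max_missing_fraction = 0.2) {
  stop_if_not_matrix_obj(ds, "cq_dataset", "ds")
  if (!nrow(ds)) stop("dataset is empty", call. = FALSE)
  genes <- sort_ids(ds$gene_id)
  samples <- sort_ids(ds$sample_id)
  ok <- !is.na(ds$cq)
  n_ok <- tapply(ok, list(factor(ds$gene_id, genes), factor(ds$sample_id, samples)),
                 sum, default = 0L)
  cell_sd <- tapply(ds$cq, list(factor(ds$gene_id, genes),
                                factor(ds$sample_id, samples)),
                    function(x) if (sum(!is.na(x)) >= 2) stats::sd(x, na.rm = TRUE) else NA_real_)
  miss <- which(n_ok == 0L, arr.ind = TRUE)
  missing_cells <- data.frame(gene_id = genes[miss[, 1]],
                              sample_id = samples[miss[, 2]],
                              stringsAsFactors = FALSE)
  flg <- which(!is.na(cell_sd) & cell_sd > max_replicate_sd, arr.ind = TRUE)
  replicate_sd_flags <- data.frame(gene_id = genes[flg[, 1]],
                                   sample_id = samples[flg[, 2]],
                                   sd = cell_sd[flg],
                                   stringsAsFactors = FALSE)
  miss_frac <- rowMeans(n_ok == 0L)
  dropped_genes <- genes[miss_frac > max_missing_fraction]
  dropped_samples <- samples[colSums(n_ok[setdiff(genes, dropped_genes), ,
                                          drop = FALSE] == 0L) > 0L]
  structure(list(missing_cells = missing_cells,
                 replicate_sd_flags = replicate_sd_flags,
                 dropped_samples = dropped_samples,
                 dropped_genes = dropped_genes,
                 n_genes = length(genes), n_samples = length(samples),
                 max_replicate_sd = max_replicate_sd,
                 max_missing_fraction = max_missing_fraction),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Cq QC report:", x$n_genes, "genes x", x$n_samples, "samples\n")
  cat("  empty cells:            ", nrow(x$missing_cells), "\n")
  cat("  replicate-SD flags (> ", x$max_replicate_sd, " cycles): ",
      nrow(x$replicate_sd_flags), "\n", sep = "")
  cat("  samples dropped by aggregation:", length(x$dropped_samples), "\n")
  cat("  genes advised for removal:     ", length(x$dropped_genes), "\n")
  invisible(x)
}

#' Aggregate technical replicates into a complete Cq matrix
#'
#' Collapses technical replicates per gene x sample cell (mean by default,
#' the de-facto qPCR convention; median offered for outlier robustness).
#' Samples with any empty cell are dropped so the matrix is complete —
#' missing data are never imputed. Gene and sample order is lexicographic
#' unless explicit orders are supplied, so downstream output is
#' deterministic.
#'
#' @param ds A `cq_dataset`.
#' @param method `"mean"` or `"median"`.
#' @param meta Optional sample-metadata data frame keyed by `sample_id`;
#'   every retained sample must be present.
#' @param assays Optional assay data frame keyed by `gene_id` (per-gene
#'   amplification efficiency etc.).
#' @param max_missing_fraction A gene empty in more than this fraction of
#'   samples raises an error advising gene removal rather than silently
#'   discarding most of the samples.
#' @param gene_order,sample_order Optional explicit identifier orders.
#' @return A list of class `cq_matrix` with elements `cq` (gene x sample
#'   matrix), `genes`, `samples`, `meta`, `assays`, `dropped_samples`.
#' @export
aggregate_replicates <- function(ds, method = c("mean", "median"),
                                 meta = NULL, assays = NULL,
                                 max_missing_fraction = 0.2,
                                 gene_order = NULL, sample_order = NULL) {
  stop_if_not_matrix_obj(ds, "cq_dataset", "ds")
  method <- match.arg(method)
  if (!nrow(ds)) stop("dataset is empty", call. = FALSE)
  genes <- gene_order %||% sort_ids(ds$gene_id)
  samples <- sample_order %||% sort_ids(ds$sample_id)
  if (!setequal(genes, unique(ds$gene_id)) && !is.null(gene_order)) {
    stop("gene_order must cover exactly the genes in the dataset", call. = FALSE)
  }
  fun <- if (method == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  }
  cq <- tapply(ds$cq, list(factor(ds$gene_id, genes),
                           factor(ds$sample_id, samples)), fun)
  cq <- matrix(unlist(cq), nrow = length(genes),
               dimnames = list(genes, samples))
  miss_frac <- rowMeans(is.na(cq))
  bad_genes <- genes[miss_frac > max_missing_fraction]
  if (length(bad_genes)) {
    stop("gene(s) missing in more than ", round(100 * max_missing_fraction),
         "% of samples: ", paste(bad_genes, collapse = ", "),
         "; remove them before aggregation", call. = FALSE)
  }
  dropped <- samples[colSums(is.na(cq)) > 0L]
  keep <- setdiff(samples, dropped)
  if (!length(keep)) stop("no sample has a complete gene profile", call. = FALSE)
  cq <- cq[, keep, drop = FALSE]
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"sample_id" %in% names(meta)) stop("metadata lacks sample_id", call. = FALSE)
    unknown <- setdiff(keep, meta$sample_id)
    if (length(unknown)) {
      stop("sample(s) absent from metadata: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(assays)) {
    assays <- as.data.frame(assays)
    if (!"gene_id" %in% names(assays)) stop("assay table lacks gene_id", call. = FALSE)
  }
  structure(list(cq = cq, genes = genes, samples = keep,
                 meta = meta, assays = assays, dropped_samples = dropped),
            class = "cq_matrix")
}

#' Subset a Cq matrix by sample metadata
#'
#' @param m A `cq_matrix` with metadata.
#' @param filter Either a function taking the metadata data frame and
#'   returning a logical vector, or a named list matched against metadata
#'   columns with `%in%` (conditions combined with AND).
#' @return A `cq_matrix` restricted to the selected samples; gene order
#'   preserved.
#' @export
subset_by_experiment <- function(m, filter) {
  stop_if_not_matrix_obj(m, "cq_matrix", "m")
  if (is.null(m$meta)) stop("cq_matrix carries no sample metadata", call. = FALSE)
  keep <- if (is.function(filter)) {
    filter(m$meta)
  } else if (is.list(filter) && !is.null(names(filter))) {
    Reduce(`&`, lapply(names(filter), function(col) {
      if (!col %in% names(m$meta)) {
        stop("metadata has no column '", col, "'", call. = FALSE)
      }
      m$meta[[col]] %in% filter[[col]]
    }))
  } else {
    stop("`filter` must be a function or a named list", call. = FALSE)
  }
  if (!is.logical(keep) || length(keep) != length(m$samples)) {
    stop("filter must yield one logical per sample", call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  if (sum(keep) < 2) {
    stop("filter selects fewer than 2 samples; stability is undefined",
         call. = FALSE)
  }
  m$cq <- m$cq[, keep, drop = FALSE]
  m$samples <- m$samples[keep]
  m$meta <- m$meta[keep, , drop = FALSE]
  rownames(m$meta) <- NULL
  m
}
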