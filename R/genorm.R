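# geNorm stability analysis: pairwise M values, stepwise exclusion ranking,
# normalization factors, the pairwise-variation (V) curve and the optimal
# reference-gene count. Conventions: log base 2 throughout, sample SD with
# the n-1 denominator, deterministic tie-breaks by gene ordering.

assert_qm_positive <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("relative quantities must be finite and positive", call. = FALSE)
  }
}

#' geNorm pairwise stability measure M
#'
#' For gene j, M_j is the arithmetic mean over all other candidate genes k
#' of the sample standard deviation (n-1 denominator) of log2(Q_j / Q_k)
#' across samples. Two genes with a constant expression ratio have M = 0;
#' lower M means more stable expression.
#'
#' @param qm A `quantity_matrix`.
#' @param genes Optional gene subset (default: all genes).
#' @return Named numeric vector of M values.
#' @export
genorm_m <- function(qm, genes = NULL) {
  stop_if_not_matrix_obj(qm, "quantity_matrix", "qm")
  q <- qm$q
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(q))
    if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "),
                              call. = FALSE)
    q <- q[genes, , drop = FALSE]
  }
  g <- nrow(q); n <- ncol(q)
  if (g < 2) stop("M requires at least 2 genes", call. = FALSE)
  if (n < 2) stop("M requires at least 2 samples", call. = FALSE)
  assert_qm_positive(q)
  l <- log2(q)
  m <- vapply(seq_len(g), function(j) {
    d <- sweep(l, 2, l[j, ], "-")               # rows: log2(Q_k) - log2(Q_j)
    sds <- apply(d, 1, stats::sd)
    sum(sds[-j]) / (g - 1)
  }, numeric(1))
  stats::setNames(m, rownames(q))
}

#' geNorm stepwise-exclusion ranking
#'
#' Iteratively computes M over the remaining genes, excludes the gene with
#' the highest M (ties broken by excluding the gene latest in the
#' deterministic gene ordering), records the average M of the set at each
#' step, and stops when two genes remain. The ranking is the reverse
#' exclusion order; the final two genes cannot be resolved further by the
#' pairwise measure and share the top position with equal M.
#'
#' @param qm A `quantity_matrix` with at least 3 genes.
#' @return A list of class `stability_report` with `per_gene_value` (M at
#'   the step each gene was excluded; the final pair's shared two-gene M),
#'   `ranking`, `final_pair`, `final_pair_m`, `exclusion_trace` (step,
#'   number of genes evaluated, mean M of that set, excluded gene and its
#'   M) and `m_steps` (the full M vector at every step, so either the
#'   average-of-remaining or the per-gene trajectory can be plotted).
#' @export
stepwise_exclusion <- function(qm) {
  stop_if_not_matrix_obj(qm, "quantity_matrix", "qm")
  genes <- qm$genes
  if (length(genes) < 3) stop("stepwise exclusion requires at least 3 genes",
                              call. = FALSE)
  order_index <- stats::setNames(seq_along(genes), genes)
  remaining <- genes
  per_gene_value <- stats::setNames(rep(NA_real_, length(genes)), genes)
  trace <- list()
  m_steps <- list()
  step <- 0L
  excluded <- character(0)
  while (length(remaining) > 2) {
    step <- step + 1L
    m <- genorm_m(qm, remaining)
    m_steps[[step]] <- m
    worst <- names(m)[m == max(m)]
    excl <- worst[which.max(order_index[worst])]
    per_gene_value[excl] <- m[[excl]]
    trace[[step]] <- data.frame(step = step, n_genes = length(remaining),
                                mean_m = mean(m), excluded_gene = excl,
                                excluded_m = m[[excl]],
                                stringsAsFactors = FALSE)
    excluded <- c(excluded, excl)
    remaining <- setdiff(remaining, excl)
  }
  m_final <- genorm_m(qm, remaining)
  step <- step + 1L
  m_steps[[step]] <- m_final
  trace[[step]] <- data.frame(step = step, n_genes = 2L,
                              mean_m = mean(m_final),
                              excluded_gene = NA_character_,
                              excluded_m = NA_real_, stringsAsFactors = FALSE)
  per_gene_value[remaining] <- m_final
  final_pair <- remaining[order(order_index[remaining])]
  structure(list(algorithm = "genorm",
                 per_gene_value = per_gene_value,
                 ranking = c(final_pair, rev(excluded)),
                 final_pair = final_pair,
                 final_pair_m = unname(m_final[1]),
                 exclusion_trace = do.call(rbind, trace),
                 m_steps = m_steps),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report (", x$algorithm, "), ", length(x$ranking),
      " genes\n", sep = "")
  cat("  ranking (best -> worst):", paste(x$ranking, collapse = ", "), "\n")
  if (x$algorithm == "genorm") {
    cat(sprintf("  final pair %s + %s, M = %.3f\n",
                x$final_pair[1], x$final_pair[2], x$final_pair_m))
  }
  invisible(x)
}

#' Normalization factor for a reference-gene set
#'
#' The per-sample normalization factor is the geometric mean of the member
#' genes' relative quantities.
#'
#' @param qm A `quantity_matrix`.
#' @param gene_set Non-empty character vector of gene identifiers.
#' @return A list of class `normalization_factors` with `genes` and the
#'   named positive vector `nf`.
#' @export
normalization_factor <- function(qm, gene_set) {
  stop_if_not_matrix_obj(qm, "quantity_matrix", "qm")
  if (!length(gene_set)) stop("gene_set must be non-empty", call. = FALSE)
  unknown <- setdiff(gene_set, qm$genes)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  q <- qm$q[gene_set, , drop = FALSE]
  assert_qm_positive(q)
  structure(list(genes = gene_set,
                 nf = apply(q, 2, geomean)),
            class = "normalization_factors")
}

#' geNorm pairwise-variation (V) curve
#'
#' For n = 2 .. G-1, V_n is the sample standard deviation across samples of
#' log2(NF_n / NF_{n+1}), where NF_n is the normalization factor built from
#' the n top-ranked genes. A V_n below the cutoff (default 0.15) means the
#' (n+1)-th gene adds no meaningful information; the optimal count is the
#' smallest such n.
#'
#' @param qm A `quantity_matrix` with at least 3 genes.
#' @param ranking Gene ranking best to worst (default: computed by
#'   [stepwise_exclusion()]).
#' @param cutoff Decision threshold on V (default 0.15; adjustable to the
#'   experimental conditions).
#' @return A list of class `vcurve` with `n`, `v`, `cutoff`, `optimal_n`
#'   (`NA` when no V falls below the cutoff) and the ranking used.
#' @export
pairwise_variation <- function(qm, ranking = NULL, cutoff = 0.15) {
  stop_if_not_matrix_obj(qm, "quantity_matrix", "qm")
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (is.null(ranking)) ranking <- stepwise_exclusion(qm)$ranking
  if (!setequal(ranking, qm$genes) || anyDuplicated(ranking)) {
    stop("ranking must be a permutation of the gene set", call. = FALSE)
  }
  G <- length(ranking)
  if (G < 3) stop("the V curve requires at least 3 genes", call. = FALSE)
  nf <- lapply(seq_len(G), function(n) normalization_factor(qm, ranking[seq_len(n)])$nf)
  ns <- 2:(G - 1)
  v <- vapply(ns, function(n) stats::sd(log2(nf[[n]] / nf[[n + 1]])), numeric(1))
  structure(list(n = ns, v = stats::setNames(v, paste0("V", ns, "/", ns + 1)),
                 cutoff = cutoff,
                 optimal_n = optimal_gene_count(v, cutoff),
                 ranking = ranking),
            class = "vcurve")
}

#' Optimal number of reference genes from a V curve
#'
#' The smallest n with V_n below the cutoff. When every V is at or above
#' the cutoff no candidate count qualifies; `NA` is returned and the
#' pragmatic fallback is to use at least the three most stable genes.
#'
#' @param v A `vcurve`, or a numeric vector of V values for
#'   n = 2, 3, ... in order.
#' @param cutoff Decision threshold when `v` is a plain vector (ignored
#'   for a `vcurve`, which carries its own).
#' @return Integer, or `NA_integer_` when no n qualifies.
#' @export
optimal_gene_count <- function(v, cutoff = 0.15) {
  if (inherits(v, "vcurve")) return(v$optimal_n)
  v <- as.numeric(v)
  if (!length(v)) stop("empty V sequence", call. = FALSE)
  ns <- seq.int(2L, length.out = length(v))
  below <- ns[v < cutoff]
  if (length(below)) below[1] else NA_integer_
}

#' @export
print.vcurve <- function(x, ...) {
  cat("Pairwise-variation curve (cutoff ", x$cutoff, "):\n", sep = "")
  print(round(x$v, 3))
  if (is.na(x$optimal_n)) {
    cat("  no V below cutoff: no candidate count qualifies;",
        "use at least the three most stable genes\n")
  } else {
    cat("  optimal number of reference genes:", x$optimal_n, "\n")
  }
  invisible(x)
}
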