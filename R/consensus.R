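# Cross-algorithm consensus: compare the geNorm and NormFinder rankings of
# one sample set, and drive the whole analysis over many sample sets.

#' Compare two stability rankings
#'
#' Reports the intersection of the top-k prefixes, the agreement of the
#' bottom-2 (least stable) genes, and whether the best gene of the second
#' ranking lies in the top k of the first — the consensus criteria used
#' when corroborating one algorithm's ranking with another's.
#'
#' @param a,b Orderings (best to worst) of the same gene set, e.g. the
#'   geNorm and NormFinder rankings.
#' @param k Prefix size; defaults to half the gene count.
#' @return A list of class `consensus_report`.
#' @export
compare_rankings <- function(a, b, k = NULL) {
  if (length(a) != length(b) || !setequal(a, b) ||
      anyDuplicated(a) || anyDuplicated(b)) {
    stop("rankings must be permutations of the same gene set", call. = FALSE)
  }
  G <- length(a)
  if (G < 2) stop("need at least 2 genes", call. = FALSE)
  if (is.null(k)) k <- max(1L, G %/% 2L)
  if (k > G) stop("k exceeds the number of genes", call. = FALSE)
  top_genes <- intersect(a[seq_len(k)], b[seq_len(k)])
  bottom <- intersect(a[(G - 1):G], b[(G - 1):G])
  structure(list(ranking_a = a, ranking_b = b, k = k,
                 top_k_overlap = length(top_genes),
                 top_k_genes = top_genes,
                 least_stable_agreement = bottom,
                 best_of_b_in_top_k_of_a = b[1] %in% a[seq_len(k)]),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("Ranking consensus (k = ", x$k, ")\n", sep = "")
  cat("  top-k overlap:", x$top_k_overlap, "of", x$k, "\n")
  cat("  least-stable agreement:",
      if (length(x$least_stable_agreement)) {
        paste(x$least_stable_agreement, collapse = ", ")
      } else "none", "\n")
  cat("  best of b in top-k of a:", x$best_of_b_in_top_k_of_a, "\n")
  invisible(x)
}

#' Run the full stability analysis over multiple sample sets
#'
#' For each sample-set filter: subset the Cq matrix, compute relative
#' quantities, run geNorm stepwise exclusion and the V curve, run
#' NormFinder, and compare the two rankings. Failures of individual sets
#' (e.g. a filter matching too few samples) are collected as error entries
#' rather than aborting the batch.
#'
#' @param m A `cq_matrix` with metadata.
#' @param set_definitions Named list of filters accepted by
#'   [subset_by_experiment()].
#' @param efficiency_mode,base Passed to [relative_quantities()].
#' @param v_cutoff Passed to [pairwise_variation()].
#' @param top_k Consensus prefix size (default half the gene count).
#' @param group_col Optional metadata column enabling grouped NormFinder.
#' @return Named list; each element is either a bundle with `genorm`,
#'   `vcurve`, `normfinder`, `normfinder_ranking`, `consensus`, `n_samples`
#'   or a list with an `error` message.
#' @export
run_all_sets <- function(m, set_definitions, efficiency_mode = "fixed_base",
                         base = 2, v_cutoff = 0.15, top_k = NULL,
                         group_col = NULL) {
  stop_if_not_matrix_obj(m, "cq_matrix", "m")
  if (!length(set_definitions)) return(stats::setNames(list(), character(0)))
  if (is.null(names(set_definitions))) {
    names(set_definitions) <- paste0("set", seq_along(set_definitions))
  }
  out <- lapply(names(set_definitions), function(nm) {
    tryCatch({
      sub <- subset_by_experiment(m, set_definitions[[nm]])
      qm <- relative_quantities(sub, mode = efficiency_mode, base = base)
      gn <- stepwise_exclusion(qm)
      vc <- pairwise_variation(qm, gn$ranking, cutoff = v_cutoff)
      groups <- if (!is.null(group_col)) {
        if (!group_col %in% names(sub$meta)) {
          stop("metadata has no column '", group_col, "'", call. = FALSE)
        }
        sub$meta[[group_col]]
      }
      nf <- normfinder_stability(log_quantities(qm), groups = groups)
      nf_rank <- rank_by_stability(nf)
      list(set = nm, n_samples = length(sub$samples),
           genorm = gn, vcurve = vc,
           normfinder = nf, normfinder_ranking = nf_rank,
           consensus = compare_rankings(gn$ranking, nf_rank, k = top_k))
    }, error = function(e) list(set = nm, error = conditionMessage(e)))
  })
  stats::setNames(out, names(set_definitions))
}
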