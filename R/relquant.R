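# Efficiency-corrected relative quantification of a target gene against a
# reference-gene normalization factor (Pfaffl-style ratio to a calibrator).
# With all efficiencies at 2 and a single reference gene this reduces
# algebraically to the classic 2^-ddCq.

#' Normalize a target gene against a reference set
#'
#' The raw per-sample ratio is `r_s = E_t^(minCq_t - Cq_t,s) / NF_s`
#' (efficiency-corrected target quantity over the reference normalization
#' factor); reported values are `r_s / mean(r over calibrator samples)`, so
#' the calibrator condition averages to 1.
#'
#' @param target_cq Named numeric vector of the target's aggregated Cq per
#'   sample; samples must be a subset of the normalization factor's.
#' @param nf A `normalization_factors` object (or named positive vector).
#' @param target_efficiency Target amplification efficiency, fold per cycle
#'   (> 1; default 2).
#' @param calibrator Either sample identifiers, or (when `conditions` is
#'   given) a condition label whose sample mean is scaled to 1.
#' @param conditions Optional named vector mapping sample to condition
#'   label, used for the calibrator lookup and for mean +/- SD aggregation
#'   over biological replicates.
#' @return A list of class `rel_expression` with `values` (per sample,
#'   calibrator mean = 1) and, when conditions are given, `aggregated`
#'   (condition, mean, sd, n).
#' @export
normalize_target <- function(target_cq, nf, target_efficiency = 2,
                             calibrator, conditions = NULL) {
  nfv <- if (inherits(nf, "normalization_factors")) nf$nf else nf
  norm_genes <- if (inherits(nf, "normalization_factors")) nf$genes else NA_character_
  if (is.null(names(target_cq)) || is.null(names(nfv))) {
    stop("target_cq and nf must be named by sample", call. = FALSE)
  }
  if (target_efficiency <= 1) {
    stop("target efficiency must exceed 1", call. = FALSE)
  }
  samples <- names(target_cq)
  missing_nf <- setdiff(samples, names(nfv))
  if (length(missing_nf)) {
    stop("no normalization factor for sample(s): ",
         paste(missing_nf, collapse = ", "), call. = FALSE)
  }
  if (!is.null(conditions) && is.null(names(conditions))) {
    stop("conditions must be named by sample", call. = FALSE)
  }
  r <- target_efficiency ^ (min(target_cq) - target_cq) / nfv[samples]

  cal_samples <- if (all(calibrator %in% samples)) {
    calibrator
  } else if (!is.null(conditions) && length(calibrator) == 1 &&
             calibrator %in% conditions[samples]) {
    samples[conditions[samples] == calibrator]
  } else {
    stop("calibrator sample(s)/condition not found: ",
         paste(calibrator, collapse = ", "), call. = FALSE)
  }
  values <- r / mean(r[cal_samples])

  aggregated <- NULL
  if (!is.null(conditions)) {
    cond <- conditions[samples]
    if (anyNA(cond)) stop("conditions must cover every target sample", call. = FALSE)
    aggregated <- do.call(rbind, lapply(unique(cond), function(cc) {
      v <- values[cond == cc]
      data.frame(condition = cc, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }
  structure(list(values = values, aggregated = aggregated,
                 normalizer = norm_genes, calibrator = calibrator,
                 target_efficiency = target_efficiency),
            class = "rel_expression")
}

#' @export
print.rel_expression <- function(x, ...) {
  cat("Relative expression (normalizer: ",
      paste(x$normalizer, collapse = " + "),
      "; calibrator: ", paste(x$calibrator, collapse = ","), " = 1)\n", sep = "")
  if (!is.null(x$aggregated)) {
    print(transform(x$aggregated, mean = round(mean, 3), sd = round(sd, 3)))
  } else {
    print(round(x$values, 3))
  }
  invisible(x)
}

#' Quantify one target under several candidate normalizer sets
#'
#' Builds the normalization factor for each candidate reference-gene set
#' and quantifies the target against each with identical calibrator
#' scaling, yielding overlay-ready side-by-side profiles (e.g. stable pair
#' vs stable singleton vs a known-unstable gene). Per-set errors are
#' collected, not fatal.
#'
#' @param target_cq Named numeric vector of target Cq per sample.
#' @param candidate_sets List of reference-gene character vectors.
#' @param qm A `quantity_matrix` holding the candidate reference genes.
#' @inheritParams normalize_target
#' @return Named list of `rel_expression` tables (or `error` entries),
#'   named by the joined gene sets.
#' @export
compare_normalizers <- function(target_cq, candidate_sets, qm,
                                target_efficiency = 2, calibrator,
                                conditions = NULL) {
  stop_if_not_matrix_obj(qm, "quantity_matrix", "qm")
  if (!length(candidate_sets)) return(stats::setNames(list(), character(0)))
  nms <- names(candidate_sets) %||%
    vapply(candidate_sets, paste, character(1), collapse = "+")
  nms[!nzchar(nms)] <- vapply(candidate_sets[!nzchar(nms)], paste,
                              character(1), collapse = "+")
  out <- lapply(candidate_sets, function(set) {
    tryCatch({
      if (!length(set)) stop("empty normalizer set", call. = FALSE)
      normalize_target(target_cq, normalization_factor(qm, set),
                       target_efficiency = target_efficiency,
                       calibrator = calibrator, conditions = conditions)
    }, error = function(e) list(error = conditionMessage(e)))
  })
  stats::setNames(out, nms)
}

#' Export relative-expression tables as a plot-ready long data frame
#'
#' @param tables Output of [compare_normalizers()] (error entries skipped).
#' @param conditions Optional named sample-to-condition vector.
#' @return Data frame with columns normalizer, sample, condition, value.
#' @export
rel_expression_table <- function(tables, conditions = NULL) {
  rows <- lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    if (!inherits(t, "rel_expression")) return(NULL)
    data.frame(normalizer = nm, sample = names(t$values),
               condition = if (!is.null(conditions)) {
                 unname(conditions[names(t$values)])
               } else NA_character_,
               value = unname(t$values), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
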