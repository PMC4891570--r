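# NormFinder model-based stability. The log-scale expression of gene i in
# sample j is modelled additively, y_ij = alpha_i + beta_j + eps_ij; a
# gene's stability value is the estimated standard deviation of its own
# error term (plus, in grouped mode, a shrunken gene-by-group bias). Lower
# values indicate more stable genes. Sample (loading) effects and per-gene
# abundance levels cancel in the fit, so the measure is invariant to both.

#' NormFinder stability values
#'
#' Single-group mode fits the additive two-way model by removing gene and
#' sample means: with residuals `r_ij = y_ij - mean_i - mean_j + grand`,
#' gene i's mean squared residual is `z_i = sum_j r_ij^2 / (n-1)` and its
#' variance estimate is `max(0, g/(g-2) * (z_i - sum_k z_k / (g(g-1))))`;
#' the stability value is its square root. Grouped mode additionally
#' estimates a gene-by-group bias d (the group mean of the full-fit
#' residuals), shrinks it by `var(d) / (var(d) + sigma2_i/n_g)`, and
#' averages `|d_tilde| + sqrt(sigma2_i/n_g)` over groups.
#'
#' @param x A `log_quantity_matrix`, a `quantity_matrix` (log2-transformed
#'   internally), or a plain gene x sample matrix of log-scale values
#'   (e.g. negated Cq; per-gene constants do not affect the result).
#' @param groups Optional per-sample group labels (vector in column order,
#'   or named by sample). At least 2 groups with at least 2 samples each.
#' @return A list of class `normfinder_result` with `stability` (named, the
#'   lower the more stable), `variance` (clipped at 0), `grouped`,
#'   `group_bias` (shrunken d, genes x groups; grouped mode only),
#'   `group_variance` (genes x groups; grouped mode only) and `clipped`
#'   (genes whose raw variance estimate fell below 0).
#' @export
normfinder_stability <- function(x, groups = NULL) {
  y <- if (inherits(x, "log_quantity_matrix")) {
    x$y
  } else if (inherits(x, "quantity_matrix")) {
    log2(x$q)
  } else {
    as.matrix(x)
  }
  g <- nrow(y); n <- ncol(y)
  if (g < 3) {
    stop("the NormFinder estimator is undefined for fewer than 3 genes",
         call. = FALSE)
  }
  if (is.null(rownames(y))) rownames(y) <- sprintf("G%02d", seq_len(g))
  if (any(!is.finite(y))) stop("log quantities must be finite", call. = FALSE)

  center2 <- function(m) {
    sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
  }
  single_var <- function(m) {
    nn <- ncol(m)
    r <- center2(m)
    z <- rowSums(r ^ 2) / (nn - 1)
    raw <- (g / (g - 2)) * (z - sum(z) / (g * (g - 1)))
    list(var = pmax(raw, 0), clipped = rownames(m)[raw < 0])
  }

  if (is.null(groups)) {
    if (n < 3) stop("single-group mode requires at least 3 samples", call. = FALSE)
    est <- single_var(y)
    return(structure(list(stability = sqrt(est$var),
                          variance = est$var,
                          grouped = FALSE,
                          group_bias = NULL, group_variance = NULL,
                          clipped = est$clipped),
                     class = "normfinder_result"))
  }

  groups <- if (!is.null(names(groups))) {
    if (!all(colnames(y) %in% names(groups))) {
      stop("groups must cover every sample", call. = FALSE)
    }
    groups[colnames(y)]
  } else {
    if (length(groups) != n) stop("groups must cover every sample", call. = FALSE)
    groups
  }
  groups <- as.character(groups)
  if (anyNA(groups)) stop("groups must cover every sample", call. = FALSE)
  lev <- unique(groups)
  if (length(lev) < 2) stop("grouped mode requires at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 samples (group '",
         names(sizes)[sizes < 2][1], "' has ", min(sizes), ")", call. = FALSE)
  }

  r_full <- center2(y)
  clipped <- character(0)
  contrib <- matrix(NA_real_, g, length(lev), dimnames = list(rownames(y), lev))
  bias <- contrib
  gvar <- contrib
  for (gr in lev) {
    cols <- groups == gr
    n_g <- sum(cols)
    est <- single_var(y[, cols, drop = FALSE])
    clipped <- union(clipped, est$clipped)
    d <- rowMeans(r_full[, cols, drop = FALSE])
    var_d <- stats::var(d)
    denom <- var_d + est$var / n_g
    d_shr <- ifelse(denom <= 0, 0, d * var_d / denom)
    bias[, gr] <- d_shr
    gvar[, gr] <- est$var
    contrib[, gr] <- abs(d_shr) + sqrt(est$var / n_g)
  }
  structure(list(stability = rowMeans(contrib),
                 variance = rowMeans(gvar),
                 grouped = TRUE,
                 group_bias = bias, group_variance = gvar,
                 clipped = clipped),
            class = "normfinder_result")
}

#' Rank genes by NormFinder stability
#'
#' Ascending stability value; ties keep the deterministic gene ordering.
#'
#' @param res A `normfinder_result`.
#' @return Character vector of gene identifiers, best (most stable) first.
#' @export
rank_by_stability <- function(res) {
  stop_if_not_matrix_obj(res, "normfinder_result", "res")
  names(res$stability)[order(res$stability)]
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("NormFinder stability (", if (x$grouped) "grouped" else "single group",
      "), ", length(x$stability), " genes\n", sep = "")
  s <- sort(x$stability)
  print(round(s, 4))
  if (length(x$clipped)) {
    cat("  variance clipped at 0 for:", paste(x$clipped, collapse = ", "), "\n")
  }
  invisible(x)
}
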