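# Cq -> relative-quantity transformation and standard-curve efficiency
# estimation. Both stability algorithms consume relative quantities
# Q = E^(minCq - Cq), computed per gene so the sample with the lowest Cq
# (highest abundance) gets Q = 1 exactly.

#' Convert a Cq matrix to relative quantities
#'
#' For gene g and sample s, `Q[g,s] = E_g^(minCq_g - Cq[g,s])`, where `E_g`
#' is either a single fixed amplification base (default 2, perfect doubling)
#' or the gene's measured assay efficiency. The per-gene minimum is taken
#' within the analyzed sample subset; because Q rescaling per gene is
#' stability-invariant, this choice does not affect rankings.
#'
#' @param m A `cq_matrix`.
#' @param mode `"fixed_base"` (one base for all genes) or `"per_gene"`
#'   (efficiencies from the assay table).
#' @param base Amplification base for `fixed_base` mode (fold per cycle).
#' @return A list of class `quantity_matrix` with matrix `q` (per-gene max
#'   exactly 1, all values in (0, 1]), the efficiency mode and the per-gene
#'   efficiencies used.
#' @export
relative_quantities <- function(m, mode = c("fixed_base", "per_gene"), base = 2) {
  stop_if_not_matrix_obj(m, "cq_matrix", "m")
  mode <- match.arg(mode)
  if (any(is.na(m$cq))) stop("Cq matrix must be complete", call. = FALSE)
  g <- nrow(m$cq)
  if (mode == "fixed_base") {
    eff <- stats::setNames(rep(base, g), m$genes)
  } else {
    if (is.null(m$assays) || !"efficiency" %in% names(m$assays)) {
      stop("per_gene mode needs an assay table with an efficiency column",
           call. = FALSE)
    }
    idx <- match(m$genes, m$assays$gene_id)
    if (anyNA(idx)) {
      stop("no assay efficiency for gene(s): ",
           paste(m$genes[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    eff <- stats::setNames(as.numeric(m$assays$efficiency[idx]), m$genes)
  }
  if (any(eff <= 1)) {
    stop("amplification efficiency must exceed 1 (fold per cycle)", call. = FALSE)
  }
  dcq <- apply(m$cq, 1, min) - m$cq          # minCq - Cq, <= 0
  q <- eff ^ dcq                              # recycles eff down rows
  dimnames(q) <- dimnames(m$cq)
  structure(list(q = q, genes = m$genes, samples = m$samples,
                 meta = m$meta, assays = m$assays,
                 efficiency_mode = mode, efficiencies = eff),
            class = "quantity_matrix")
}

#' Wrap a positive matrix as a relative-quantity matrix
#'
#' Rescales each gene (row) by its maximum so the invariant "per-gene max
#' Q = 1" holds. Useful for constructing inputs directly in tests and
#' examples; stability measures are invariant to the per-gene rescaling.
#'
#' @param q Positive numeric matrix, genes in rows.
#' @param meta Optional sample metadata.
#' @return A `quantity_matrix`.
#' @export
as_quantity_matrix <- function(q, meta = NULL) {
  q <- as.matrix(q)
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("relative quantities must be finite and positive", call. = FALSE)
  }
  if (is.null(rownames(q))) rownames(q) <- sprintf("G%02d", seq_len(nrow(q)))
  if (is.null(colnames(q))) colnames(q) <- sprintf("S%03d", seq_len(ncol(q)))
  q <- q / apply(q, 1, max)
  structure(list(q = q, genes = rownames(q), samples = colnames(q),
                 meta = meta, assays = NULL,
                 efficiency_mode = "fixed_base",
                 efficiencies = stats::setNames(rep(2, nrow(q)), rownames(q))),
            class = "quantity_matrix")
}

#' Log-transform relative quantities
#'
#' @param qm A `quantity_matrix`.
#' @param log_base Logarithm base (default 2, the Cq doubling scale).
#' @return A list of class `log_quantity_matrix` with matrix `y`
#'   (per-gene max 0).
#' @export
log_quantities <- function(qm, log_base = 2) {
  stop_if_not_matrix_obj(qm, "quantity_matrix", "qm")
  if (log_base <= 0 || log_base == 1) stop("invalid log base", call. = FALSE)
  y <- log(qm$q) / log(log_base)
  structure(list(y = y, genes = qm$genes, samples = qm$samples,
                 meta = qm$meta, log_base = log_base),
            class = "log_quantity_matrix")
}

#' Amplification efficiency from a dilution-series standard curve
#'
#' Ordinary least squares of Cq on log10 template dilution; the efficiency
#' (fold amplification per cycle) is `10^(-1/slope)`. A perfect doubling
#' assay has slope -3.3219 and efficiency 2.
#'
#' @param points Data frame with columns `log10_dilution` and `cq`, or a
#'   numeric vector of log10 dilutions (then `cq` must be given).
#' @param cq Cq values when `points` is a vector.
#' @param gene_id Optional assay label carried into the result.
#' @return A list of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and `efficiency`.
#' @export
efficiency_from_standard_curve <- function(points, cq = NULL, gene_id = NA_character_) {
  if (is.data.frame(points)) {
    dil <- points$log10_dilution
    cqv <- points$cq
  } else {
    dil <- as.numeric(points)
    cqv <- as.numeric(cq)
  }
  if (length(dil) != length(cqv) || length(dil) < 3) {
    stop("a standard curve needs at least 3 dilution points", call. = FALSE)
  }
  if (length(unique(dil)) < 2) {
    stop("at least 2 distinct dilutions are required", call. = FALSE)
  }
  fit <- stats::lm(cqv ~ dil)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("standard-curve slope must be negative: more template must lower Cq",
         call. = FALSE)
  }
  structure(list(gene_id = gene_id,
                 points = data.frame(log10_dilution = dil, cq = cqv),
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(cqv, stats::fitted(fit))^2,
                 efficiency = 10 ^ (-1 / slope)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Standard curve", if (!is.na(x$gene_id)) paste0("(", x$gene_id, ")"), "\n")
  cat(sprintf("  slope %.4f, intercept %.3f, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  efficiency %.3f-fold per cycle\n", x$efficiency))
  invisible(x)
}
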