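# Independent brute-force oracles and fixture builders. The oracles are
# written as plain double loops, deliberately naive, so they stay
# independent of the vectorized implementation paths they check.

# geNorm M by explicit double loop over gene pairs.
oracle_genorm_m <- function(q) {
  l <- log2(q)
  g <- nrow(q)
  m <- numeric(g)
  for (j in seq_len(g)) {
    acc <- 0
    for (k in seq_len(g)) {
      if (k != j) acc <- acc + stats::sd(l[j, ] - l[k, ])
    }
    m[j] <- acc / (g - 1)
  }
  stats::setNames(m, rownames(q))
}

# Stepwise exclusion recomputed from scratch at every step with the oracle
# M, using the same tie rule (exclude the tied gene latest in row order).
oracle_exclusion_order <- function(q) {
  genes <- rownames(q)
  idx <- stats::setNames(seq_along(genes), genes)
  remaining <- genes
  excluded <- character(0)
  while (length(remaining) > 2) {
    m <- oracle_genorm_m(q[remaining, , drop = FALSE])
    worst <- names(m)[m == max(m)]
    excl <- worst[which.max(idx[worst])]
    excluded <- c(excluded, excl)
    remaining <- setdiff(remaining, excl)
  }
  list(excluded = excluded, final_pair = remaining[order(idx[remaining])])
}

# Random positive quantity matrix (log-normal on the Cq doubling scale).
rand_q <- function(g, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- 2 ^ matrix(stats::rnorm(g * n, 0, 1.5), g, n,
                  dimnames = list(sprintf("G%02d", seq_len(g)),
                                  sprintf("S%03d", seq_len(n))))
  q
}

rand_qm <- function(g, n, seed = NULL) as_quantity_matrix(rand_q(g, n, seed))

# Small long-format Cq CSV on disk; returns the path.
write_fixture_csv <- function(lines, dir = tempdir()) {
  path <- tempfile("cq", tmpdir = dir, fileext = ".csv")
  writeLines(lines, path)
  path
}

# Wrap a complete Cq matrix as a cq_matrix object without replicate rows.
make_cq_matrix <- function(cq, meta = NULL, assays = NULL) {
  structure(list(cq = cq, genes = rownames(cq), samples = colnames(cq),
                 meta = meta, assays = assays, dropped_samples = character(0)),
            class = "cq_matrix")
}
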