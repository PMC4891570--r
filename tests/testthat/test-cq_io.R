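# Cq ingestion, QC, replicate aggregation and metadata subsetting.

test_that("long reader parses records, degenerate and malformed inputs", {
  p <- write_fixture_csv(c("sample_id,gene_id,replicate,cq",
                           "S1,geneA,1,20.0", "S1,geneA,2,20.2",
                           "S1,geneB,1,25.0"))
  ds <- read_cq_long(p)
  expect_s3_class(ds, "cq_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(ds$cq, c(20.0, 20.2, 25.0))

  empty <- read_cq_long(write_fixture_csv("sample_id,gene_id,replicate,cq"))
  expect_equal(nrow(empty), 0)

  expect_error(read_cq_long(write_fixture_csv(c("sample_id,gene_id,cq",
                                                "S1,geneA,20"))),
               "replicate")
  expect_error(read_cq_long(write_fixture_csv(c("sample_id,gene_id,replicate,cq",
                                                "S1,geneA,1,20.0",
                                                "S1,geneB,1,oops"))),
               "row 2")
})

test_that("a Cq of NA survives parsing and is flagged by validation", {
  rows <- c(sprintf("S%d,geneA,1,%.1f", 1:5, 20 + 1:5 / 10),
            "S1,geneB,1,NA", sprintf("S%d,geneB,1,%.1f", 2:5, 24 + 2:5 / 10))
  p <- write_fixture_csv(c("sample_id,gene_id,replicate,cq", rows))
  ds <- read_cq_long(p)
  expect_true(is.na(ds$cq[ds$gene_id == "geneB" & ds$sample_id == "S1"]))
  qc <- validate_dataset(ds)
  expect_equal(qc$missing_cells,
               data.frame(gene_id = "geneB", sample_id = "S1",
                          stringsAsFactors = FALSE))
  expect_equal(qc$dropped_samples, "S1")
  expect_equal(qc$dropped_genes, character(0))
})

test_that("wide reader is content-equivalent to the long reader", {
  wide <- write_fixture_csv(c("gene_id,S1.1,S2.1",
                              "geneA,20.0,21.0", "geneB,25.0,26.0"))
  ds <- read_cq_wide(wide)
  expect_equal(nrow(ds), 4)

  # round trip of a random replicate-level dataset through both formats
  set.seed(7)
  sim <- simulate_cq(sim_config(n_genes = 5, n_samples = 6,
                                n_tech_replicates = 3, seed = 7))
  ds0 <- sim$dataset
  long_path <- tempfile(fileext = ".csv")
  write_cq_long(ds0, long_path)
  wide_df <- data.frame(gene_id = sort(unique(ds0$gene_id)))
  cols <- unique(ds0[, c("sample_id", "replicate")])
  for (i in seq_len(nrow(cols))) {
    sel <- ds0[ds0$sample_id == cols$sample_id[i] &
                 ds0$replicate == cols$replicate[i], ]
    wide_df[[paste0(cols$sample_id[i], ".", cols$replicate[i])]] <-
      sel$cq[match(wide_df$gene_id, sel$gene_id)]
  }
  wide_path <- tempfile(fileext = ".csv")
  utils::write.csv(wide_df, wide_path, row.names = FALSE, quote = FALSE)

  key <- function(d) d[order(d$sample_id, d$gene_id, d$replicate), ]
  a <- key(as.data.frame(read_cq_long(long_path)))
  b <- key(as.data.frame(read_cq_wide(wide_path)))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[, 1:3], b[, 1:3])
  expect_equal(a$cq, b$cq, tolerance = 1e-12)

  expect_error(read_cq_wide(write_fixture_csv(c("gene_id,S1.1,S1.1",
                                                "geneA,20,21"))),
               "duplicate column")
  blank <- read_cq_wide(write_fixture_csv(c("gene_id,S1.1,S2.1",
                                            "geneA,20.0,", "geneB,25.0,26.0")))
  expect_equal(sum(is.na(blank$cq)), 1)
})

test_that("replicate-SD QC flags dispersed triplets with the sample SD", {
  ds <- as_cq_dataset(data.frame(
    sample_id = rep("S1", 6), gene_id = rep(c("A", "B"), each = 3),
    replicate = rep(1:3, 2),
    cq = c(20.0, 20.1, 20.2, 20.0, 20.1, 26.0)))
  qc <- validate_dataset(ds, max_replicate_sd = 0.5)
  expect_equal(qc$replicate_sd_flags$gene_id, "B")
  expect_equal(qc$replicate_sd_flags$sd, sd(c(20.0, 20.1, 26.0)))
  expect_equal(nrow(qc$missing_cells), 0)
})

test_that("replicate aggregation collapses to a complete deterministic matrix", {
  ds <- as_cq_dataset(data.frame(
    sample_id = rep("S1", 6), gene_id = rep(c("A", "B"), each = 3),
    replicate = rep(1:3, 2),
    cq = c(20.0, 20.2, 20.4, 20.0, 20.2, 24.0)))
  m <- aggregate_replicates(ds)
  expect_equal(unname(m$cq["A", "S1"]), 20.2)
  m2 <- aggregate_replicates(ds, method = "median")
  expect_equal(unname(m2$cq["B", "S1"]), 20.2)

  # invariant to replicate ordering
  shuf <- as_cq_dataset(as.data.frame(ds)[sample(6), ])
  expect_equal(aggregate_replicates(shuf)$cq, m$cq)

  # full study design shape
  pd <- longan_study_design(seed = 3)
  M <- aggregate_replicates(pd$dataset, meta = pd$meta)
  expect_equal(dim(M$cq), c(12L, 150L))
  expect_false(anyNA(M$cq))
})

test_that("a gene missing in too many samples is a hard error", {
  df <- expand.grid(sample_id = paste0("S", 1:10), gene_id = c("A", "B"),
                    replicate = 1L, stringsAsFactors = FALSE)
  df$cq <- 20
  df$cq[df$gene_id == "B" & df$sample_id %in% paste0("S", 1:5)] <- NA
  expect_error(aggregate_replicates(as_cq_dataset(df)),
               "remove them before aggregation")
})

test_that("metadata subsetting matches the study bookkeeping and composes", {
  pd <- longan_study_design(seed = 5)
  m <- aggregate_replicates(pd$dataset, meta = pd$meta)
  expect_equal(length(subset_by_experiment(m, list(experimental_set = "NAA"))$samples), 9)
  expect_equal(length(subset_by_experiment(
    m, list(tissue = "aril", treatment = "4C"))$samples), 6)
  expect_error(subset_by_experiment(m, list(tissue = "no-such-tissue")),
               "fewer than 2")

  # filtering by A then B equals filtering by A AND B
  ab <- subset_by_experiment(subset_by_experiment(m, list(tissue = "pericarp")),
                             list(experimental_set = "NAA"))
  both <- subset_by_experiment(m, list(tissue = "pericarp",
                                       experimental_set = "NAA"))
  expect_equal(ab$cq, both$cq)
  expect_equal(ab$meta, both$meta)
  # gene order preserved
  expect_equal(ab$genes, m$genes)
})
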