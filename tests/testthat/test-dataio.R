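test_that("labeled_dataset maps class names deterministically", {
  x <- matrix(rnorm(4), 2, 2)
  ds <- make_ds(x, c("tumour", "normal"))
  expect_identical(ds$labels, c(1L, -1L))  # lexicographically larger -> +1
  expect_identical(unname(ds$class_names[["+1"]]), "tumour")

  ds2 <- make_ds(x, c("tumour", "normal"), positive = "normal")
  expect_identical(ds2$labels, c(-1L, 1L))
})

test_that("labeled_dataset validates shapes and label arity", {
  x <- matrix(rnorm(6), 2, 3)
  expect_error(make_ds(x, c(1, -1, 1)), "label count")
  expect_error(make_ds(matrix(rnorm(9), 3, 3), c("a", "b", "c")),
               "distinct values")
})

test_that("expression tables round-trip in both orientations", {
  syn <- synth_dataset(synth_config(n_per_class = 5, m_informative = 2,
                                    m_redundant = 1, m_noise = 7, seed = 3))
  ds <- syn$dataset
  for (orient in c("genes_in_rows", "samples_in_rows")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_expression_table(ds, path, orientation = orient)
    back <- read_expression_table(path, orientation = orient,
                                  positive = "tumour")
    expect_equal(back$x, ds$x)
    expect_identical(back$labels, ds$labels)
    expect_identical(colnames(back$x), colnames(ds$x))
  }
  # csv dialect
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_table(ds, path)
  expect_equal(read_expression_table(path, positive = "tumour")$x, ds$x)
})

test_that("orientation flag is self-inverse", {
  syn <- synth_dataset(synth_config(n_per_class = 4, m_informative = 1,
                                    m_redundant = 0, m_noise = 5, seed = 9))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(syn$dataset, p1, orientation = "genes_in_rows")
  write_expression_table(syn$dataset, p2, orientation = "samples_in_rows")
  a <- read_expression_table(p1, "genes_in_rows", positive = "tumour")
  b <- read_expression_table(p2, "samples_in_rows", positive = "tumour")
  expect_equal(a$x, b$x)
  expect_identical(a$labels, b$labels)
})

test_that("labels can come from a separate two-column file", {
  syn <- synth_dataset(synth_config(n_per_class = 3, m_informative = 1,
                                    m_redundant = 0, m_noise = 2, seed = 2))
  ds <- syn$dataset
  mat <- withr::local_tempfile(fileext = ".tsv")
  labf <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(ds, mat)
  # shuffle label file rows: matching must go by sample id
  idx <- rev(seq_len(nrow(ds$x)))
  writeLines(paste(rownames(ds$x)[idx],
                   ifelse(ds$labels[idx] == 1L, "tumour", "normal"),
                   sep = "\t"),
             labf)
  back <- read_expression_table(mat, label_file = labf, positive = "tumour")
  expect_identical(back$labels, ds$labels)
})

test_that("parse errors name the offending location", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "g1\t1.0\t2.0", "g2\t3.0"), p)
  expect_error(read_expression_table(p), "ragged row: line 3")

  writeLines(c("gene_id\tS1\tS2", "g1\t1.0\toops", "class\ta\tb"), p)
  expect_error(read_expression_table(p), "row 'g1', column 'S2'")

  writeLines(c("gene_id\tS1\tS2", "g1\t1\t2"), p)
  expect_error(read_expression_table(p), "no class labels")
})

test_that("missing values are rejected unless explicitly allowed", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2\tS3", "g1\t1\tNA\t3", "g2\t4\t5\t6",
               "class\ta\tb\ta"), p)
  expect_error(read_expression_table(p), "missing value")
  ds <- read_expression_table(p, allow_missing = TRUE)
  expect_true(anyNA(ds$x))
  imp <- impute_missing(ds)
  expect_false(anyNA(imp$x))
  expect_equal(imp$x[2, "g1"], 2)  # median of observed values 1, 3
  expect_equal(attr(imp, "impute_log")$imputed_cells, 1L)
})

test_that("selection reports round-trip with order preserved", {
  syn <- synth_dataset(synth_config(n_per_class = 8, m_informative = 3,
                                    m_redundant = 2, m_noise = 10,
                                    effect = 3, seed = 5))
  fit <- genescreen(syn$dataset)
  p <- withr::local_tempfile(fileext = ".tsv")
  metrics <- list(accuracy = 93.75, mcc = 0.856)
  write_selection_report(fit$stage2, p, metrics = metrics)
  back <- read_selection_report(p)
  expect_identical(back$selection$gene_id, fit$stage2$gene_ids)
  expect_identical(colnames(back$selection),
                   c("rank", "gene_id", "stage", "relevance", "redundancy",
                     "score"))
  expect_equal(back$metrics[["accuracy"]], 93.75)

  # empty metrics: selection block still written, metrics block omitted
  write_selection_report(fit$stage2, p)
  back2 <- read_selection_report(p)
  expect_length(back2$metrics, 0)
  expect_identical(back2$selection$gene_id, fit$stage2$gene_ids)
})
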