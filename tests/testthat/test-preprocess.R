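test_that("duplicate-gene removal keeps the first occurrence", {
  x <- matrix(1:12, 2, 6,
              dimnames = list(NULL, c("g1", "g2", "g1", "g3", "g2", "g1")))
  ds <- make_ds(x, c(-1, 1))
  out <- remove_duplicate_genes(ds)
  expect_identical(colnames(out$x), c("g1", "g2", "g3"))
  expect_equal(out$x[, "g1"], x[, 1], ignore_attr = TRUE)  # first kept
  expect_equal(attr(out, "removal_log")$removed_count, 3L)
  expect_identical(attr(out, "removal_log")$gene_ids, c("g1", "g2", "g1"))

  # all-unique input is unchanged
  ds2 <- make_ds(matrix(rnorm(8), 2, 4), c(-1, 1))
  out2 <- remove_duplicate_genes(ds2)
  expect_equal(out2$x, ds2$x)
  expect_equal(attr(out2, "removal_log")$removed_count, 0L)
})

test_that("dedup arithmetic matches the many-duplicates regime", {
  # 60 entries of which 13 are later duplicate occurrences -> 47 unique
  ids <- sprintf("G%03d", 1:47)
  ids <- c(ids, sample(ids, 13))
  x <- matrix(rnorm(2 * 60), 2, 60, dimnames = list(NULL, ids))
  out <- remove_duplicate_genes(make_ds(x, c(-1, 1)))
  expect_equal(ncol(out$x), 47)
  expect_equal(attr(out, "removal_log")$removed_count, 13L)
})

test_that("per-sample standardization gives zero mean, unit population SD", {
  ds <- make_ds(rbind(c(1, 2, 3), c(10, 20, 60)), c(-1, 1))
  out <- standardize_samples(ds)
  expect_equal(out$x[1, ], c(-1.224744871391589, 0, 1.224744871391589),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (i in 1:2) {
    expect_lt(abs(mean(out$x[i, ])), 1e-9)
    expect_lt(abs(sqrt(mean((out$x[i, ] - mean(out$x[i, ]))^2)) - 1), 1e-9)
  }
  # idempotence
  out2 <- standardize_samples(out)
  expect_equal(out2$x, out$x, tolerance = 1e-9)
  # constant array is an error naming the sample
  bad <- make_ds(rbind(c(1, 1, 1), c(1, 2, 3)), c(-1, 1))
  rownames(bad$x) <- c("arrayA", "arrayB")
  expect_error(standardize_samples(bad), "arrayA")
})

test_that("MDL discretizer reproduces hand-evaluated cases", {
  # clear class-separated gap: exactly one cut inside (3, 10)
  cuts <- genescreen:::mdl_cut_points(c(1, 2, 3, 10, 11, 12),
                                      c("A", "A", "A", "B", "B", "B"))
  expect_length(cuts, 1)
  expect_equal(cuts, 6.5)

  # alternating classes: best gain 0.311 bits fails the MDL test
  expect_length(genescreen:::mdl_cut_points(c(1, 2, 3, 4),
                                            c("A", "B", "A", "B")), 0)

  # pure class: zero cuts for every gene
  expect_length(genescreen:::mdl_cut_points(rnorm(10), rep("A", 10)), 0)
})

test_that("discretizer bins follow the documented interval convention", {
  model <- structure(list(cuts = list(g = 6.5), fit_sample_ids = "s"),
                     class = "mdl_discretizer")
  ds <- make_ds(matrix(c(1, 6.5, 12), 3, 1, dimnames = list(NULL, "g")),
                c(-1, 1, 1))
  dds <- apply_discretizer(model, ds)
  expect_identical(as.vector(dds$x), c(0L, 1L, 1L))

  # no cuts -> all-zero bins; out-of-range values fall into edge bins
  model$cuts$g <- numeric(0)
  expect_identical(as.vector(apply_discretizer(model, ds)$x), c(0L, 0L, 0L))
  model$cuts$g <- c(2, 4)
  ds2 <- make_ds(matrix(c(-99, 3, 99), 3, 1, dimnames = list(NULL, "g")),
                 c(-1, 1, 1))
  expect_identical(as.vector(apply_discretizer(model, ds2)$x), c(0L, 1L, 2L))

  # unknown gene is an error
  ds3 <- make_ds(matrix(1, 1, 1, dimnames = list(NULL, "other")), 1)
  expect_error(apply_discretizer(model, ds3), "absent")
})

test_that("recursive MDL equals brute-force search on small genes", {
  set.seed(41)
  for (case in 1:200) {
    n <- sample(4:8, 1)
    values <- if (case %% 2 == 0) rnorm(n) else round(rnorm(n), 1)
    labels <- sample(c(-1, 1), n, replace = TRUE)
    expect_equal(genescreen:::mdl_cut_points(values, labels),
                 oracle_mdl(values, labels),
                 info = sprintf("case %d", case))
  }
})

test_that("bins are invariant to strictly increasing transforms", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 16
    labels <- sample(c(-1L, 1L), n, replace = TRUE)
    v <- rnorm(n) + labels
    for (f in list(function(z) z^3, exp, function(z) 5 * z + 2)) {
      b1 <- findInterval(v, genescreen:::mdl_cut_points(v, labels))
      b2 <- findInterval(f(v), genescreen:::mdl_cut_points(f(v), labels))
      expect_identical(b1, b2)
    }
  }
})

test_that("applying a discretizer never consults labels", {
  syn <- synth_dataset(synth_config(n_per_class = 8, m_informative = 3,
                                    m_redundant = 0, m_noise = 5,
                                    effect = 2, seed = 11))
  model <- fit_mdl_discretizer(syn$dataset)
  a <- apply_discretizer(model, syn$dataset)
  flipped <- syn$dataset
  flipped$labels <- -flipped$labels
  b <- apply_discretizer(model, flipped)
  expect_identical(a$x, b$x)
})

test_that("refitting on already-discrete bins is idempotent", {
  syn <- synth_dataset(synth_config(n_per_class = 10, m_informative = 2,
                                    m_redundant = 0, m_noise = 4,
                                    effect = 4, seed = 13))
  model <- fit_mdl_discretizer(syn$dataset)
  dds <- apply_discretizer(model, syn$dataset)
  ds_bins <- labeled_dataset(matrix(as.numeric(dds$x), nrow(dds$x),
                                    dimnames = dimnames(dds$x)),
                             dds$labels)
  model2 <- fit_mdl_discretizer(ds_bins)
  dds2 <- apply_discretizer(model2, ds_bins)
  expect_identical(dds2$x, dds$x)
})
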