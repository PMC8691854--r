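test_that("GA defaults match the published search settings", {
  cfg <- ga_config()
  expect_equal(cfg$pop_size, 20L)
  expect_equal(cfg$generations, 20L)
  expect_equal(cfg$p_crossover, 0.6)
  expect_equal(cfg$p_mutation, 0.033)
  expect_error(ga_config(pop_size = 1), "pop_size")
  expect_error(ga_config(p_mutation = 1.5), "probabilities")
})

test_that("CFS merit obeys its closed forms", {
  y <- c(1L, 1L, -1L, -1L)
  dds <- bins_ds(cbind(perfect = c(1L, 1L, 0L, 0L),
                       copy = c(1L, 1L, 0L, 0L),
                       weak = c(1L, 0L, 0L, 0L)), y)
  # k = 1: merit equals SU with the class
  expect_equal(cfs_merit("weak", dds),
               symmetrical_uncertainty(dds$x[, "weak"], y))
  expect_equal(cfs_merit("perfect", dds), 1)
  # two identical perfectly predictive genes: 2*1/sqrt(2+2) = 1,
  # no better than the single gene
  expect_equal(cfs_merit(c("perfect", "copy"), dds), 1)
  expect_error(cfs_merit(character(0), dds), "empty")
})

test_that("merit rises when adding an informative non-redundant gene", {
  # two independent perfectly informative halves of the class signal
  y <- rep(c(1L, -1L), each = 4)
  g1 <- c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L)
  g2 <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)  # the class itself
  dds <- bins_ds(cbind(g1 = g1, g2 = g2), y)
  expect_gt(cfs_merit(c("g1", "g2"), dds), cfs_merit("g1", dds))
})

test_that("wrapper fitness is perfect on a separating gene, deterministic", {
  ds <- separable_ds(n = 20, m_noise = 5, seed = 2)
  model <- fit_mdl_discretizer(ds)
  dds <- apply_discretizer(model, ds)
  expect_equal(wrapper_accuracy_fitness("sep", dds), 1.0)
  a <- wrapper_accuracy_fitness(c("sep", "noise1"), dds, inner_seed = 4)
  b <- wrapper_accuracy_fitness(c("sep", "noise1"), dds, inner_seed = 4)
  expect_identical(a, b)
  # duplicating every sample leaves the (pooled) fitness structure valid
  dds2 <- dds
  dds2$x <- rbind(dds$x, dds$x)
  rownames(dds2$x) <- paste0("r", seq_len(nrow(dds2$x)))
  dds2$labels <- c(dds$labels, dds$labels)
  expect_equal(wrapper_accuracy_fitness("sep", dds2), 1.0)
})

test_that("wrapper fitness hovers at chance under permuted labels", {
  accs <- sapply(1:20, function(r) {
    ds <- withr::with_seed(3 + r, {
      labs <- sample(rep(c(-1L, 1L), each = 30))
      labeled_dataset(matrix(rnorm(60 * 4), 60,
                             dimnames = list(NULL, paste0("g", 1:4))), labs)
    })
    bins <- ds
    bins$x <- matrix(as.integer(ds$x > 0), nrow(ds$x),
                     dimnames = dimnames(ds$x))
    class(bins) <- c("discretized_dataset", "labeled_dataset")
    wrapper_accuracy_fitness(c("g1", "g2"), bins, inner_seed = r)
  })
  # binomial null: mean accuracy within 3 sigma of 0.5
  se <- sqrt(0.25 / (60 * 20))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("GA trivial, determinism and containment properties hold", {
  ds <- separable_ds(n = 16, m_noise = 8, seed = 5)
  dds <- apply_discretizer(fit_mdl_discretizer(ds), ds)
  # single candidate -> that gene, any seed
  for (s in c(1, 99)) {
    res <- ga_select("sep", dds, ga_config(seed = s))
    expect_identical(res$gene_ids, "sep")
  }
  cands <- ig_survivors(filter_by_ig(dds))
  r1 <- ga_select(cands, dds, ga_config(seed = 42))
  r2 <- ga_select(cands, dds, ga_config(seed = 42))
  expect_identical(r1$gene_ids, r2$gene_ids)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(r1$gene_ids %in% cands))
  expect_identical(r1$stage, "stage1")
})

test_that("elitism makes the best-fitness trace non-decreasing", {
  set.seed(8)
  bins <- matrix(sample(0:1, 24 * 12, replace = TRUE), 24, 12,
                 dimnames = list(NULL, paste0("g", 1:12)))
  dds <- bins_ds(bins, rep(c(-1L, 1L), 12))
  res <- ga_select(colnames(bins), dds, ga_config(seed = 3))
  expect_true(all(diff(res$trace$best) >= -1e-12))
})

test_that("a neutral GA (no crossover, no mutation) preserves the initial best", {
  set.seed(10)
  bins <- matrix(sample(0:1, 20 * 10, replace = TRUE), 20, 10,
                 dimnames = list(NULL, paste0("g", 1:10)))
  dds <- bins_ds(bins, rep(c(-1L, 1L), 10))
  res <- ga_select(colnames(bins), dds,
                   ga_config(p_crossover = 0, p_mutation = 0, seed = 6))
  expect_equal(res$trace$best[length(res$trace$best)], res$trace$best[1],
               tolerance = 1e-12)
  expect_equal(res$fitness, res$trace$best[1], tolerance = 1e-12)
})

test_that("GA lands in the top tier of exhaustively enumerated subsets", {
  ds <- withr::with_seed(21, {
    labs <- rep(c(-1L, 1L), each = 15)
    x <- cbind(matrix(rnorm(30 * 4, mean = rep(labs, 4) * 0.8), 30, 4),
               matrix(rnorm(30 * 6), 30, 6))
    colnames(x) <- paste0("g", 1:10)
    labeled_dataset(x, labs)
  })
  dds <- apply_discretizer(fit_mdl_discretizer(ds), ds)
  oracle <- oracle_all_merits(dds$x, dds$labels)
  cutoff <- stats::quantile(oracle$merits, 0.95)
  hits <- sapply(1:20, function(s) {
    res <- ga_select(colnames(dds$x), dds, ga_config(seed = s))
    mask <- colnames(dds$x) %in% res$gene_ids
    oracle_merit_of(oracle, mask) >= cutoff - 1e-12
  })
  expect_true(all(hits))
})
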