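test_that("classifier adapters handle canonical small cases", {
  # single training sample: constant predictor for every kind
  for (kind in c("svm", "nb", "dt", "knn")) {
    fit <- train_classifier(kind, matrix(1.0, 1, 2), 1L)
    expect_identical(predict_classifier(fit, matrix(rnorm(6), 3, 2)),
                     rep(1L, 3))
  }
  # XOR-labelled data: 1-NN memorises the training set
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(-1L, 1L, 1L, -1L)
  fit <- train_classifier("knn", x, y, knn_k = 1)
  expect_identical(predict_classifier(fit, x), y)
  # separable data: every adapter gets it right
  ds <- separable_ds(n = 16, m_noise = 2, seed = 4)
  for (kind in c("svm", "nb", "dt", "knn")) {
    fit <- train_classifier(kind, ds$x, ds$labels)
    expect_identical(predict_classifier(fit, ds$x), ds$labels,
                     info = kind)
  }
  expect_error(train_classifier("boost", ds$x, ds$labels))
})

test_that("adapter defaults serialize to the documented settings", {
  d <- classifier_defaults()
  expect_equal(d$svm, list(kernel = "linear", cost = 1))
  expect_equal(d$knn$k, 1L)
  expect_equal(d$dt$split, "information")
  expect_equal(classifier_defaults(knn_k = 7)$knn$k, 7L)
})

test_that("folds partition samples and respect stratification", {
  labels <- rep(c(-1L, 1L), c(22, 40))
  folds <- make_folds(labels, k = 10, seed = 2)
  expect_setequal(unique(folds), 1:10)
  expect_equal(length(folds), 62)
  for (f in 1:10) {
    expect_true(sum(folds == f & labels == 1L) %in% 3:5)
    expect_true(sum(folds == f & labels == -1L) %in% 1:3)
  }
  expect_identical(make_folds(labels, 10, seed = 2),
                   make_folds(labels, 10, seed = 2))
  expect_error(make_folds(labels, k = 100), "cannot make")
})

test_that("hold-out split sizes match a 70/30 partition of 62 samples", {
  labels <- rep(c(-1L, 1L), c(22, 40))
  ts <- genescreen:::protocol_test_sets(protocol("split", seed = 5), labels)
  expect_length(ts, 1)
  n_test <- sum(ts[[1]])
  expect_gte(n_test, 16)
  expect_lte(n_test, 19)
  # both classes present on both sides
  expect_equal(length(unique(labels[ts[[1]]])), 2)
  expect_equal(length(unique(labels[!ts[[1]]])), 2)
})

test_that("LOOCV evaluates each sample exactly once", {
  ds <- separable_ds(n = 10, m_noise = 3, seed = 6)
  cfg <- pipeline_config(classifiers = "knn", evaluate_stages = "stage2")
  ev <- run_protocol(ds, protocol("loocv"), cfg)
  cm <- ev$stages$stage2$knn$cm
  expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, 10)
  expect_equal(sort(unique(ev$predictions$sample_id)),
               sort(rownames(ds$x)))
  expect_equal(nrow(ev$predictions), 10)
})

test_that("a perfectly separating gene yields 100% pooled accuracy", {
  ds <- separable_ds(n = 20, m_noise = 6, seed = 8)
  cfg <- pipeline_config()
  ev <- run_protocol(ds, protocol("kfold", k = 10), cfg)
  for (cl in c("svm", "nb", "dt", "knn"))
    expect_equal(ev$stages$stage2[[cl]]$metrics$accuracy, 100, info = cl)
  # pooled totals equal the sample count under k-fold too
  cm <- ev$stages$stage2$svm$cm
  expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, 20)
})

test_that("per-fold selection never reads test labels", {
  ds <- separable_ds(n = 16, m_noise = 6, seed = 3)
  prot <- protocol("split", seed = 2, stratified = FALSE)
  cfg <- pipeline_config(classifiers = "knn")
  ev1 <- run_protocol(ds, prot, cfg)
  # permute the labels of the test partition only
  test <- genescreen:::protocol_test_sets(prot, ds$labels)[[1]]
  ds2 <- ds
  ds2$labels[test] <- withr::with_seed(9, sample(ds$labels[test]))
  ev2 <- run_protocol(ds2, prot, cfg)
  expect_identical(ev1$selections, ev2$selections)
  expect_identical(
    ev1$predictions[c("sample_id", "classifier", "pred")],
    ev2$predictions[c("sample_id", "classifier", "pred")])
})

test_that("global selection mode equals evaluating a saved selection", {
  syn <- synth_dataset(synth_config(n_per_class = 10, m_informative = 3,
                                    m_redundant = 2, m_noise = 15,
                                    effect = 2.5, seed = 14))
  cfg <- pipeline_config(selection_mode = "global", classifiers = "knn",
                         prot = protocol("kfold", k = 5))
  ev_global <- run_protocol(syn$dataset, cfg$protocol, cfg)
  fit <- genescreen(syn$dataset, config = cfg)
  ev_fixed <- run_protocol(syn$dataset, cfg$protocol, cfg,
                           selection = list(stage1 = fit$stage1,
                                            stage2 = fit$stage2))
  expect_equal(evaluation_table(ev_global), evaluation_table(ev_fixed))
  expect_true(ev_global$optimistic)
})

test_that("stratification failures are reported", {
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  ds <- labeled_dataset(x, c(1L, rep(-1L, 5)))
  expect_error(run_protocol(ds, protocol("kfold", k = 3),
                            pipeline_config(classifiers = "knn")),
               ">= 2 samples per class")
})
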