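#' Evaluation protocol descriptor
#'
#' @param kind `"kfold"` (stratified 10-fold by default), `"loocv"`
#'   (leave-one-out), or `"split"` (one stratified hold-out split,
#'   70/30 by default).
#' @param k number of folds for `"kfold"`.
#' @param train_frac training fraction for `"split"`.
#' @param seed RNG seed for fold/split assignment.
#' @param stratified preserve class proportions across folds/splits.
#' @returns A list of class `gs_protocol`.
#' @export
protocol <- function(kind = c("kfold", "loocv", "split"),
                     k = 10L, train_frac = 0.7, seed = 1L,
                     stratified = TRUE) {
  kind <- match.arg(kind)
  if (kind == "kfold" && k < 2L) stopf("k must be >= 2")
  if (kind == "split" && (train_frac <= 0 || train_frac >= 1))
    stopf("train_frac must lie in (0, 1)")
  structure(list(kind = kind, k = as.integer(k), train_frac = train_frac,
                 seed = as.integer(seed), stratified = stratified),
            class = "gs_protocol")
}

#' Assign samples to cross-validation folds
#'
#' Stratified assignment shuffles each class separately and deals its
#' samples across folds round-robin, so fold class proportions track the
#' dataset's.
#'
#' @param labels class labels.
#' @param k number of folds (`k = length(labels)` gives LOOCV).
#' @param seed RNG seed.
#' @param stratified stratify by class.
#' @returns Integer fold id (1..k) per sample.
#' @export
make_folds <- function(labels, k, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (k > n) stopf("cannot make %d folds from %d samples", k, n)
  with_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    folds
  })
}

# test-set membership per evaluation unit, as a list of logical vectors
protocol_test_sets <- function(prot, labels) {
  n <- length(labels)
  if (prot$kind == "loocv") {
    lapply(seq_len(n), function(i) seq_len(n) == i)
  } else if (prot$kind == "kfold") {
    folds <- make_folds(labels, prot$k, seed = prot$seed,
                        stratified = prot$stratified)
    lapply(sort(unique(folds)), function(f) folds == f)
  } else {
    test <- with_seed(prot$seed, {
      keep <- logical(n)
      if (prot$stratified) {
        for (cl in unique(labels)) {
          idx <- sample(which(labels == cl))
          n_train <- max(1L, min(length(idx) - 1L,
                                 round(prot$train_frac * length(idx))))
          keep[idx[seq_len(n_train)]] <- TRUE
        }
      } else {
        n_train <- max(1L, min(n - 1L, round(prot$train_frac * n)))
        keep[sample.int(n, n_train)] <- TRUE
      }
      !keep
    })
    list(test)
  }
}

#' Run the leakage-safe evaluation harness
#'
#' Evaluates the two-stage selection pipeline under a resampling protocol.
#' For every fold (or the single hold-out split) the discretizer is fitted
#' and both selection stages are run on the training samples only; the
#' fitted models are then applied to the held-out samples, classifiers are
#' trained on the training portion restricted to the selected genes, and
#' test predictions are pooled into one confusion matrix per classifier
#' and stage.
#'
#' With `selection_mode = "global"` (or an explicit `selection`), gene
#' selection is instead performed once on all samples and only classifier
#' training/testing follows the protocol — this mirrors reporting a single
#' selected subset but is optimistic, and results are labelled as such.
#'
#' @param ds a [labeled_dataset()] with binary labels.
#' @param prot a [protocol()].
#' @param config a [pipeline_config()].
#' @param selection optional fixed selection: a list with character
#'   elements `stage1` and `stage2` (or objects carrying `gene_ids`).
#'   Implies global-style evaluation.
#' @returns An object of class `gs_evaluation`: per stage and classifier,
#'   the pooled `confusion_matrix`, its [binary_metrics()], and ROC
#'   points; plus the per-fold selected genes and a long prediction table.
#' @export
run_protocol <- function(ds, prot = protocol(), config = pipeline_config(),
                         selection = NULL) {
  require_binary(ds, "protocol evaluation")
  ds <- preprocess_dataset(ds, config)
  labels <- ds$labels
  if (min(table(labels)) < 2L && prot$kind != "loocv")
    stopf("stratified protocols need >= 2 samples per class")
  test_sets <- protocol_test_sets(prot, labels)

  global <- !is.null(selection) || config$selection_mode == "global"
  if (is.null(selection) && global) {
    sel_all <- two_stage_select(ds, config)
    selection <- list(stage1 = sel_all$stage1$gene_ids,
                      stage2 = sel_all$stage2$gene_ids)
  }
  if (!is.null(selection)) {
    selection <- lapply(selection, function(s)
      if (is.character(s)) s else s$gene_ids)
  }

  stages <- config$evaluate_stages
  classifiers <- config$classifiers
  pred_rows <- list()
  fold_selections <- list()

  for (f in seq_along(test_sets)) {
    test <- test_sets[[f]]
    train_ds <- subset_dataset(ds, samples = which(!test))
    test_ds <- subset_dataset(ds, samples = which(test))
    if (length(unique(train_ds$labels)) < 2L)
      stopf("stratification error: training portion of fold %d lacks a class", f)

    if (global) {
      genes_by_stage <- selection[stages]
      union_genes <- unique(unlist(genes_by_stage))
      model <- fit_mdl_discretizer(subset_dataset(train_ds,
                                                  genes = union_genes))
    } else {
      fold_cfg <- config
      fold_cfg$ga$seed <- config$ga$seed + f
      sel <- two_stage_select(train_ds, fold_cfg)
      genes_by_stage <- list(stage1 = sel$stage1$gene_ids,
                             stage2 = sel$stage2$gene_ids)[stages]
      model <- sel$discretizer
    }
    fold_selections[[f]] <- genes_by_stage

    for (stage in stages) {
      genes <- genes_by_stage[[stage]]
      dtr <- apply_discretizer(model, subset_dataset(train_ds, genes = genes))
      dte <- apply_discretizer(model, subset_dataset(test_ds, genes = genes))
      for (cl in classifiers) {
        fit <- train_classifier(cl, dtr$x, dtr$labels, knn_k = config$knn_k)
        pred <- predict_classifier(fit, dte$x)
        score <- tryCatch(predict_classifier(fit, dte$x, type = "score"),
                          error = function(e) rep(NA_real_, nrow(dte$x)))
        pred_rows[[length(pred_rows) + 1L]] <-
          data.frame(sample_id = sample_ids(dte), fold = f, stage = stage,
                     classifier = cl, truth = dte$labels, pred = pred,
                     score = as.numeric(score), stringsAsFactors = FALSE)
      }
    }
  }

  predictions <- do.call(rbind, pred_rows)
  results <- list()
  for (stage in stages) {
    results[[stage]] <- list()
    for (cl in classifiers) {
      p <- predictions[predictions$stage == stage &
                         predictions$classifier == cl, ]
      cm <- confusion_matrix(truth = p$truth, pred = p$pred)
      results[[stage]][[cl]] <- list(
        cm = cm,
        metrics = binary_metrics(cm),
        roc = roc_points(p$truth, p$pred,
                         if (!anyNA(p$score)) p$score))
    }
  }

  structure(list(protocol = prot, config = config, stages = results,
                 predictions = predictions, selections = fold_selections,
                 global_selection = if (global) selection,
                 optimistic = global, class_names = ds$class_names),
            class = "gs_evaluation")
}

#' @export
print.gs_evaluation <- function(x, digits = 3L, ...) {
  cat(sprintf("<gs_evaluation> protocol: %s%s%s\n", x$protocol$kind,
              if (x$protocol$kind == "kfold")
                sprintf(" (k=%d)", x$protocol$k) else "",
              if (x$optimistic)
                "  [global selection: optimistic estimate]" else ""))
  for (stage in names(x$stages)) {
    cat(sprintf("-- %s --\n", stage))
    tab <- do.call(rbind, lapply(names(x$stages[[stage]]), function(cl) {
      m <- x$stages[[stage]][[cl]]$metrics
      data.frame(classifier = cl,
                 accuracy = round(m$accuracy, 2L),
                 sensitivity = round(m$sensitivity, digits),
                 specificity = round(m$specificity, digits),
                 mcc = round(m$mcc, digits),
                 wTPR = round(m$weighted_tpr, digits),
                 wFPR = round(m$weighted_fpr, digits))
    }))
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Export evaluation metrics as a data frame
#'
#' @param x a `gs_evaluation`.
#' @returns Long data frame: stage, classifier, metric, value.
#' @export
evaluation_table <- function(x) {
  rows <- list()
  for (stage in names(x$stages)) for (cl in names(x$stages[[stage]])) {
    m <- x$stages[[stage]][[cl]]$metrics
    for (k in c("accuracy", "sensitivity", "specificity", "mcc",
                "weighted_tpr", "weighted_fpr"))
      rows[[length(rows) + 1L]] <- data.frame(
        stage = stage, classifier = cl, metric = k,
        value = m[[k]], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
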