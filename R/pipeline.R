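#' Pipeline configuration
#'
#' All tunables of the two-stage selection pipeline with their defaults:
#' GA population 20, 20 generations, crossover 0.6, per-bit mutation
#' 0.033; information-gain threshold 0; 10-fold cross-validation.
#'
#' @param dedupe remove duplicate gene identifiers first (keep-first).
#' @param standardize standardize each sample array to zero mean / unit
#'   (population) variance before discretization.
#' @param impute `"none"` (reject missing values) or `"median"`
#'   (per-gene median imputation, logged).
#' @param ig_threshold information-gain survival threshold in bits.
#' @param ga a [ga_config()].
#' @param mrmr_scheme `"MID"` or `"MIQ"`.
#' @param mrmr_size `"auto"` or a positive integer.
#' @param prot default evaluation [protocol()].
#' @param classifiers classifiers to evaluate.
#' @param selection_mode `"per_fold"` (selection re-run inside every
#'   training fold; statistically honest, the default) or `"global"`
#'   (selection once on all samples; optimistic, mirrors reporting a
#'   single subset).
#' @param evaluate_stages which stage outputs to evaluate.
#' @param knn_k neighbourhood size for the knn adapter.
#' @returns A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dedupe = TRUE, standardize = FALSE,
                            impute = c("none", "median"),
                            ig_threshold = 0,
                            ga = ga_config(),
                            mrmr_scheme = c("MID", "MIQ"),
                            mrmr_size = "auto",
                            prot = protocol("kfold", k = 10L),
                            classifiers = c("svm", "nb", "dt", "knn"),
                            selection_mode = c("per_fold", "global"),
                            evaluate_stages = c("stage1", "stage2"),
                            knn_k = 1L) {
  structure(list(dedupe = dedupe, standardize = standardize,
                 impute = match.arg(impute),
                 ig_threshold = ig_threshold, ga = ga,
                 mrmr_scheme = match.arg(mrmr_scheme),
                 mrmr_size = mrmr_size, protocol = prot,
                 classifiers = match.arg(classifiers,
                                         c("svm", "nb", "dt", "knn"),
                                         several.ok = TRUE),
                 selection_mode = match.arg(selection_mode),
                 evaluate_stages = match.arg(evaluate_stages,
                                             c("stage1", "stage2"),
                                             several.ok = TRUE),
                 knn_k = as.integer(knn_k)),
            class = "pipeline_config")
}

preprocess_dataset <- function(ds, config) {
  if (config$dedupe) ds <- remove_duplicate_genes(ds)
  if (config$impute == "median" && anyNA(ds$x)) ds <- impute_missing(ds)
  if (anyNA(ds$x))
    stopf("dataset contains missing values; set impute = 'median'")
  if (config$standardize) ds <- standardize_samples(ds)
  ds
}

# Core two-stage selection on one (training) dataset: discretize ->
# IG filter -> GA -> mRMR.  Assumes preprocessing already applied.
two_stage_select <- function(ds, config) {
  require_binary(ds, "two-stage selection")
  model <- fit_mdl_discretizer(ds)
  dds <- apply_discretizer(model, ds)
  ranking <- filter_by_ig(dds, config$ig_threshold)
  survivors <- ig_survivors(ranking)
  if (length(survivors) == 0L)
    stopf(paste("pipeline halted at stage 1 (information-gain filter):",
                "no gene has positive information gain"))
  stage1 <- ga_select(survivors, dds, config$ga)
  stage2 <- mrmr_select(stage1, dds, target_size = config$mrmr_size,
                        scheme = config$mrmr_scheme)
  list(discretizer = model, dds = dds, ranking = ranking,
       stage1 = stage1, stage2 = stage2)
}

#' Fit the two-stage multifilter gene-selection model
#'
#' The main entry point.  Runs the full selection cascade on all supplied
#' samples — Fayyad-Irani MDL discretization, information-gain filtering
#' at the configured threshold, genetic-algorithm subset search, then
#' greedy mRMR refinement — and trains the configured classifiers on the
#' final (stage-2) gene subset so the fitted object can predict new
#' samples.  Honest generalisation estimates come from [run_protocol()],
#' which repeats the selection inside every training fold.
#'
#' @param x numeric expression matrix (samples x genes) or a
#'   [labeled_dataset()].
#' @param y class labels (ignored when `x` is a `labeled_dataset`).
#' @param config a [pipeline_config()].
#' @param positive name of the class mapped to +1 (see
#'   [labeled_dataset()]).
#' @returns An object of class `genescreen` with components `ranking`
#'   (the `ig_ranking`), `stage1` (`gene_subset`), `stage2`
#'   (`mrmr_result`), `discretizer`, `classifiers` (trained adapters on
#'   the stage-2 genes), `counts` (named integers m >= p >= q >= s),
#'   `manifest`, `config` and `call`.  Supports `print()`, `summary()`,
#'   `coef()` (the selection table), `predict()` and `plot()`.
#' @examples
#' syn <- synth_dataset(synth_config(n_per_class = 10, m_informative = 3,
#'                                   m_redundant = 2, m_noise = 20,
#'                                   effect = 3, seed = 7))
#' fit <- genescreen(syn$dataset)
#' fit
#' coef(fit)
#' @export
genescreen <- function(x, y = NULL, config = pipeline_config(),
                       positive = NULL) {
  cl <- match.call()
  ds <- if (inherits(x, "labeled_dataset")) x
        else labeled_dataset(x, y, positive = positive)
  require_binary(ds, "genescreen")
  if (nrow(ds$x) < 4L) stopf("need at least 4 samples")
  ds <- preprocess_dataset(ds, config)
  sel <- two_stage_select(ds, config)

  dds2 <- subset_dataset(sel$dds, genes = sel$stage2$gene_ids)
  classifiers <- lapply(setNames(config$classifiers, config$classifiers),
                        function(k) train_classifier(k, dds2$x, dds2$labels,
                                                     knn_k = config$knn_k))

  counts <- c(m = ncol(ds$x),
              p = length(ig_survivors(sel$ranking)),
              q = sel$stage1$size,
              s = sel$stage2$size)
  manifest <- list(
    package = "genescreen",
    version = as.character(utils::packageVersion("genescreen")),
    n_samples = nrow(ds$x),
    class_names = as.list(ds$class_names),
    counts = as.list(counts),
    preprocessing = list(dedupe = config$dedupe,
                         standardize = config$standardize,
                         impute = config$impute,
                         duplicates_removed =
                           attr(ds, "removal_log")$removed_count %||% 0L),
    ig_threshold = config$ig_threshold,
    ga = unclass(config$ga),
    mrmr = list(scheme = config$mrmr_scheme,
                target_size = config$mrmr_size),
    classifiers = classifier_defaults(config$knn_k)[config$classifiers],
    selected = list(stage1 = sel$stage1$gene_ids,
                    stage2 = sel$stage2$gene_ids))

  structure(list(ranking = sel$ranking, stage1 = sel$stage1,
                 stage2 = sel$stage2, discretizer = sel$discretizer,
                 classifiers = classifiers, counts = counts,
                 manifest = manifest, config = config,
                 class_names = ds$class_names, call = cl),
            class = "genescreen")
}

#' @export
print.genescreen <- function(x, ...) {
  cat("Two-stage multifilter gene selection\n")
  cat(sprintf("  gene counts: m=%d -> IG survivors p=%d -> GA q=%d -> mRMR s=%d\n",
              x$counts["m"], x$counts["p"], x$counts["q"], x$counts["s"]))
  cat(sprintf("  stage-2 genes: %s%s\n",
              paste(head(x$stage2$gene_ids, 8L), collapse = ", "),
              if (x$stage2$size > 8L) ", ..." else ""))
  invisible(x)
}

#' @export
summary.genescreen <- function(object, ...) {
  structure(list(fit = object), class = "summary.genescreen")
}

#' @export
print.summary.genescreen <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat(sprintf("\nGA best fitness %.4f after %d generations (pop %d)\n",
              fit$stage1$fitness, fit$config$ga$generations,
              fit$config$ga$pop_size))
  cat("\nStage-2 selection path:\n")
  print.data.frame(fit$stage2$trace, digits = 4L, row.names = FALSE)
  invisible(x)
}

#' @export
coef.genescreen <- function(object, stage = c("stage2", "stage1"), ...) {
  stage <- match.arg(stage)
  selection_table(if (stage == "stage2") object$stage2 else object$stage1)
}

#' @rdname genescreen
#' @param object a fitted `genescreen` model.
#' @param newdata numeric matrix (samples x genes) or `labeled_dataset`
#'   containing at least the model's selected genes.
#' @param classifier which trained adapter to use.
#' @param type `"class"` for \{-1, +1\}, `"label"` for class names,
#'   `"score"` for continuous scores.
#' @param ... unused.
#' @export
predict.genescreen <- function(object, newdata,
                               classifier = NULL,
                               type = c("class", "label", "score"), ...) {
  type <- match.arg(type)
  classifier <- classifier %||% names(object$classifiers)[1L]
  if (!classifier %in% names(object$classifiers))
    stopf("no trained '%s' classifier in this fit", classifier)
  x <- if (inherits(newdata, "labeled_dataset")) newdata$x else newdata
  genes <- object$stage2$gene_ids
  missing <- setdiff(genes, colnames(x))
  if (length(missing) > 0L)
    stopf("newdata lacks selected gene(s): %s",
          paste(head(missing, 5L), collapse = ", "))
  nd <- labeled_dataset(x[, genes, drop = FALSE],
                        rep(1L, nrow(x)))  # placeholder labels, never used
  bins <- apply_discretizer(object$discretizer, nd)
  out <- predict_classifier(object$classifiers[[classifier]], bins$x,
                            type = if (type == "score") "score" else "class")
  if (type == "label") {
    ifelse(out == 1L, object$class_names[["+1"]], object$class_names[["-1"]])
  } else out
}

#' @export
plot.genescreen <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  tr <- x$stage1$trace
  graphics::plot(tr$generation, tr$best, type = "s", lwd = 2,
                 xlab = "generation", ylab = "fitness",
                 main = "GA search (stage 1)",
                 ylim = range(c(tr$best, tr$mean)))
  graphics::lines(tr$generation, tr$mean, lty = 2)
  graphics::legend("bottomright", legend = c("best", "mean"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  st <- x$stage2$trace
  graphics::plot(st$step, st$score, type = "b", pch = 19,
                 xlab = "selection step", ylab = "relevance - redundancy",
                 main = "mRMR path (stage 2)")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Write a run manifest
#'
#' Serialises the fitted model's manifest (configuration, seeds, gene
#' counts m >= p >= q >= s, selected genes) as YAML, after asserting the
#' stage containment chain.
#'
#' @param fit a `genescreen` fit.
#' @param path output file.
#' @returns `path`, invisibly.
#' @export
write_manifest <- function(fit, path) {
  counts <- unlist(fit$manifest$counts)
  if (any(diff(counts) > 0))
    stopf("containment violated: counts %s are not non-increasing",
          paste(counts, collapse = " >= "))
  if (!all(fit$stage2$gene_ids %in% fit$stage1$gene_ids) ||
      !all(fit$stage1$gene_ids %in% ig_survivors(fit$ranking)))
    stopf("containment violated: selected genes escape their parent stage")
  yaml::write_yaml(fit$manifest, path)
  invisible(path)
}
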