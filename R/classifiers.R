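# Classifier adapters.  Each adapter trains on a numeric matrix of
# (discretized) expression values with labels in {-1, +1} and predicts
# hard classes plus, where the underlying model offers one, a continuous
# score for the positive class (used for ROC points).
#
# Realisations: svm = e1071 linear kernel, C = 1, no scaling; nb =
# categorical naive Bayes on bin factors with Laplace smoothing; dt =
# rpart with the information (entropy) split criterion and small-sample
# control (minsplit 4, minbucket 2); knn = class::knn, k = 1 by default.
# A training set containing a single class yields a constant-majority
# predictor for every kind (svm/nb cannot be fitted on one class).

#' Train a classifier adapter
#'
#' @param kind one of `"svm"`, `"nb"`, `"dt"`, `"knn"`.
#' @param x numeric training matrix (samples x genes), typically
#'   discretized bins.
#' @param y labels in \{-1, +1\}.
#' @param knn_k neighbourhood size for `"knn"`.
#' @returns An object of class `gs_classifier` for
#'   [predict_classifier()].
#' @export
train_classifier <- function(kind = c("svm", "nb", "dt", "knn"),
                             x, y, knn_k = 1L) {
  kind <- match.arg(kind)
  if (nrow(x) == 0L) stopf("empty training set")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    return(structure(list(kind = "constant", constant = y[1L]),
                     class = "gs_classifier"))
  }
  yf <- factor(y, levels = c(-1L, 1L))
  colnames(x) <- paste0("V", seq_len(ncol(x)))  # syntactic names for formulas
  fit <- switch(kind,
    svm = e1071::svm(x, yf, kernel = "linear", cost = 1, scale = FALSE),
    nb = {
      levs <- lapply(seq_len(ncol(x)), function(j) sort(unique(x[, j])))
      df <- as.data.frame(lapply(seq_len(ncol(x)), function(j)
        factor(x[, j], levels = levs[[j]])))
      names(df) <- colnames(x)
      list(model = e1071::naiveBayes(df, yf, laplace = 1), levels = levs)
    },
    dt = {
      df <- as.data.frame(x)
      df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(minsplit = 4L,
                                                  minbucket = 2L,
                                                  cp = 0.01, xval = 0L))
    },
    knn = list(train = x, cl = yf, k = as.integer(knn_k)))
  structure(list(kind = kind, fit = fit), class = "gs_classifier")
}

#' Predict with a classifier adapter
#'
#' @param object a `gs_classifier` from [train_classifier()].
#' @param newx numeric matrix of test samples (same gene columns as
#'   training).
#' @param type `"class"` for hard labels in \{-1, +1\}, `"score"` for a
#'   continuous score increasing with the positive class (`NULL` when the
#'   model offers none).
#' @param ... unused.
#' @returns Integer labels or numeric scores.
#' @export
predict_classifier <- function(object, newx, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (object$kind == "constant") {
    if (type == "class") return(rep(object$constant, nrow(newx)))
    return(rep(as.numeric(object$constant), nrow(newx)))
  }
  colnames(newx) <- paste0("V", seq_len(ncol(newx)))
  switch(object$kind,
    svm = {
      p <- predict(object$fit, newx, decision.values = TRUE)
      if (type == "class") return(unname(as.integer(as.character(p))))
      dv <- unname(drop(attr(p, "decision.values")))
      # orient the decision value towards class +1
      if (identical(colnames(attr(p, "decision.values"))[1L], "-1/1")) -dv else dv
    },
    nb = {
      df <- as.data.frame(lapply(seq_len(ncol(newx)), function(j)
        factor(newx[, j], levels = object$fit$levels[[j]])))
      names(df) <- colnames(newx)
      pr <- predict(object$fit$model, df, type = "raw")
      if (type == "score") return(unname(pr[, "1"]))
      unname(ifelse(pr[, "1"] >= pr[, "-1"], 1L, -1L))
    },
    dt = {
      pr <- predict(object$fit, as.data.frame(newx))
      if (type == "score") return(unname(pr[, "1"]))
      unname(ifelse(pr[, "1"] >= pr[, "-1"], 1L, -1L))
    },
    knn = {
      k <- min(object$fit$k, nrow(object$fit$train))
      # fixed seed: class::knn breaks distance/vote ties via the RNG, and
      # predictions must be a pure function of (model, newx)
      p <- with_seed(1712L,
                     class::knn(object$fit$train, newx, object$fit$cl,
                                k = k, prob = TRUE))
      if (type == "class") return(as.integer(as.character(p)))
      win <- attr(p, "prob")
      unname(ifelse(p == "1", win, 1 - win))
    })
}

#' Default adapter settings
#'
#' The fixed hyperparameters each adapter uses (no tuning), as a named
#' list suitable for embedding in a run manifest.
#'
#' @param knn_k neighbourhood size reported for knn.
#' @returns Named list of adapter settings.
#' @export
classifier_defaults <- function(knn_k = 1L) {
  list(svm = list(kernel = "linear", cost = 1),
       nb = list(model = "categorical", laplace = 1),
       dt = list(split = "information"),
       knn = list(k = as.integer(knn_k)))
}
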