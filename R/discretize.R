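#' Fayyad-Irani MDL entropy discretization
#'
#' Fits per-gene cut points by recursive entropy minimisation with the
#' minimum-description-length (MDL) stopping rule.  For one gene, the
#' candidate cuts are the midpoints between consecutive distinct sorted
#' values that lie on a class boundary; the cut minimising the weighted
#' class entropy of the two induced partitions (equivalently, maximising
#' information gain) is accepted iff
#'
#' \deqn{Gain(T) > \frac{\log_2(N-1)}{N} + \frac{\Delta(T)}{N}}
#'
#' with \eqn{\Delta(T) = \log_2(3^k - 2) - [k H(S) - k_1 H(S_1) - k_2
#' H(S_2)]}, where \eqn{k}, \eqn{k_1}, \eqn{k_2} count the classes present
#' in the partition and its two halves and entropies are in bits.  The
#' recursion continues independently on each side until a cut is rejected.
#' Ties between equal-gain cuts go to the leftmost (smallest value).
#'
#' Cut points are fitted from the training samples only; applying the
#' fitted model never consults labels, so the model can safely be applied
#' to held-out test samples (see [apply_discretizer()]).
#'
#' @param train a [labeled_dataset()] of training samples (labels are
#'   consulted here and only here).
#' @returns An object of class `mdl_discretizer`: a list with `cuts` (a
#'   named list of strictly increasing numeric cut vectors, one per gene;
#'   possibly empty vectors) and `fit_sample_ids`.
#' @references Fayyad & Irani's recursive minimal-entropy partitioning
#'   with MDL stopping, the standard supervised discretizer for
#'   microarray pipelines.
#' @export
fit_mdl_discretizer <- function(train) {
  if (nrow(train$x) < 1L) stopf("cannot fit a discretizer on 0 samples")
  labs <- train$labels
  cuts <- lapply(seq_len(ncol(train$x)),
                 function(j) mdl_cut_points(train$x[, j], labs))
  names(cuts) <- gene_ids(train)
  structure(list(cuts = cuts, fit_sample_ids = sample_ids(train)),
            class = "mdl_discretizer")
}

#' @export
print.mdl_discretizer <- function(x, ...) {
  nc <- lengths(x$cuts)
  cat(sprintf("<mdl_discretizer> %d genes fitted on %d samples\n",
              length(x$cuts), length(x$fit_sample_ids)))
  cat(sprintf("  genes with >=1 cut: %d; max cuts: %d\n",
              sum(nc > 0L), if (length(nc)) max(nc) else 0L))
  invisible(x)
}

# MDL cut points for a single gene.  values: numeric; labels: class codes.
mdl_cut_points <- function(values, labels) {
  ord <- order(values)
  codes <- match(labels, unique(labels))
  recurse_mdl(values[ord], codes[ord], max(codes))
}

# values sorted ascending; codes in 1..n_classes.
recurse_mdl <- function(values, codes, n_classes) {
  n <- length(values)
  if (n < 2L) return(numeric(0))

  # counts per distinct value x class
  vals <- unique(values)
  g <- length(vals)
  if (g < 2L) return(numeric(0))
  grp <- findInterval(values, vals)              # sorted -> group index
  counts <- matrix(0L, g, n_classes)
  for (i in seq_len(n)) counts[grp[i], codes[i]] <- counts[grp[i], codes[i]] + 1L

  # boundary candidates: adjacent distinct values not pure in the same class
  pure_class <- ifelse(rowSums(counts > 0L) == 1L, max.col(counts), NA_integer_)
  boundary <- which(!(pure_class[-g] == pure_class[-1L] &
                        !is.na(pure_class[-g]) & !is.na(pure_class[-1L])))
  if (length(boundary) == 0L) return(numeric(0))

  cum <- apply(counts, 2L, cumsum)
  if (g == 1L) cum <- matrix(cum, nrow = 1L)
  total <- cum[g, ]
  h_s <- entropy_from_counts(total)

  n_left <- rowSums(cum)[boundary]
  gains <- vapply(seq_along(boundary), function(b) {
    left <- cum[boundary[b], ]
    right <- total - left
    h_s - (sum(left) / n) * entropy_from_counts(left) -
      (sum(right) / n) * entropy_from_counts(right)
  }, 0)

  best <- which(gains > max(gains) - 1e-12)[1L]   # leftmost among ties
  bi <- boundary[best]
  left <- cum[bi, ]
  right <- total - left
  k <- sum(total > 0L)
  k1 <- sum(left > 0L)
  k2 <- sum(right > 0L)
  delta <- log2(3^k - 2) -
    (k * h_s - k1 * entropy_from_counts(left) - k2 * entropy_from_counts(right))
  threshold <- (log2(n - 1) + delta) / n
  if (gains[best] <= threshold) return(numeric(0))

  cut <- (vals[bi] + vals[bi + 1L]) / 2
  split_at <- n_left[best]
  c(recurse_mdl(values[seq_len(split_at)], codes[seq_len(split_at)], n_classes),
    cut,
    recurse_mdl(values[(split_at + 1L):n], codes[(split_at + 1L):n], n_classes))
}

#' Apply a fitted discretizer to a dataset
#'
#' Maps every expression value to an integer bin index among its gene's
#' fitted cut points.  Bins are numbered from 0; the convention is
#' left-closed/right-open, i.e. `bin(x) = #\{cuts <= x\}`, so a value equal
#' to a cut falls in the upper bin.  Values beyond the fitted range fall
#' into the first/last bin.  A gene with no cuts maps everything to bin 0.
#' Application is a pure function of the model and the expression values;
#' labels are never consulted.
#'
#' @param model an `mdl_discretizer` from [fit_mdl_discretizer()].
#' @param ds a [labeled_dataset()] whose genes are all present in the
#'   model (extra model genes are ignored).
#' @returns A `labeled_dataset` whose matrix holds integer bin indices;
#'   it additionally carries class `discretized_dataset`.
#' @export
apply_discretizer <- function(model, ds) {
  ids <- gene_ids(ds)
  missing <- setdiff(ids, names(model$cuts))
  if (length(missing) > 0L)
    stopf("gene(s) absent from discretization model: %s",
          paste(head(missing, 5L), collapse = ", "))
  x <- ds$x
  for (j in seq_along(ids)) {
    cuts <- model$cuts[[ids[j]]]
    x[, j] <- if (length(cuts) == 0L) 0 else findInterval(x[, j], cuts)
  }
  storage.mode(x) <- "integer"
  out <- ds
  out$x <- x
  class(out) <- c("discretized_dataset", "labeled_dataset")
  out
}

#' @rdname apply_discretizer
#' @param object an `mdl_discretizer`.
#' @param newdata a [labeled_dataset()].
#' @param ... unused.
#' @export
predict.mdl_discretizer <- function(object, newdata, ...) {
  apply_discretizer(object, newdata)
}

#' Serialize / deserialize a discretization model as TSV
#'
#' One line per gene: `gene_id<TAB>cut1<TAB>cut2...` (no cuts: just the
#' identifier).  Intended for audit trails.
#'
#' @param model an `mdl_discretizer`.
#' @param path output (input) file.
#' @returns `path` invisibly; `read_discretizer()` returns the model.
#' @export
write_discretizer <- function(model, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (g in names(model$cuts))
    writeLines(paste(c(g, format(model$cuts[[g]], digits = 17, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_discretizer
#' @export
read_discretizer <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  cuts <- lapply(parts, function(p) as.numeric(p[-1L]))
  names(cuts) <- vapply(parts, `[`, "", 1L)
  structure(list(cuts = cuts, fit_sample_ids = character(0)),
            class = "mdl_discretizer")
}
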