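#' Remove duplicated gene identifiers
#'
#' Microarray exports often list the same accession more than once; only
#' the first occurrence (file order) is kept.  Removal is by identifier,
#' not by expression values.
#'
#' @param ds a [labeled_dataset()].
#' @returns The deduplicated dataset, with attribute `removal_log`: a list
#'   with `removed_count` and the removed `gene_ids`.
#' @examples
#' x <- matrix(rnorm(12), 2, 6,
#'             dimnames = list(NULL, c("g1", "g2", "g1", "g3", "g2", "g1")))
#' ds <- remove_duplicate_genes(labeled_dataset(x, c(-1, 1)))
#' attr(ds, "removal_log")$removed_count  # 3
#' @export
remove_duplicate_genes <- function(ds) {
  ids <- gene_ids(ds)
  dup <- duplicated(ids)
  out <- subset_dataset(ds, genes = which(!dup))
  attr(out, "removal_log") <- list(removed_count = sum(dup),
                                   gene_ids = ids[dup])
  out
}

#' Standardize each sample array to zero mean and unit variance
#'
#' Each sample (array) is centred and scaled across its genes using the
#' population standard deviation (divisor `n`, not `n - 1`).  A sample
#' whose values are all equal cannot be scaled and raises an error naming
#' the sample.
#'
#' @param ds a [labeled_dataset()].
#' @returns The standardized dataset.
#' @export
standardize_samples <- function(ds) {
  x <- ds$x
  m <- ncol(x)
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    mu <- mean(v)
    s <- sqrt(sum((v - mu)^2) / m)
    if (s == 0)
      stopf("sample '%s' is constant and cannot be standardized",
            sample_ids(ds)[i])
    x[i, ] <- (v - mu) / s
  }
  out <- ds
  out$x <- x
  out
}

#' Impute missing expression values by per-gene median
#'
#' Optional companion to `read_expression_table(allow_missing = TRUE)`.
#' Each `NA` cell is replaced by the median of its gene's observed values;
#' the count of imputed cells is attached as attribute `impute_log`.
#'
#' @param ds a [labeled_dataset()] possibly containing `NA` cells.
#' @returns The completed dataset.
#' @export
impute_missing <- function(ds) {
  x <- ds$x
  n_imputed <- 0L
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      if (all(miss))
        stopf("gene '%s' has no observed values to impute from",
              gene_ids(ds)[j])
      x[miss, j] <- stats::median(x[!miss, j])
      n_imputed <- n_imputed + sum(miss)
    }
  }
  out <- ds
  out$x <- x
  attr(out, "impute_log") <- list(imputed_cells = n_imputed)
  out
}
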