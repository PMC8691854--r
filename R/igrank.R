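#' Class entropy in bits
#'
#' \eqn{H = -\sum_c p_c \log_2 p_c} over the empirical class proportions.
#'
#' @param labels non-empty discrete vector.
#' @returns Entropy in bits, in `[0, log2(#classes)]`.
#' @examples
#' class_entropy(c(1, 1, -1, -1))       # 1 bit
#' class_entropy(c(1, 1, 1, -1, -1, -1, -1, -1))  # 0.9544
#' @export
class_entropy <- function(labels) {
  if (length(labels) == 0L) stopf("cannot compute entropy of an empty vector")
  entropy_bits(labels)
}

#' Information gain of a discretized gene about the class
#'
#' \eqn{IG = H(labels) - \sum_v \frac{n_v}{n} H(labels \mid bin = v)}; on
#' discrete data this equals the mutual information between gene bins and
#' class labels.  The result is clamped at 0 to absorb floating-point
#' round-off.
#'
#' @param gene_bins discrete vector of bin indices.
#' @param labels discrete class vector of the same length.
#' @returns Gain in bits, in `[0, min(H(labels), H(gene_bins))]`.
#' @export
information_gain <- function(gene_bins, labels) {
  if (length(gene_bins) != length(labels))
    stopf("length mismatch: %d bins vs %d labels",
          length(gene_bins), length(labels))
  if (length(labels) == 0L) stopf("empty input")
  n <- length(labels)
  h <- class_entropy(labels)
  cond <- 0
  for (v in unique(gene_bins)) {
    sel <- gene_bins == v
    cond <- cond + sum(sel) / n * entropy_bits(labels[sel])
  }
  max(0, h - cond)
}

#' Rank genes by information gain and filter at a threshold
#'
#' Computes the information gain of every gene in a discretized dataset
#' and retains those strictly above `threshold` (default 0: any gene whose
#' discretization carries no class information is dropped, which includes
#' every gene the MDL discretizer left with a single bin).  On floating
#' point, "above zero" is implemented as `> max(threshold, 1e-12)` so a
#' constant gene can never survive through round-off.
#'
#' @param dds a discretized dataset from [apply_discretizer()].
#' @param threshold survival threshold in bits.
#' @returns An object of class `ig_ranking`: a data frame with columns
#'   `rank`, `gene_id`, `ig` sorted by decreasing gain (ties keep input
#'   gene order), with attributes `threshold` and `survivors` (character
#'   vector of surviving gene ids, in rank order).
#' @export
filter_by_ig <- function(dds, threshold = 0) {
  ig <- vapply(seq_len(ncol(dds$x)),
               function(j) information_gain(dds$x[, j], dds$labels), 0)
  ord <- order(-ig, seq_along(ig))
  out <- data.frame(rank = seq_along(ord),
                    gene_id = gene_ids(dds)[ord],
                    ig = ig[ord],
                    stringsAsFactors = FALSE)
  eff <- max(threshold, 1e-12)
  attr(out, "threshold") <- threshold
  attr(out, "survivors") <- out$gene_id[out$ig > eff]
  class(out) <- c("ig_ranking", "data.frame")
  out
}

#' @export
print.ig_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<ig_ranking> %d genes, %d above threshold %g bits\n",
              nrow(x), length(attr(x, "survivors")), attr(x, "threshold")))
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

#' @rdname filter_by_ig
#' @param ranking an `ig_ranking`.
#' @export
ig_survivors <- function(ranking) attr(ranking, "survivors")
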