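#' Mutual information between two discrete vectors
#'
#' \eqn{I(x; y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x) p(y)}} in
#' bits, estimated from the joint contingency table (clamped at 0 against
#' round-off).  Symmetric, and `mutual_information(x, x)` equals the
#' entropy of `x`.
#'
#' @param x,y discrete vectors of equal, positive length.
#' @returns Mutual information in bits (>= 0).
#' @examples
#' mutual_information(c(1, 1, 0, 0), c(1, 1, 0, 0))  # 1 bit
#' mutual_information(c(1, 0, 1, 0), c(1, 1, 0, 0))  # 0
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stopf("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) == 0L) stopf("empty input")
  max(0, entropy_bits(x) + entropy_bits(y) - entropy_bits(paste(x, y)))
}

#' Stage-2 minimum-redundancy-maximum-relevance selection
#'
#' Greedy mRMR over the stage-1 gene subset using discrete mutual
#' information, in the MID (difference) scheme: the first pick maximises
#' relevance \eqn{I(g; class)}; each later step picks
#' \eqn{\arg\max_g [I(g; class) - \frac{1}{|S|} \sum_{s \in S} I(g; s)]}
#' (MIQ replaces the difference with the quotient
#' \eqn{I(g; class) / \bar I}).  Ties at any step go to the smallest
#' original gene index.  In `target_size = "auto"` mode selection stops
#' before the first step whose best score is not strictly positive
#' (minimum one gene); an integer `target_size` larger than the candidate
#' set is clamped with a warning.
#'
#' @param stage1 a `gene_subset` from [ga_select()], or a character vector
#'   of gene identifiers.
#' @param dds discretized dataset containing those genes.
#' @param target_size `"auto"` or a positive integer.
#' @param scheme `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @returns An object of class `mrmr_result`: `gene_ids` in greedy
#'   selection order, `stage = "stage2"`, `size`, `scheme`, and `trace`
#'   (data frame: step, gene_id, relevance, redundancy, score).
#' @export
mrmr_select <- function(stage1, dds, target_size = "auto",
                        scheme = c("MID", "MIQ")) {
  scheme <- match.arg(scheme)
  genes <- if (inherits(stage1, "gene_subset")) stage1$gene_ids else stage1
  q <- length(genes)
  if (q == 0L) stopf("stage-1 subset is empty")
  stopifnot(all(genes %in% gene_ids(dds)))
  auto <- identical(target_size, "auto")
  if (!auto) {
    target_size <- as.integer(target_size)
    if (target_size < 1L) stopf("target_size must be >= 1")
    if (target_size > q) {
      warnf("target_size %d exceeds stage-1 subset size %d; clamped",
            target_size, q)
      target_size <- q
    }
  }

  x <- dds$x[, genes, drop = FALSE]
  relevance <- vapply(seq_len(q),
                      function(j) mutual_information(x[, j], dds$labels), 0)
  mi_ff <- matrix(NA_real_, q, q)  # filled lazily
  get_mi <- function(a, b) {
    if (is.na(mi_ff[a, b])) {
      v <- mutual_information(x[, a], x[, b])
      mi_ff[a, b] <<- v
      mi_ff[b, a] <<- v
    }
    mi_ff[a, b]
  }

  selected <- integer(0)
  trace <- data.frame(step = integer(0), gene_id = character(0),
                      relevance = numeric(0), redundancy = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  limit <- if (auto) q else target_size
  repeat {
    remaining <- setdiff(seq_len(q), selected)
    if (length(remaining) == 0L || length(selected) >= limit) break
    if (length(selected) == 0L) {
      red <- rep(0, length(remaining))
      score <- relevance[remaining]
    } else {
      red <- vapply(remaining, function(g)
        mean(vapply(selected, function(s) get_mi(g, s), 0)), 0)
      score <- if (scheme == "MID") relevance[remaining] - red
               else relevance[remaining] / pmax(red, .Machine$double.eps)
    }
    best <- remaining[which(score > max(score) - 1e-12)[1L]]  # smallest index
    best_pos <- match(best, remaining)
    if (auto && length(selected) >= 1L && score[best_pos] <= 1e-12) break
    selected <- c(selected, best)
    trace <- rbind(trace, data.frame(step = length(selected),
                                     gene_id = genes[best],
                                     relevance = relevance[best],
                                     redundancy = red[best_pos],
                                     score = score[best_pos],
                                     stringsAsFactors = FALSE))
  }
  structure(list(gene_ids = genes[selected], stage = "stage2",
                 size = length(selected), scheme = scheme, trace = trace),
            class = "mrmr_result")
}

#' @export
print.mrmr_result <- function(x, ...) {
  cat(sprintf("<mrmr_result> %d genes (%s scheme)\n", x$size, x$scheme))
  print.data.frame(head(x$trace, 10L))
  if (x$size > 10L) cat("  ...\n")
  invisible(x)
}
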