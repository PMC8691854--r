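#' Genetic-algorithm configuration
#'
#' Defaults are the stage-1 search settings used throughout the package:
#' population 20, 20 generations, crossover probability 0.6, per-bit
#' mutation probability 0.033.
#'
#' @param pop_size population size (>= 2).
#' @param generations number of generations (>= 1); no early stopping.
#' @param p_crossover probability a selected pair undergoes single-point
#'   crossover.
#' @param p_mutation per-bit flip probability.
#' @param seed RNG seed for the whole run.
#' @param fitness `"cfs"` (correlation-based subset merit, the default,
#'   filter-style and fast) or `"wrapper"` (inner-CV classifier accuracy).
#' @param init_bit_prob probability a chromosome bit starts set.
#' @param wrapper_classifier,inner_folds,inner_seed wrapper-fitness
#'   settings (ignored for `fitness = "cfs"`).
#' @returns A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 20L, generations = 20L,
                      p_crossover = 0.6, p_mutation = 0.033,
                      seed = 1L, fitness = c("cfs", "wrapper"),
                      init_bit_prob = 0.5,
                      wrapper_classifier = "knn",
                      inner_folds = 5L, inner_seed = 1L) {
  fitness <- match.arg(fitness)
  if (pop_size < 2L) stopf("pop_size must be >= 2")
  if (generations < 1L) stopf("generations must be >= 1")
  for (p in c(p_crossover, p_mutation, init_bit_prob))
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 seed = as.integer(seed), fitness = fitness,
                 init_bit_prob = init_bit_prob,
                 wrapper_classifier = wrapper_classifier,
                 inner_folds = as.integer(inner_folds),
                 inner_seed = as.integer(inner_seed)),
            class = "ga_config")
}

#' Symmetrical uncertainty between two discrete vectors
#'
#' \eqn{SU(x, y) = 2 I(x; y) / (H(x) + H(y))}, a correlation-like
#' normalisation of mutual information in `[0, 1]`.  Defined as 0 when
#' both vectors are constant.
#'
#' @param x,y discrete vectors of equal length.
#' @returns SU in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y) {
  denom <- entropy_bits(x) + entropy_bits(y)
  if (denom == 0) return(0)
  min(1, 2 * mutual_information(x, y) / denom)
}

# SU caches used by the CFS fitness: feature-class vector and
# feature-feature matrix over a candidate gene set.
su_cache <- function(dds, candidates) {
  x <- dds$x[, candidates, drop = FALSE]
  L <- ncol(x)
  su_fc <- vapply(seq_len(L),
                  function(j) symmetrical_uncertainty(x[, j], dds$labels), 0)
  su_ff <- diag(1, L)
  if (L > 1L) {
    for (a in seq_len(L - 1L)) for (b in (a + 1L):L) {
      s <- symmetrical_uncertainty(x[, a], x[, b])
      su_ff[a, b] <- s
      su_ff[b, a] <- s
    }
  }
  list(fc = su_fc, ff = su_ff)
}

merit_from_cache <- function(mask, cache) {
  k <- sum(mask)
  rcf <- mean(cache$fc[mask])
  rff <- if (k > 1L) {
    sub <- cache$ff[mask, mask, drop = FALSE]
    (sum(sub) - k) / (k * (k - 1L))
  } else 0
  k * rcf / sqrt(k + k * (k - 1L) * rff)
}

#' Correlation-based subset merit (CFS)
#'
#' \deqn{merit = \frac{k \bar r_{cf}}{\sqrt{k + k (k - 1) \bar r_{ff}}}}
#' where \eqn{\bar r_{cf}} is the mean feature-class symmetrical
#' uncertainty over the `k` subset genes and \eqn{\bar r_{ff}} the mean
#' pairwise feature-feature symmetrical uncertainty.  High merit rewards
#' class-informative genes and penalises mutual redundancy; for a single
#' gene the merit is its SU with the class.
#'
#' @param genes gene identifiers (or column indices) of a non-empty subset.
#' @param dds a discretized dataset.
#' @returns Merit score (>= 0).
#' @export
cfs_merit <- function(genes, dds) {
  if (length(genes) == 0L) stopf("subset is empty")
  cache <- su_cache(dds, genes)
  merit_from_cache(rep(TRUE, length(cache$fc)), cache)
}

#' Wrapper fitness: inner cross-validated accuracy of a gene subset
#'
#' Evaluates a subset by stratified inner cross-validation of a classifier
#' restricted to those genes.  Deterministic given `inner_seed`.
#'
#' @param genes non-empty gene identifiers (or indices).
#' @param dds a discretized dataset with binary labels.
#' @param classifier one of `"svm"`, `"nb"`, `"dt"`, `"knn"`.
#' @param inner_folds number of inner folds.
#' @param inner_seed RNG seed for the fold assignment.
#' @returns Pooled inner-CV accuracy fraction in `[0, 1]`.
#' @export
wrapper_accuracy_fitness <- function(genes, dds, classifier = "knn",
                                     inner_folds = 5L, inner_seed = 1L) {
  if (length(genes) == 0L) stopf("subset is empty")
  require_binary(dds, "wrapper fitness")
  sub <- subset_dataset(dds, genes = genes)
  folds <- make_folds(sub$labels, k = inner_folds, seed = inner_seed,
                      stratified = TRUE)
  correct <- 0L
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- train_classifier(classifier,
                            sub$x[!test, , drop = FALSE], sub$labels[!test])
    pred <- predict_classifier(fit, sub$x[test, , drop = FALSE])
    correct <- correct + sum(pred == sub$labels[test])
  }
  correct / length(sub$labels)
}

#' Stage-1 genetic-algorithm gene-subset search
#'
#' Searches the space of subsets of `candidates` (normally the
#' information-gain survivors) with a generational genetic algorithm:
#' fitness-proportional (roulette) selection with a rank fallback when any
#' fitness is non-positive, single-point crossover, independent per-bit
#' mutation, and elitism of one (the best-ever chromosome always
#' survives).  Chromosomes that mutate to all-zero are repaired by setting
#' one uniformly random bit.  The best-ever chromosome over the whole run
#' is returned.
#'
#' @param candidates character vector of candidate gene identifiers
#'   (chromosome bit order follows this vector).
#' @param dds discretized dataset containing at least those genes.
#' @param config a [ga_config()].
#' @returns An object of class `gene_subset` with elements `gene_ids`
#'   (selected genes, in candidate order), `stage = "stage1"`, `size`,
#'   `fitness` (best merit/accuracy), `relevance` (per-gene information
#'   gain, for reporting), `trace` (data frame: generation, best, mean),
#'   `repairs`, and `config`.
#' @export
ga_select <- function(candidates, dds, config = ga_config()) {
  L <- length(candidates)
  if (L == 0L) stopf("no candidate genes to search over")
  stopifnot(all(candidates %in% gene_ids(dds)))

  if (config$fitness == "cfs") {
    cache <- su_cache(dds, candidates)
    fitfun <- function(mask) merit_from_cache(mask, cache)
  } else {
    fitfun <- function(mask)
      wrapper_accuracy_fitness(candidates[mask], dds,
                               classifier = config$wrapper_classifier,
                               inner_folds = config$inner_folds,
                               inner_seed = config$inner_seed)
  }

  repairs <- 0L
  repair <- function(mask) {
    if (!any(mask)) {
      mask[sample.int(length(mask), 1L)] <- TRUE
      repairs <<- repairs + 1L
    }
    mask
  }

  res <- with_seed(config$seed, {
    np <- config$pop_size
    pop <- matrix(runif(np * L) < config$init_bit_prob, np, L)
    for (i in seq_len(np)) pop[i, ] <- repair(pop[i, ])
    fit <- apply(pop, 1L, fitfun)
    best_i <- which.max(fit)
    best_mask <- pop[best_i, ]
    best_fit <- fit[best_i]
    trace <- data.frame(generation = 0:config$generations,
                        best = NA_real_, mean = NA_real_)
    trace$best[1L] <- max(fit)
    trace$mean[1L] <- mean(fit)

    for (gen in seq_len(config$generations)) {
      weights <- if (any(fit <= 0)) rank(fit) else fit
      children <- matrix(FALSE, np, L)
      i <- 1L
      while (i <= np) {
        pair <- sample.int(np, 2L, replace = TRUE, prob = weights)
        c1 <- pop[pair[1L], ]
        c2 <- pop[pair[2L], ]
        if (L >= 2L && runif(1L) < config$p_crossover) {
          pt <- sample.int(L - 1L, 1L)
          tmp <- c1
          c1 <- c(c1[seq_len(pt)], c2[(pt + 1L):L])
          c2 <- c(c2[seq_len(pt)], tmp[(pt + 1L):L])
        }
        c1 <- repair(xor(c1, runif(L) < config$p_mutation))
        children[i, ] <- c1
        if (i + 1L <= np) {
          c2 <- repair(xor(c2, runif(L) < config$p_mutation))
          children[i + 1L, ] <- c2
        }
        i <- i + 2L
      }
      pop <- children
      fit <- apply(pop, 1L, fitfun)
      # elitism: re-insert the best-ever over the current worst
      worst <- which.min(fit)
      if (best_fit > fit[worst]) {
        pop[worst, ] <- best_mask
        fit[worst] <- best_fit
      }
      if (max(fit) > best_fit) {
        best_i <- which.max(fit)
        best_mask <- pop[best_i, ]
        best_fit <- fit[best_i]
      }
      trace$best[gen + 1L] <- max(fit)
      trace$mean[gen + 1L] <- mean(fit)
    }
    list(mask = best_mask, fitness = best_fit, trace = trace)
  })

  sel <- candidates[res$mask]
  rel <- vapply(sel, function(g)
    information_gain(dds$x[, g], dds$labels), 0)
  structure(list(gene_ids = sel, stage = "stage1", size = length(sel),
                 fitness = res$fitness, relevance = unname(rel),
                 trace = res$trace, repairs = repairs, config = config),
            class = "gene_subset")
}

#' @export
print.gene_subset <- function(x, ...) {
  cat(sprintf("<gene_subset> %s: %d genes, fitness %.4f\n",
              x$stage, x$size, x$fitness %||% NA_real_))
  cat("  ", paste(head(x$gene_ids, 10L), collapse = ", "),
      if (x$size > 10L) "..." else "", "\n")
  invisible(x)
}
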