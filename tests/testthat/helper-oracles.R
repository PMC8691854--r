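# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with R/: entropies come from table(),
# recursion and greedy loops are written naively.

oracle_entropy <- function(v) {
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log2(p))
}

oracle_mi <- function(x, y) {
  joint <- table(x, y)
  n <- sum(joint)
  total <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    pij <- joint[i, j] / n
    if (pij > 0) {
      pi_ <- sum(joint[i, ]) / n
      p_j <- sum(joint[, j]) / n
      total <- total + pij * log2(pij / (pi_ * p_j))
    }
  }
  total
}

oracle_ig <- function(bins, labels) {
  h <- oracle_entropy(labels)
  for (v in unique(bins)) {
    sub <- labels[bins == v]
    h <- h - length(sub) / length(labels) * oracle_entropy(sub)
  }
  h
}

# Brute-force Fayyad-Irani discretization: evaluates EVERY midpoint
# between consecutive distinct sorted values, verifies the best gain is
# attained at a class-boundary midpoint, applies the MDL test, recurses.
oracle_mdl <- function(values, labels) {
  n <- length(values)
  ord <- order(values)
  values <- values[ord]
  labels <- labels[ord]
  vals <- unique(values)
  if (n < 2 || length(vals) < 2) return(numeric(0))

  mids <- (vals[-length(vals)] + vals[-1]) / 2
  gains <- sapply(mids, function(cut) {
    left <- labels[values <= cut]
    right <- labels[values > cut]
    oracle_entropy(labels) -
      length(left) / n * oracle_entropy(left) -
      length(right) / n * oracle_entropy(right)
  })
  # boundary midpoints: adjacent value groups not pure in the same class
  grp_class <- lapply(vals, function(v) unique(labels[values == v]))
  is_boundary <- sapply(seq_along(mids), function(i) {
    a <- grp_class[[i]]
    b <- grp_class[[i + 1]]
    !(length(a) == 1 && length(b) == 1 && a == b)
  })
  if (!any(is_boundary)) return(numeric(0))
  stopifnot(max(gains[is_boundary]) >= max(gains) - 1e-12)
  cand <- which(is_boundary & gains > max(gains[is_boundary]) - 1e-12)
  best <- cand[1]
  cut <- mids[best]

  left_lab <- labels[values <= cut]
  right_lab <- labels[values > cut]
  k <- length(unique(labels))
  delta <- log2(3^k - 2) -
    (k * oracle_entropy(labels) -
       length(unique(left_lab)) * oracle_entropy(left_lab) -
       length(unique(right_lab)) * oracle_entropy(right_lab))
  if (gains[best] <= (log2(n - 1) + delta) / n) return(numeric(0))
  c(oracle_mdl(values[values <= cut], left_lab),
    cut,
    oracle_mdl(values[values > cut], right_lab))
}

# Naive greedy mRMR (MID scheme) over gene columns of a bin matrix.
oracle_mrmr <- function(bins, labels, target) {
  q <- ncol(bins)
  rel <- sapply(seq_len(q), function(j) oracle_mi(bins[, j], labels))
  selected <- integer(0)
  while (length(selected) < target) {
    remaining <- setdiff(seq_len(q), selected)
    score <- sapply(remaining, function(g) {
      if (length(selected) == 0) rel[g]
      else rel[g] - mean(sapply(selected, function(s) oracle_mi(bins[, g], bins[, s])))
    })
    selected <- c(selected, remaining[which(score > max(score) - 1e-12)[1]])
  }
  selected
}

oracle_su <- function(x, y) {
  denom <- oracle_entropy(x) + oracle_entropy(y)
  if (denom == 0) 0 else 2 * oracle_mi(x, y) / denom
}

# CFS merit of every non-empty subset of the gene columns, via an
# independently computed SU cache.
oracle_all_merits <- function(bins, labels) {
  L <- ncol(bins)
  fc <- sapply(seq_len(L), function(j) oracle_su(bins[, j], labels))
  ff <- outer(seq_len(L), seq_len(L), Vectorize(function(a, b)
    if (a == b) 1 else oracle_su(bins[, a], bins[, b])))
  merits <- numeric(2^L - 1)
  masks <- vector("list", 2^L - 1)
  for (code in seq_len(2^L - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(L) - 1)))
    k <- sum(mask)
    rcf <- mean(fc[mask])
    rff <- if (k > 1) mean(ff[mask, mask][upper.tri(diag(k))]) else 0
    merits[code] <- k * rcf / sqrt(k + k * (k - 1) * rff)
    masks[[code]] <- mask
  }
  list(merits = merits, masks = masks, fc = fc, ff = ff)
}

oracle_merit_of <- function(oracle, mask) {
  code <- sum(2^(which(mask) - 1))
  oracle$merits[code]
}
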