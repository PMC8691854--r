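# Small in-code fixtures.

make_ds <- function(x, labels, ...) {
  labeled_dataset(as.matrix(x), labels, ...)
}

# n samples, balanced labels, one perfectly separating gene plus noise.
separable_ds <- function(n = 20, m_noise = 10, seed = 1) {
  stopifnot(n %% 2 == 0)
  labels <- rep(c(-1L, 1L), each = n / 2)
  withr::with_seed(seed, {
    x <- cbind(sep = labels * 5 + rnorm(n, sd = 0.1),
               matrix(rnorm(n * m_noise), n,
                      dimnames = list(NULL, paste0("noise", seq_len(m_noise)))))
  })
  labeled_dataset(x, labels)
}

# discretized dataset straight from integer bins
bins_ds <- function(bins, labels) {
  ds <- labeled_dataset(as.matrix(bins), labels)
  storage.mode(ds$x) <- "integer"
  class(ds) <- c("discretized_dataset", "labeled_dataset")
  ds
}
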