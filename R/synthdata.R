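#' Synthetic microarray design
#'
#' Describes a two-class expression dataset with three gene roles:
#' *informative* genes whose class-conditional means differ by `effect`
#' standard deviations, *redundant* genes correlated (`rho`) with an
#' informative parent, and *noise* genes independent of the class.  The
#' defaults emulate the few-samples/many-genes structure of tumour-versus-
#' normal microarray studies.
#'
#' @param n_per_class samples per class.
#' @param m_informative,m_redundant,m_noise gene counts per role
#'   (`m_informative >= 1` whenever `m_redundant >= 1`).
#' @param effect between-class mean shift of informative genes, in units
#'   of `noise_sd`.
#' @param rho correlation of each redundant gene with its parent, in
#'   `[0, 1]`.
#' @param noise_sd within-class standard deviation.
#' @param distribution `"gaussian"` class-conditional model (default) or
#'   `"lognormal"` (exponentiated values, mimicking raw intensities).
#' @param duplicate_ids number of genes whose identifier is deliberately
#'   duplicated (to exercise duplicate removal).
#' @param seed RNG seed.
#' @returns A list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 20L, m_informative = 10L,
                         m_redundant = 20L, m_noise = 500L,
                         effect = 1.5, rho = 0.9, noise_sd = 1,
                         distribution = c("gaussian", "lognormal"),
                         duplicate_ids = 0L, seed = 1L) {
  if (any(c(n_per_class, m_informative, m_redundant, m_noise) < 0L))
    stopf("counts must be non-negative")
  if (n_per_class < 1L) stopf("need at least 1 sample per class")
  if (m_redundant >= 1L && m_informative < 1L)
    stopf("redundant genes need at least one informative parent")
  if (rho < 0 || rho > 1) stopf("rho must lie in [0, 1]")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  structure(list(n_per_class = as.integer(n_per_class),
                 m_informative = as.integer(m_informative),
                 m_redundant = as.integer(m_redundant),
                 m_noise = as.integer(m_noise),
                 effect = effect, rho = rho, noise_sd = noise_sd,
                 distribution = match.arg(distribution),
                 duplicate_ids = as.integer(duplicate_ids),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic two-class expression dataset
#'
#' Deterministic given `cfg$seed`.  Informative gene values are drawn from
#' class-conditional normals with means `± effect/2` (in `noise_sd`
#' units); redundant gene `j` equals `rho * parent + sqrt(1 - rho^2) *
#' eps` with its parent assigned round-robin among the informative genes;
#' noise genes are class-independent draws.  Gene identifiers follow the
#' pattern `SYN000001, ...`; `cfg$duplicate_ids` genes reuse the previous
#' gene's identifier so the duplicate-removal path can be exercised.
#'
#' @param cfg a [synth_config()].
#' @returns A list with `dataset` (a [labeled_dataset()], class names
#'   `normal`/`tumour` mapped to -1/+1) and `roles` (character vector per
#'   gene: `informative`, `redundant` or `noise`, named by gene id
#'   position).
#' @export
synth_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- 2L * cfg$n_per_class
  m <- cfg$m_informative + cfg$m_redundant + cfg$m_noise
  if (m < 1L) stopf("design has no genes")
  labels <- rep(c(-1L, 1L), each = cfg$n_per_class)
  with_seed(cfg$seed, {
    x <- matrix(NA_real_, n, m)
    roles <- character(m)
    shift <- cfg$effect * cfg$noise_sd / 2
    j <- 0L
    for (i in seq_len(cfg$m_informative)) {
      j <- j + 1L
      x[, j] <- rnorm(n, mean = labels * shift, sd = cfg$noise_sd)
      roles[j] <- "informative"
    }
    for (i in seq_len(cfg$m_redundant)) {
      j <- j + 1L
      parent <- ((i - 1L) %% cfg$m_informative) + 1L
      x[, j] <- cfg$rho * x[, parent] +
        sqrt(1 - cfg$rho^2) * rnorm(n, sd = cfg$noise_sd)
      roles[j] <- "redundant"
    }
    for (i in seq_len(cfg$m_noise)) {
      j <- j + 1L
      x[, j] <- rnorm(n, sd = cfg$noise_sd)
      roles[j] <- "noise"
    }
    if (cfg$distribution == "lognormal") x <- exp(x)
    ids <- sprintf("SYN%06d", seq_len(m))
    if (cfg$duplicate_ids > 0L) {
      k <- min(cfg$duplicate_ids, m - 1L)
      dup_at <- sort(sample(2:m, k))
      for (d in dup_at) ids[d] <- ids[d - 1L]  # sequential: chains allowed
    }
    dimnames(x) <- list(sprintf("SAMP%03d", seq_len(n)), ids)
    ds <- labeled_dataset(x,
                          ifelse(labels == 1L, "tumour", "normal"),
                          positive = "tumour")
    names(roles) <- ids
    list(dataset = ds, roles = roles, config = cfg)
  })
}

#' Write ground-truth gene roles as TSV
#'
#' @param syn result of [synth_dataset()].
#' @param path output file.
#' @returns `path`, invisibly.
#' @export
write_roles <- function(syn, path) {
  write.table(data.frame(gene_id = names(syn$roles), role = syn$roles),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
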