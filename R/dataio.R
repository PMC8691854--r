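#' Construct a labelled expression dataset
#'
#' Bundles a continuous expression matrix with a binary class label per
#' sample.  This is the container every selection and evaluation function
#' in the package consumes.  Samples are rows and genes are columns;
#' [read_expression_table()] normalises file orientation on load.
#'
#' Class labels are stored internally as integers in \{-1, +1\}.  When
#' `labels` is a factor or character vector with two distinct values, the
#' lexicographically smaller name maps to -1 unless `positive` names the
#' class that should map to +1 (for tumour/normal data you would usually
#' set `positive = "tumour"`).
#'
#' @param x numeric matrix, samples in rows and genes in columns.  Row and
#'   column names become sample and gene identifiers (generated when
#'   absent).  Duplicate gene identifiers are permitted on construction;
#'   uniqueness is established by [remove_duplicate_genes()].
#' @param labels class label per sample: integers in \{-1, +1\} or a
#'   two-valued factor/character vector.
#' @param positive optional name of the class mapped to +1.
#' @returns An object of class `labeled_dataset`: a list with elements
#'   `x` (matrix), `labels` (integer vector in \{-1, +1\}) and
#'   `class_names` (character vector named `"-1"`, `"+1"`).
#' @examples
#' ds <- labeled_dataset(matrix(rnorm(20), 4, 5),
#'                       c("normal", "tumour", "tumour", "normal"),
#'                       positive = "tumour")
#' ds$labels
#' @export
labeled_dataset <- function(x, labels, positive = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`x` must be a numeric matrix (samples x genes)")
  if (length(labels) != nrow(x))
    stopf("label count (%d) does not match sample count (%d)",
          length(labels), nrow(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("G", seq_len(ncol(x)))

  if (is.factor(labels)) labels <- as.character(labels)
  uniq <- unique(labels)
  if (length(uniq) > 2L)
    stopf("labels must take at most 2 distinct values, found %d", length(uniq))
  if (is.numeric(labels) && all(labels %in% c(-1, 1))) {
    lab <- as.integer(labels)
    class_names <- c("-1" = "-1", "+1" = "+1")
  } else {
    labels <- as.character(labels)
    lv <- sort(unique(labels))
    if (!is.null(positive)) {
      if (!positive %in% lv)
        stopf("positive class '%s' not among labels (%s)",
              positive, paste(lv, collapse = ", "))
      pos <- positive
    } else {
      pos <- lv[length(lv)]  # lexicographically larger name -> +1
    }
    neg <- setdiff(lv, pos)
    if (length(neg) == 0L) neg <- pos  # single-class data
    lab <- ifelse(labels == pos, 1L, -1L)
    class_names <- c("-1" = neg[1L], "+1" = pos)
  }
  structure(list(x = x, labels = lab, class_names = class_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(-1L, 1L)))
  cat(sprintf("<labeled_dataset> %d samples x %d genes\n",
              nrow(x$x), ncol(x$x)))
  cat(sprintf("  classes: %s (-1) n=%d | %s (+1) n=%d\n",
              x$class_names[["-1"]], tab[["-1"]],
              x$class_names[["+1"]], tab[["1"]]))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$x)

gene_ids <- function(ds) colnames(ds$x)
sample_ids <- function(ds) rownames(ds$x)

label_names <- function(ds) {
  ifelse(ds$labels == 1L, ds$class_names[["+1"]], ds$class_names[["-1"]])
}

# Subset a dataset by sample index and/or gene identifier/index.
subset_dataset <- function(ds, samples = NULL, genes = NULL) {
  x <- ds$x
  labels <- ds$labels
  if (!is.null(samples)) {
    x <- x[samples, , drop = FALSE]
    labels <- labels[samples]
  }
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  out <- ds
  out$x <- x
  out$labels <- labels
  out
}

require_binary <- function(ds, what = "this operation") {
  if (length(unique(ds$labels)) != 2L)
    stopf("%s requires exactly 2 classes; found %d",
          what, length(unique(ds$labels)))
  invisible(ds)
}

detect_sep <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

parse_numeric_cells <- function(fields, row_labels, col_labels, allow_missing) {
  n <- length(fields)
  m <- length(fields[[1L]])
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    bad <- which(is.na(v) & !(fields[[i]] %in% c("NA", "")))
    if (length(bad) > 0L)
      stopf("cell at row '%s', column '%s' does not parse as a number: '%s'",
            row_labels[i], col_labels[bad[1L]], fields[[i]][bad[1L]])
    if (!allow_missing && anyNA(v))
      stopf("missing value at row '%s', column '%s' (use allow_missing = TRUE and impute_missing())",
            row_labels[i], col_labels[which(is.na(v))[1L]])
    out[i, ] <- v
  }
  out
}

#' Read a delimited expression table
#'
#' Loads a CSV/TSV expression matrix with gene identifiers and per-sample
#' class labels into a [labeled_dataset()].  The delimiter (comma or tab)
#' is auto-detected from the header line.
#'
#' Two layouts are supported.  With `orientation = "genes_in_rows"` the
#' header holds sample identifiers, each subsequent row is one gene
#' (identifier first), and an optional final row whose identifier is
#' `"class"` carries the labels.  With `orientation = "samples_in_rows"`
#' the header holds gene identifiers, each row is one sample, and an
#' optional `"class"` column carries the labels.  Labels may instead be
#' supplied in a separate two-column (sample_id, class) delimited file via
#' `label_file`.
#'
#' @param path file to read.
#' @param orientation matrix layout in the file; see Details.
#' @param label_file optional path to a two-column (sample_id, class)
#'   delimited label file; overrides any class row/column in `path`.
#' @param positive passed to [labeled_dataset()].
#' @param allow_missing if `FALSE` (default) any missing cell is an error;
#'   if `TRUE`, missing cells are kept as `NA` for [impute_missing()].
#' @returns A [labeled_dataset()].
#' @seealso [write_expression_table()] for the inverse operation.
#' @export
read_expression_table <- function(path,
                                  orientation = c("genes_in_rows",
                                                  "samples_in_rows"),
                                  label_file = NULL,
                                  positive = NULL,
                                  allow_missing = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("file %s has no data rows", path)
  sep <- detect_sep(lines[1L])
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L]))
    stopf("ragged row: line %d has %d fields, expected %d",
          which(widths != widths[1L])[1L], widths[widths != widths[1L]][1L],
          widths[1L])
  header <- fields[[1L]]
  body <- fields[-1L]
  row_ids <- vapply(body, `[`, "", 1L)
  cells <- lapply(body, `[`, -1L)
  col_ids <- header[-1L]

  labels_raw <- NULL
  is_class_row <- tolower(row_ids) == "class"
  if (orientation == "genes_in_rows") {
    if (any(is_class_row)) {
      labels_raw <- cells[[which(is_class_row)[1L]]]
      cells <- cells[!is_class_row]
      row_ids <- row_ids[!is_class_row]
    }
    x <- parse_numeric_cells(cells, row_ids, col_ids, allow_missing)
    x <- t(x)
    dimnames(x) <- list(col_ids, row_ids)   # samples x genes
  } else {
    class_col <- which(tolower(col_ids) == "class")
    if (length(class_col) > 0L) {
      labels_raw <- vapply(cells, `[`, "", class_col[1L])
      cells <- lapply(cells, `[`, -class_col[1L])
      col_ids <- col_ids[-class_col[1L]]
    }
    x <- parse_numeric_cells(cells, row_ids, col_ids, allow_missing)
    dimnames(x) <- list(row_ids, col_ids)
  }

  if (!is.null(label_file)) {
    lab_tab <- read.table(label_file, sep = detect_sep(readLines(label_file, n = 1L)),
                          header = FALSE, colClasses = "character")
    if (ncol(lab_tab) != 2L)
      stopf("label file %s must have exactly 2 columns (sample_id, class)",
            label_file)
    idx <- match(rownames(x), lab_tab[[1L]])
    if (anyNA(idx))
      stopf("label file is missing samples: %s",
            paste(rownames(x)[is.na(idx)], collapse = ", "))
    labels_raw <- lab_tab[[2L]][idx]
  }
  if (is.null(labels_raw))
    stopf("no class labels found in %s: add a 'class' row/column or pass label_file",
          path)
  suppressWarnings({
    num <- as.numeric(labels_raw)
  })
  if (!anyNA(num) && all(num %in% c(-1, 1))) labels_raw <- num
  labeled_dataset(x, labels_raw, positive = positive)
}

#' Write a delimited expression table
#'
#' Writes a [labeled_dataset()] in the layout read by
#' [read_expression_table()].  The delimiter is a comma when `path` ends
#' in `.csv`, otherwise a tab.  Labels are written as a final `"class"`
#' row (genes-in-rows) or column (samples-in-rows), using the original
#' class names.
#'
#' @param ds a [labeled_dataset()].
#' @param path output file.
#' @param orientation matrix layout to write.
#' @returns `path`, invisibly.
#' @export
write_expression_table <- function(ds, path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  labs <- label_names(ds)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  fmt_row <- function(...) paste(c(...), collapse = sep)
  if (orientation == "genes_in_rows") {
    writeLines(fmt_row("gene_id", sample_ids(ds)), con)
    for (j in seq_len(ncol(ds$x)))
      writeLines(fmt_row(gene_ids(ds)[j],
                         format(ds$x[, j], digits = 17, trim = TRUE,
                                scientific = FALSE)), con)
    writeLines(fmt_row("class", labs), con)
  } else {
    writeLines(fmt_row("sample_id", gene_ids(ds), "class"), con)
    for (i in seq_len(nrow(ds$x)))
      writeLines(fmt_row(sample_ids(ds)[i],
                         format(ds$x[i, ], digits = 17, trim = TRUE,
                                scientific = FALSE), labs[i]), con)
  }
  invisible(path)
}

#' Tabulate a selection result for reporting
#'
#' Produces the standard report table (rank, gene_id, stage, relevance,
#' redundancy, score) from a stage-1 [ga_select()] result or a stage-2
#' [mrmr_select()] result.
#'
#' @param result a `gene_subset` or `mrmr_result`.
#' @returns A data frame with one row per selected gene.
#' @export
selection_table <- function(result) UseMethod("selection_table")

#' @export
selection_table.gene_subset <- function(result) {
  rel <- result$relevance %||% rep(NA_real_, length(result$gene_ids))
  data.frame(rank = seq_along(result$gene_ids),
             gene_id = result$gene_ids,
             stage = result$stage,
             relevance = rel,
             redundancy = NA_real_,
             score = rep(result$fitness %||% NA_real_,
                         length(result$gene_ids)),
             stringsAsFactors = FALSE)
}

#' @export
selection_table.mrmr_result <- function(result) {
  tr <- result$trace
  data.frame(rank = tr$step,
             gene_id = tr$gene_id,
             stage = "stage2",
             relevance = tr$relevance,
             redundancy = tr$redundancy,
             score = tr$score,
             stringsAsFactors = FALSE)
}

#' Write a selection/metrics report
#'
#' Emits a tab-delimited report with a `#SELECTION` block (the
#' [selection_table()] of `result`) and, when `metrics` is non-empty, a
#' `#METRICS` key-value block.  The file round-trips through
#' [read_selection_report()].
#'
#' @param result a `gene_subset` or `mrmr_result`; must be non-empty.
#' @param path output file.
#' @param metrics optional named list/vector of scalar metrics.
#' @returns `path`, invisibly.
#' @export
write_selection_report <- function(result, path, metrics = NULL) {
  tab <- selection_table(result)
  if (nrow(tab) == 0L) stopf("selection result is empty; nothing to report")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#SELECTION", con)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  for (i in seq_len(nrow(tab)))
    writeLines(paste(c(tab$rank[i], tab$gene_id[i], tab$stage[i],
                       format(c(tab$relevance[i], tab$redundancy[i],
                                tab$score[i]), digits = 17, trim = TRUE)),
                     collapse = "\t"), con)
  metrics <- unlist(metrics)
  if (length(metrics) > 0L) {
    writeLines("#METRICS", con)
    for (k in names(metrics))
      writeLines(paste(k, format(metrics[[k]], digits = 17, trim = TRUE),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Read back a selection report
#'
#' @param path a file written by [write_selection_report()].
#' @returns A list with `selection` (data frame) and `metrics`
#'   (named numeric, possibly empty).
#' @export
read_selection_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sel_at <- which(lines == "#SELECTION")
  met_at <- which(lines == "#METRICS")
  if (length(sel_at) != 1L) stopf("%s is not a selection report", path)
  sel_end <- if (length(met_at) == 1L) met_at - 1L else length(lines)
  sel <- read.table(text = lines[(sel_at + 1L):sel_end], sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  metrics <- numeric(0)
  if (length(met_at) == 1L && met_at < length(lines)) {
    kv <- read.table(text = lines[(met_at + 1L):length(lines)], sep = "\t",
                     header = FALSE, stringsAsFactors = FALSE)
    metrics <- setNames(as.numeric(kv[[2L]]), kv[[1L]])
  }
  list(selection = sel, metrics = metrics)
}
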