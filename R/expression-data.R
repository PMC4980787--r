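#' Expression dataset container
#'
#' An `expression_dataset` holds a samples-by-genes matrix of expression
#' intensities together with one class label per sample and one identifier
#' per gene. It is the common currency of the prefilter, the fitness
#' evaluator and the swarm search. Labels may be arbitrary strings or
#' integers; internally they are kept as a factor whose levels follow the
#' order of first appearance in the input, so runs are deterministic for a
#' given file.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param labels vector of per-sample class labels (length `nrow(values)`).
#' @param gene_ids character vector of per-gene identifiers; defaults to
#'   the column names of `values` or `g0..g{n-1}` when absent.
#' @return An object of class `expression_dataset` with elements `values`,
#'   `labels` (factor), `gene_ids`, `n_samples` and `n_genes`.
#' @examples
#' m <- matrix(rnorm(12), nrow = 4)
#' expression_dataset(m, labels = c("A", "A", "B", "B"))
#' @export
expression_dataset <- function(values, labels, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing values; ",
         "re-load with `impute = TRUE` or clean the input", call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("`labels` must have one entry per sample (row)", call. = FALSE)
  }
  labels <- factor(as.character(labels), levels = unique(as.character(labels)))
  if (nlevels(labels) < 2) {
    stop("at least 2 distinct classes are required", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
  }
  if (is.null(gene_ids)) {
    gene_ids <- paste0("g", seq_len(ncol(values)) - 1L)
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(values)) {
    stop("`gene_ids` must have one entry per gene (column)", call. = FALSE)
  }
  dimnames(values) <- NULL
  structure(
    list(
      values = values,
      labels = labels,
      gene_ids = gene_ids,
      n_samples = nrow(values),
      n_genes = ncol(values)
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d samples x %d genes, %d classes (%s)\n",
    x$n_samples, x$n_genes, nlevels(x$labels),
    paste(sprintf("%s: %d", levels(x$labels), tabulate(x$labels)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Coerce a labelled data frame to an expression dataset
#'
#' The first column (by default) carries the class label; every remaining
#' column is a gene. Gene order in the data frame is preserved exactly.
#'
#' @param data a data frame with one label column and numeric gene columns.
#' @param label_column index or name of the label column. Default 1.
#' @param impute replace missing expression values by the gene mean instead
#'   of rejecting the input. Default `FALSE` (reject).
#' @return An [expression_dataset()].
#' @examples
#' df <- data.frame(class = c("A", "A", "B", "B"),
#'                  g0 = c(1, 2, 3, 4), g1 = c(4, 3, 2, 1))
#' as_expression_dataset(df)
#' @export
as_expression_dataset <- function(data, label_column = 1, impute = FALSE) {
  if (inherits(data, "expression_dataset")) {
    return(data)
  }
  data <- as.data.frame(data)
  if (is.character(label_column)) {
    label_column <- match(label_column, names(data))
  }
  if (is.na(label_column) || label_column < 1 || label_column > ncol(data)) {
    stop("label column not present in `data`", call. = FALSE)
  }
  labels <- data[[label_column]]
  expr <- data[, -label_column, drop = FALSE]
  not_num <- !vapply(expr, is.numeric, logical(1))
  if (any(not_num)) {
    stop("non-numeric expression column(s): ",
         paste(names(expr)[not_num], collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(expr)
  if (anyNA(values)) {
    if (!impute) {
      stop("expression matrix contains missing values; ",
           "pass `impute = TRUE` for per-gene mean imputation", call. = FALSE)
    }
    for (j in seq_len(ncol(values))) {
      nas <- is.na(values[, j])
      if (any(nas)) values[nas, j] <- mean(values[, j], na.rm = TRUE)
    }
  }
  expression_dataset(values, labels, gene_ids = names(expr))
}

#' Convert an expression dataset back to a tibble
#'
#' Inverse of [as_expression_dataset()]: label column first, then one
#' column per gene, in stored order.
#'
#' @param x an `expression_dataset`.
#' @param ... unused.
#' @return A tibble with `n_samples` rows.
#' @export
as_tibble.expression_dataset <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$values))
  names(out) <- x$gene_ids
  dplyr::bind_cols(tibble::tibble(class = as.character(x$labels)), out)
}

#' Read a labelled expression matrix from disk
#'
#' Supported formats are delimited text (`csv`, `tsv`; header row with gene
#' identifiers optional) and MATLAB `mat` files holding a single
#' uncompressed numeric matrix whose first column is the diagnosis code --
#' the layout in which the classic cancer microarray benchmark collections
#' are distributed. Rows are samples; the label column (default: first) is
#' the class; all remaining columns are genes, order preserved.
#'
#' @param path file to read.
#' @param format `"csv"`, `"tsv"` or `"mat"`; default guessed from the file
#'   extension.
#' @param label_column index of the label column. Default 1.
#' @param header does the delimited file carry a header row of identifiers?
#'   Default `TRUE` for csv/tsv; ignored for mat.
#' @param impute see [as_expression_dataset()].
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(path,
                                    format = c("auto", "csv", "tsv", "mat"),
                                    label_column = 1,
                                    header = TRUE,
                                    impute = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mat = "mat",
                     stop("cannot guess format from extension '", ext,
                          "'; pass `format`", call. = FALSE))
  }
  if (format == "mat") {
    m <- read_mat_matrix(path)
    labels <- m[, label_column]
    values <- m[, -label_column, drop = FALSE]
    return(expression_dataset(values, labels,
                              gene_ids = paste0("g", seq_len(ncol(values)) - 1L)))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!header) {
    names(df) <- c("class", paste0("g", seq_len(ncol(df) - 1L) - 1L))
  }
  as_expression_dataset(df, label_column = label_column, impute = impute)
}

#' Write an expression dataset as delimited text
#'
#' @param dataset an `expression_dataset`.
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression_dataset <- function(dataset, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- as.data.frame(as_tibble.expression_dataset(dataset))
  utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a selection run record
#'
#' `write_run_result()` stores the machine-readable JSON record (selected
#' gene identifiers, accuracy, fitness, subset size, seed, the resolved
#' parameter snapshot and the per-iteration trace) and appends one
#' human-readable summary line. `read_run_result()` restores the record.
#'
#' @param result a `mabc_result` as returned by [mabc_select()].
#' @param path output file (JSON).
#' @return `path` (write) or a list with class `mabc_result` (read).
#' @export
write_run_result <- function(result, path) {
  stopifnot(inherits(result, "mabc_result"))
  rec <- list(
    summary = sprintf(
      "selected %d gene(s) [%s] accuracy %.4f%% fitness %.6f seed %d",
      result$n_selected, paste(result$selected_genes, collapse = ", "),
      result$accuracy, result$fitness, result$seed),
    selected_genes = result$selected_genes,
    selected_idx = result$selected_idx,
    accuracy = result$accuracy,
    fitness = result$fitness,
    n_selected = result$n_selected,
    seed = result$seed,
    params = result$params[setdiff(names(result$params), "c1")],
    trace = as.data.frame(result$trace)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_result
#' @export
read_run_result <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec$trace <- tibble::as_tibble(rec$trace)
  class(rec) <- "mabc_result"
  rec
}
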