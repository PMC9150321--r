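#' Annotated expression dataset
#'
#' The universal input container of the package: a cells x genes matrix of
#' library-size-normalized, `log2(x + 1)`-transformed expression values,
#' per-cell annotation columns (at least one naming cell-type classes), and
#' optionally a matching matrix of raw counts (needed only for copy-number
#' inference).
#'
#' @param matrix Numeric cells x genes matrix, nonnegative, no missing
#'   values. Rownames are cell ids, colnames gene symbols (both unique).
#' @param annotations A `data.frame` with one row per cell; each column is a
#'   categorical annotation (e.g. cell type), possibly at several hierarchy
#'   levels.
#' @param counts Optional raw count matrix with identical dimnames.
#' @param dataset_name Character scalar identifying the dataset.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `counts`, `annotations`, `dataset_name`, `cell_ids`,
#'   `gene_symbols`.
#' @export
expression_dataset <- function(matrix, annotations, counts = NULL,
                               dataset_name = "dataset") {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  cell_ids <- rownames(matrix)
  gene_symbols <- colnames(matrix)
  if (is.null(cell_ids) || is.null(gene_symbols))
    stop("`matrix` must carry cell ids as rownames and gene symbols as colnames",
         call. = FALSE)
  gene_symbols <- trimws(gene_symbols)
  cell_ids <- trimws(cell_ids)
  colnames(matrix) <- gene_symbols
  rownames(matrix) <- cell_ids
  if (anyNA(matrix))
    stop("expression matrix contains missing values", call. = FALSE)
  if (any(matrix < 0))
    stop("normalization error: expression matrix contains negative values; ",
         "expected nonnegative log2(1 + normalized count) values", call. = FALSE)
  if (anyDuplicated(gene_symbols))
    stop("indexing error: duplicate gene symbols: ",
         paste(head(unique(gene_symbols[duplicated(gene_symbols)]), 5),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("indexing error: duplicate cell ids", call. = FALSE)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (nrow(annotations) != nrow(matrix))
    stop("`annotations` must have one row per cell", call. = FALSE)
  rownames(annotations) <- cell_ids
  if (!is.null(counts)) {
    if (!identical(dim(counts), dim(matrix)))
      stop("`counts` must have the same dimensions as `matrix`", call. = FALSE)
    if (!identical(trimws(rownames(counts)), cell_ids) ||
        !identical(trimws(colnames(counts)), gene_symbols))
      stop("`counts` must have identical cell/gene indexing to `matrix`",
           call. = FALSE)
    if (any(counts < 0) || anyNA(counts))
      stop("`counts` must be nonnegative with no missing values", call. = FALSE)
  }
  structure(list(matrix = matrix, counts = counts, annotations = annotations,
                 dataset_name = as.character(dataset_name)[1],
                 cell_ids = cell_ids, gene_symbols = gene_symbols),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> '%s': %d cells x %d genes\n",
              x$dataset_name, nrow(x$matrix), ncol(x$matrix)))
  cat("  annotations:", paste(colnames(x$annotations), collapse = ", "), "\n")
  cat("  raw counts:", if (is.null(x$counts)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Check that a dataset looks like unscaled log-normalized expression
#'
#' The pipeline assumes the full gene complement of library-size-normalized,
#' log2-transformed (not z-scaled) expression. This validator emits warnings
#' (never errors) when the matrix looks z-scaled — negative entries or
#' per-gene means numerically centred at zero — or when the gene count is
#' small enough to suggest a pre-filtered (e.g. highly-variable-genes-only)
#' input.
#'
#' @param dataset An [expression_dataset()].
#' @param min_genes Floor below which the gene set is flagged as incomplete
#'   (default 5000).
#' @return Invisibly, a character vector of warning messages (empty if clean).
#' @export
validate_normalization <- function(dataset, min_genes = 5000) {
  stopifnot(inherits(dataset, "expression_dataset"))
  msgs <- character(0)
  m <- dataset$matrix
  gene_means <- colMeans(m)
  if (any(m < 0) || mean(abs(gene_means) < 1e-8) > 0.5) {
    msgs <- c(msgs, "scaled data: matrix looks z-scored (negative values or per-gene means ~ 0); provide unscaled log2(1 + normalized) values")
  }
  if (ncol(m) < min_genes) {
    msgs <- c(msgs, sprintf("incomplete gene set: only %d genes present (< %d); the full profiled gene complement is expected, not a preselected subset",
                            ncol(m), min_genes))
  }
  for (msg in msgs) warning(msg, call. = FALSE)
  invisible(msgs)
}

# internal: pull a validated label vector from a dataset
.get_labels <- function(dataset, label_column) {
  if (!label_column %in% colnames(dataset$annotations))
    stop(sprintf("label column '%s' not found in annotations (have: %s)",
                 label_column,
                 paste(colnames(dataset$annotations), collapse = ", ")),
         call. = FALSE)
  labels <- as.character(dataset$annotations[[label_column]])
  if (anyNA(labels))
    stop(sprintf("label column '%s' contains missing values", label_column),
         call. = FALSE)
  labels
}
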