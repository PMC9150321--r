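# Reading and writing annotated cell x gene matrices in the h5ad (AnnData)
# HDF5 layout. Only the subset of the schema the pipeline touches is
# handled: X (dense or CSR/CSC sparse), obs/var dataframes with string,
# numeric, boolean or categorical columns, and named layers (for raw counts).

.h5_read_attr <- function(path, name, attr) {
  att <- rhdf5::h5readAttributes(path, name)
  att[[attr]]
}

# decode one obs/var column written by anndata (plain array, nullable, or
# categorical group with codes + categories)
.h5_read_column <- function(path, name) {
  x <- rhdf5::h5read(path, name)
  if (is.list(x) && !is.null(x$categories)) {
    codes <- as.integer(x$codes) + 1L
    out <- as.character(x$categories)[ifelse(codes == 0L, NA_integer_, codes)]
    return(out)
  }
  if (is.list(x) && !is.null(x$values)) x <- x$values
  as.vector(x)
}

# X or a layer; returns a dense R matrix in HDF5 (row-major) orientation,
# i.e. cells x genes once transposed from the R read
.h5_read_matrix <- function(path, name, n_obs, n_var) {
  att <- tryCatch(rhdf5::h5readAttributes(path, name), error = function(e) list())
  enc <- att[["encoding-type"]]
  if (!is.null(enc) && enc %in% c("csr_matrix", "csc_matrix")) {
    g <- rhdf5::h5read(path, name)
    shape <- as.integer(att[["shape"]])  # (n_obs, n_var)
    if (enc == "csr_matrix") {
      # CSR of X == CSC of t(X): indptr over rows, indices are columns
      sp <- Matrix::sparseMatrix(i = as.integer(g$indices) + 1L,
                                 p = as.numeric(g$indptr),
                                 x = as.numeric(g$data), dims = rev(shape))
      m <- t(as.matrix(sp))
    } else {
      sp <- Matrix::sparseMatrix(i = as.integer(g$indices) + 1L,
                                 p = as.numeric(g$indptr),
                                 x = as.numeric(g$data), dims = shape)
      m <- as.matrix(sp)
    }
    storage.mode(m) <- "double"
    return(m)
  }
  m <- rhdf5::h5read(path, name)
  # anndata stores (n_obs, n_var) C-order; rhdf5 reads it as n_var x n_obs
  m <- t(m)
  storage.mode(m) <- "double"
  m
}

#' Read an annotated expression matrix from an h5ad file
#'
#' Reads `X` (dense or sparse), the `obs` index and requested label columns,
#' the `var` index (gene symbols), and, when present, the raw-count layer
#' `layers/counts`.
#'
#' @param path Path to an existing `.h5ad` file.
#' @param label_columns Character vector of `obs` columns that must be
#'   present; they become the dataset's annotation columns. Additional obs
#'   columns are read too when available.
#' @param dataset_name Name recorded on the returned dataset; defaults to the
#'   file name without extension.
#' @return An [expression_dataset()].
#' @export
read_h5ad <- function(path, label_columns = character(0), dataset_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dataset_name))
    dataset_name <- sub("\\.h5ad$", "", basename(path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  obs_cols <- contents$name[contents$group == "/obs" & contents$name != "_index"]
  idx_name <- tryCatch(.h5_read_attr(path, "obs", "_index"),
                       error = function(e) "_index")
  if (is.null(idx_name)) idx_name <- "_index"
  obs_cols <- setdiff(obs_cols, idx_name)
  missing <- setdiff(label_columns, obs_cols)
  if (length(missing))
    stop("labeled error: label column(s) missing from obs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cell_ids <- as.character(rhdf5::h5read(path, paste0("obs/", idx_name)))
  var_idx <- tryCatch(.h5_read_attr(path, "var", "_index"),
                      error = function(e) "_index")
  if (is.null(var_idx)) var_idx <- "_index"
  gene_symbols <- as.character(rhdf5::h5read(path, paste0("var/", var_idx)))
  m <- .h5_read_matrix(path, "X", length(cell_ids), length(gene_symbols))
  dimnames(m) <- list(cell_ids, gene_symbols)
  ann <- as.data.frame(setNames(
    lapply(obs_cols, function(col) .h5_read_column(path, paste0("obs/", col))),
    obs_cols), stringsAsFactors = FALSE, optional = TRUE)
  if (!length(obs_cols)) ann <- data.frame(row.names = cell_ids)
  counts <- NULL
  if (any(contents$group == "/layers" & contents$name == "counts")) {
    counts <- .h5_read_matrix(path, "layers/counts",
                              length(cell_ids), length(gene_symbols))
    dimnames(counts) <- dimnames(m)
  }
  expression_dataset(m, ann, counts = counts, dataset_name = dataset_name)
}

.h5_string_attr <- function(obj, name, value) {
  rhdf5::h5writeAttribute(value, obj, name, variableLengthString = TRUE,
                          asScalar = length(value) == 1)
}

.h5_write_array <- function(fid, name, m) {
  # write transposed so python/anndata sees (n_obs, n_var) row-major
  rhdf5::h5write(t(m), fid, name)
  did <- rhdf5::H5Dopen(fid, name)
  .h5_string_attr(did, "encoding-type", "array")
  .h5_string_attr(did, "encoding-version", "0.2.0")
  rhdf5::H5Dclose(did)
}

.h5_write_df <- function(fid, group, index, columns) {
  gid <- rhdf5::H5Gcreate(fid, group)
  .h5_string_attr(gid, "encoding-type", "dataframe")
  .h5_string_attr(gid, "encoding-version", "0.2.0")
  .h5_string_attr(gid, "_index", "_index")
  if (length(columns)) {
    .h5_string_attr(gid, "column-order", names(columns))
  } else {
    rhdf5::h5writeAttribute(numeric(0), gid, "column-order")
  }
  write_col <- function(name, value) {
    if (is.character(value)) {
      rhdf5::h5write(value, gid, name, variableLengthString = TRUE)
      enc <- "string-array"
    } else {
      rhdf5::h5write(value, gid, name)
      enc <- "array"
    }
    did <- rhdf5::H5Dopen(gid, name)
    .h5_string_attr(did, "encoding-type", enc)
    .h5_string_attr(did, "encoding-version", "0.2.0")
    rhdf5::H5Dclose(did)
  }
  write_col("_index", as.character(index))
  for (nm in names(columns)) {
    v <- columns[[nm]]
    if (is.factor(v)) v <- as.character(v)
    write_col(nm, v)
  }
  rhdf5::H5Gclose(gid)
}

#' Write an expression dataset to an h5ad file
#'
#' Writes a dense `X`, the annotation columns into `obs`, gene symbols into
#' `var`, and the raw counts (if present) into `layers/counts`, using the
#' AnnData on-disk schema so the file is readable by the python ecosystem.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  .h5_string_attr(fid, "encoding-type", "anndata")
  .h5_string_attr(fid, "encoding-version", "0.1.0")
  .h5_write_array(fid, "X", dataset$matrix)
  cols <- as.list(dataset$annotations)
  .h5_write_df(fid, "obs", dataset$cell_ids, cols)
  .h5_write_df(fid, "var", dataset$gene_symbols, list())
  if (!is.null(dataset$counts)) {
    gid <- rhdf5::H5Gcreate(fid, "layers")
    .h5_string_attr(gid, "encoding-type", "dict")
    .h5_string_attr(gid, "encoding-version", "0.1.0")
    rhdf5::H5Gclose(gid)
    .h5_write_array(fid, "layers/counts", dataset$counts)
  }
  rhdf5::H5Fclose(fid)
  invisible(path)
}
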