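#' Directed gene signature
#'
#' A named, ordered, duplicate-free gene list with a direction: enriched in
#' the class of interest (`"up_in_class"`, e.g. the tumor signature) or
#' depleted in it (`"down_in_class"`, the "normal" signature).
#'
#' @param name Signature name (e.g. `"tumor"`).
#' @param genes Character vector of gene symbols; whitespace is stripped,
#'   duplicates are an error.
#' @param direction `"up_in_class"` or `"down_in_class"`.
#' @param provenance Optional list of `(dataset_name, comparison)` records
#'   describing where the signature came from.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes,
                           direction = c("up_in_class", "down_in_class"),
                           provenance = list()) {
  direction <- match.arg(direction)
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("signature '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(genes))
    stop("signature '", name, "' contains duplicate genes", call. = FALSE)
  structure(list(name = as.character(name)[1], genes = genes,
                 direction = direction, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> '%s' (%s): %d genes\n",
              x$name, x$direction, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Read gene signatures from a GMT file
#'
#' GMT dialect: one tab-separated line per set, fields `name`,
#' `description`, then genes. Duplicate genes within a set are dropped
#' (keeping the first occurrence) with a warning.
#'
#' @param path Path to a GMT file.
#' @param directions Optional named character vector mapping set names to
#'   directions; unnamed sets default to `"up_in_class"`.
#' @return A named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path, directions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    name <- trimws(fields[1])
    genes <- trimws(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate genes deduplicated (first occurrence kept)",
                      name), call. = FALSE)
      genes <- genes[!duplicated(genes)]
    }
    dir <- if (!is.null(directions) && name %in% names(directions))
      directions[[name]] else "up_in_class"
    sigs[[name]] <- gene_signature(name, genes, direction = dir)
  }
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures A single [gene_signature()] or a list of them.
#' @param path Output path.
#' @param description Description field written as the second GMT column.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path, description = "sctumor") {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    stopifnot(inherits(s, "gene_signature"))
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
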