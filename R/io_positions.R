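# Gene genomic positions: the only thing copy-number inference needs from
# the genome is a linear ordering of genes, so the table is kept minimal.

# natural chromosome ordering: numeric tokens first in numeric order, then
# the rest lexicographically (chr1, chr2, ..., chr10, ..., chrX, chrY)
.chrom_order <- function(chrom) {
  token <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(token))
  order(is.na(num), num, token, method = "radix")
}

#' Read a gene genomic-position table
#'
#' Expects a tab-delimited file with a header and four columns: gene symbol,
#' chromosome, start, end (1-based inclusive coordinates). Rows are returned
#' sorted by chromosome (natural order) then start. Only the ordering of
#' genes is consumed downstream.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `gene`, `chromosome`, `start`, `end`,
#'   class `gene_positions`.
#' @export
read_gene_positions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4)
    stop("gene position table must have 4 columns: gene, chromosome, start, end",
         call. = FALSE)
  tab <- tab[, 1:4]
  names(tab) <- c("gene", "chromosome", "start", "end")
  gene_positions(tab)
}

#' Construct a validated gene-position table
#'
#' @param tab A `data.frame` with columns `gene`, `chromosome`, `start`,
#'   `end`.
#' @return The table sorted by (chromosome, start), class `gene_positions`.
#' @export
gene_positions <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chromosome", "start", "end") %in% names(tab)))
  tab$gene <- trimws(as.character(tab$gene))
  tab$chromosome <- as.character(tab$chromosome)
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  if (any(tab$start > tab$end))
    stop("coordinate error: start > end for gene(s): ",
         paste(head(tab$gene[tab$start > tab$end], 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$gene))
    stop("duplicate gene symbols in position table", call. = FALSE)
  chroms <- unique(tab$chromosome)
  chroms <- chroms[.chrom_order(chroms)]
  ord <- order(match(tab$chromosome, chroms), tab$start, method = "radix")
  tab <- tab[ord, c("gene", "chromosome", "start", "end")]
  rownames(tab) <- NULL
  class(tab) <- c("gene_positions", "data.frame")
  tab
}

#' Write a gene-position table as TSV
#'
#' @param positions A `gene_positions` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(positions, path) {
  utils::write.table(positions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
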