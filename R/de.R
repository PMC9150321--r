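# Per-dataset differential expression between two annotated cell classes.
#
# The test statistic is a two-sample t-statistic with deliberately
# overestimated variance: both group variance terms are divided by the size
# of the group under test (the "up" class, typically the smaller one), which
# inflates the standard error relative to Welch's t and makes the gene
# ranking conservative. Degrees of freedom follow Welch-Satterthwaite on the
# inflated variance terms, with each term's own group contributing its
# (n - 1) denominator. The log2 fold change is the difference of group
# means on the log2(1 + normalized) layer.

#' Differential expression with overestimated variance
#'
#' For every gene, computes the overestimated-variance t-statistic, a
#' two-sided p-value, a Benjamini-Hochberg adjusted p-value (within this
#' comparison), and the approximate log2 fold change (difference of group
#' means on the log2 layer, up class minus down class).
#'
#' @param dataset An [expression_dataset()] carrying the log2 layer.
#' @param up_class,down_class Labels of the two classes being compared; the
#'   statistic tests enrichment in `up_class`.
#' @param label_column Annotation column holding the class labels.
#' @return A `data.frame` (class `de_result`) with one row per gene:
#'   `gene`, `log2fc`, `t_statistic`, `p_value`, `p_adj`. Attributes
#'   `dataset_name` and `comparison` record provenance.
#' @export
differential_expression <- function(dataset, up_class, down_class,
                                    label_column) {
  stopifnot(inherits(dataset, "expression_dataset"))
  labels <- .get_labels(dataset, label_column)
  for (cls in c(up_class, down_class)) {
    n <- sum(labels == cls)
    if (n == 0)
      stop(sprintf("label error: class '%s' absent from column '%s'",
                   cls, label_column), call. = FALSE)
    if (n < 2)
      stop(sprintf("insufficient cells: class '%s' has %d cell(s), need >= 2",
                   cls, n), call. = FALSE)
  }
  m_up <- dataset$matrix[labels == up_class, , drop = FALSE]
  m_dn <- dataset$matrix[labels == down_class, , drop = FALSE]
  n_up <- nrow(m_up); n_dn <- nrow(m_dn)
  mean_up <- colMeans(m_up); mean_dn <- colMeans(m_dn)
  var_up <- colSums(sweep(m_up, 2, mean_up)^2) / (n_up - 1)
  var_dn <- colSums(sweep(m_dn, 2, mean_dn)^2) / (n_dn - 1)
  # overestimated variance: both terms share the up-group denominator
  v1 <- var_up / n_up
  v2 <- var_dn / n_up
  se <- sqrt(v1 + v2)
  delta <- mean_up - mean_dn
  t_stat <- ifelse(se == 0, ifelse(delta == 0, 0, sign(delta) * Inf),
                   delta / se)
  df <- (v1 + v2)^2 / (v1^2 / (n_up - 1) + v2^2 / (n_dn - 1))
  df[!is.finite(df) | df <= 0] <- n_up + n_dn - 2
  p <- ifelse(is.infinite(t_stat), 0,
              2 * pt(-abs(t_stat), df = df))
  p[t_stat == 0] <- 1
  res <- data.frame(gene = dataset$gene_symbols,
                    log2fc = delta,
                    t_statistic = t_stat,
                    p_value = p,
                    p_adj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "dataset_name") <- dataset$dataset_name
  attr(res, "comparison") <- c(up = up_class, down = down_class)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Average filtered fold changes across datasets and rank genes
#'
#' For one comparison computed on several datasets, a gene's fold changes
#' are averaged over exactly those datasets where its adjusted p-value
#' passes the threshold (`p_adj < p_adj_threshold`); a dataset where the
#' gene fails (or is absent) contributes nothing, and genes failing
#' everywhere are dropped. Genes are then ranked by average fold change,
#' descending, ties broken lexicographically by symbol, and the top
#' `n_top` are returned.
#'
#' @param de_results A list of `de_result` tables for the same comparison.
#' @param n_top Number of top-ranked genes to keep (default 300).
#' @param p_adj_threshold Adjusted p-value cut for a fold change to count
#'   (default 0.1).
#' @return A `data.frame` with columns `gene`, `avg_log2fc`, `n_datasets`,
#'   at most `n_top` rows, ranked.
#' @export
average_and_rank <- function(de_results, n_top = 300, p_adj_threshold = 0.1) {
  if (inherits(de_results, "de_result")) de_results <- list(de_results)
  stopifnot(length(de_results) >= 1, n_top >= 1,
            p_adj_threshold > 0, p_adj_threshold <= 1)
  cmp <- attr(de_results[[1]], "comparison")
  for (d in de_results) {
    if (!is.null(cmp) && !is.null(attr(d, "comparison")) &&
        !identical(attr(d, "comparison"), cmp))
      stop("all de_results must share the same comparison", call. = FALSE)
  }
  passing <- lapply(de_results, function(d) d[d$p_adj < p_adj_threshold,
                                              c("gene", "log2fc")])
  all_pass <- do.call(rbind, passing)
  if (is.null(all_pass) || nrow(all_pass) == 0) {
    warning("no genes pass the p_adj filter in any dataset; empty list",
            call. = FALSE)
    return(data.frame(gene = character(0), avg_log2fc = numeric(0),
                      n_datasets = integer(0)))
  }
  avg <- tapply(all_pass$log2fc, all_pass$gene, mean)
  n_ds <- tapply(all_pass$log2fc, all_pass$gene, length)
  out <- data.frame(gene = names(avg), avg_log2fc = as.numeric(avg),
                    n_datasets = as.integer(n_ds),
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-out$avg_log2fc, out$gene, method = "radix")
  out <- out[ord, ]
  rownames(out) <- NULL
  head(out, n_top)
}

#' Consolidate per-comparison ranked lists into a signature
#'
#' Up mode takes the set intersection across comparisons (a gene must be
#' enriched against every contrasted class); down mode takes the union
#' (depletion against any class suffices). Output is ordered
#' lexicographically.
#'
#' @param gene_lists A list of character vectors (or `average_and_rank`
#'   tables) — one ranked list per comparison.
#' @param mode `"up"` (intersection) or `"down"` (union).
#' @return Character vector of gene symbols, lexicographically sorted.
#' @export
integrate_signatures <- function(gene_lists, mode = c("up", "down")) {
  mode <- match.arg(mode)
  stopifnot(length(gene_lists) >= 1)
  sets <- lapply(gene_lists, function(x) {
    if (is.data.frame(x)) x <- x$gene
    unique(as.character(x))
  })
  out <- Reduce(if (mode == "up") intersect else union, sets)
  if (!length(out))
    warning("empty signature after ", mode, "-mode consolidation",
            call. = FALSE)
  sort(out, method = "radix")
}

#' Derive tumor and normal gene signatures from annotated datasets
#'
#' Runs the full first step of the workflow: per dataset and per comparison
#' (`tumor vs each contrast class`), differential expression in both
#' directions; per comparison, fold-change averaging across datasets and
#' top-`n_top` ranking; then intersection across comparisons for the
#' tumor-enriched list and union for the tumor-depleted ("normal") list.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param label_column Annotation column with the class labels.
#' @param tumor_label Label of the class of interest.
#' @param normal_labels Labels to contrast against; default: every other
#'   label observed in `label_column` across datasets.
#' @param n_top,p_adj_threshold See [average_and_rank()].
#' @return A list with [gene_signature()] elements `tumor` and `normal`.
#' @export
derive_signatures <- function(datasets, label_column, tumor_label = "Tumor",
                              normal_labels = NULL, n_top = 300,
                              p_adj_threshold = 0.1) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  if (is.null(normal_labels)) {
    normal_labels <- sort(unique(unlist(lapply(datasets, function(d)
      setdiff(unique(.get_labels(d, label_column)), tumor_label)))))
  }
  if (!length(normal_labels)) stop("no contrast classes found", call. = FALSE)
  up_lists <- list(); down_lists <- list()
  provenance <- list()
  for (cls in normal_labels) {
    de_up <- lapply(datasets, function(d)
      differential_expression(d, tumor_label, cls, label_column))
    de_dn <- lapply(datasets, function(d)
      differential_expression(d, cls, tumor_label, label_column))
    up_lists[[cls]] <- average_and_rank(de_up, n_top, p_adj_threshold)
    down_lists[[cls]] <- average_and_rank(de_dn, n_top, p_adj_threshold)
    provenance <- c(provenance, lapply(datasets, function(d)
      list(dataset_name = d$dataset_name,
           comparison = c(tumor_label, cls))))
  }
  up_genes <- integrate_signatures(up_lists, "up")
  down_genes <- integrate_signatures(down_lists, "down")
  if (!length(up_genes)) stop("empty tumor signature", call. = FALSE)
  if (!length(down_genes)) stop("empty normal signature", call. = FALSE)
  list(tumor = gene_signature("tumor", up_genes, "up_in_class", provenance),
       normal = gene_signature("normal", down_genes, "down_in_class",
                               provenance))
}
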