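# Multi-dataset synthetic cohorts with the statistical structure the
# classifier assumes: negative-binomial counts with gene-wise base means
# shared across datasets, per-dataset batch offsets, class imbalance,
# planted tumor-up / tumor-depleted marker genes, and contiguous
# copy-number segments multiplying counts in tumor cells. The normalized
# layer is computed exactly as the pipeline expects its inputs:
# log2(1 + 1e4 * count / library size).

#' Specification of a synthetic multi-dataset cohort
#'
#' Defaults describe the study conditions the package is validated under:
#' 4 datasets of 2000 cells x 6000 genes, a 1:7 tumor:normal imbalance,
#' 150 planted tumor-up and 150 tumor-depleted marker genes with a mean
#' log2 effect of 1.5, moderate per-dataset batch effects, and one 300-gene
#' 2x copy-number gain in tumor cells. Planted markers are sampled from the
#' upper half of base expression (a marker must be detectably expressed to
#' be one) and never overlap the CNV segment.
#'
#' @param n_datasets,n_cells,n_genes Cohort dimensions.
#' @param tumor_fraction Fraction of tumor cells per dataset (default 1/8).
#' @param n_planted_up,n_planted_down Numbers of planted marker genes.
#' @param effect_size Mean log2 shift of planted markers in tumor cells.
#' @param batch_sd SD (log2 units) of the per-dataset gene-wise offset.
#' @param cnv_segments List of segments, each
#'   `list(chromosome =, start =, n_genes =, fold =)` with `start` the gene
#'   index within that chromosome's block; `NULL` plants none; the default
#'   is one 300-gene 2x gain on chr2.
#' @param dispersion Negative-binomial overdispersion (size = 1/dispersion).
#' @param library_sd SD (log scale) of per-cell library-size factors.
#' @param n_chromosomes Chromosomes the genes are spread over (default 10).
#' @param seed RNG seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_datasets = 4, n_cells = 2000, n_genes = 6000,
                        tumor_fraction = 1 / 8, n_planted_up = 150,
                        n_planted_down = 150, effect_size = 1.5,
                        batch_sd = 0.5,
                        cnv_segments = list(list(chromosome = "chr2",
                                                 start = 1, n_genes = 300,
                                                 fold = 2)),
                        dispersion = 0.5, library_sd = 0.3,
                        n_chromosomes = 10, seed = 1) {
  spec <- list(n_datasets = n_datasets, n_cells = n_cells, n_genes = n_genes,
               tumor_fraction = tumor_fraction, n_planted_up = n_planted_up,
               n_planted_down = n_planted_down, effect_size = effect_size,
               batch_sd = batch_sd, cnv_segments = cnv_segments,
               dispersion = dispersion, library_sd = library_sd,
               n_chromosomes = n_chromosomes, seed = seed)
  with(spec, {
    stopifnot(n_datasets >= 1, n_cells >= 4, n_genes >= 10,
              dispersion > 0, library_sd >= 0, batch_sd >= 0,
              n_chromosomes >= 1, effect_size >= 0)
    if (tumor_fraction <= 0 || tumor_fraction >= 1)
      stop("tumor_fraction must be in (0, 1)", call. = FALSE)
    n_cnv <- sum(vapply(cnv_segments, function(s) s$n_genes, numeric(1)),
                 0)
    if (n_planted_up + n_planted_down + n_cnv > n_genes)
      stop("spec error: planted genes exceed n_genes", call. = FALSE)
  })
  class(spec) <- "cohort_spec"
  spec
}

#' Uniformly spaced gene positions for simulated genes
#'
#' @param gene_symbols Character vector of gene names, assigned to
#'   chromosomes in consecutive blocks.
#' @param n_chromosomes Number of chromosomes.
#' @param spacing Base pairs between gene starts (default 1e4).
#' @return A [gene_positions()] table.
#' @export
simulate_gene_positions <- function(gene_symbols, n_chromosomes = 10,
                                    spacing = 1e4) {
  g <- length(gene_symbols)
  per <- ceiling(g / n_chromosomes)
  chrom <- paste0("chr", rep(seq_len(n_chromosomes), each = per))[seq_len(g)]
  within <- unlist(lapply(rle(chrom)$lengths, seq_len))
  start <- 1 + (within - 1) * spacing
  gene_positions(data.frame(gene = gene_symbols, chromosome = chrom,
                            start = start, end = start + spacing / 2,
                            stringsAsFactors = FALSE))
}

#' Simulate a multi-dataset cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `datasets` (list of
#'   [expression_dataset()] with `counts` layers), and `truth` — the
#'   ground-truth manifest with `planted_up`, `planted_down`, `cnv_genes`,
#'   `cnv_segments`, `positions`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  g <- spec$n_genes
  genes <- sprintf("G%05d", seq_len(g))
  positions <- simulate_gene_positions(genes, spec$n_chromosomes)
  base_mean <- rlnorm(g, meanlog = 0, sdlog = 1)
  names(base_mean) <- genes
  # CNV segments: contiguous spans in genome order
  cnv_fold <- rep(1, g); names(cnv_fold) <- genes
  cnv_genes <- character(0)
  for (seg in spec$cnv_segments) {
    block <- positions$gene[positions$chromosome == seg$chromosome]
    if (seg$start + seg$n_genes - 1 > length(block))
      stop("spec error: CNV segment exceeds chromosome ", seg$chromosome,
           call. = FALSE)
    span <- block[seg$start:(seg$start + seg$n_genes - 1)]
    cnv_fold[span] <- seg$fold
    cnv_genes <- union(cnv_genes, span)
  }
  eligible <- setdiff(genes[base_mean >= median(base_mean)], cnv_genes)
  if (length(eligible) < spec$n_planted_up + spec$n_planted_down)
    stop("spec error: not enough well-expressed genes to plant markers",
         call. = FALSE)
  planted_up <- sort(sample(eligible, spec$n_planted_up))
  planted_down <- sort(sample(setdiff(eligible, planted_up),
                              spec$n_planted_down))
  up_mult <- rep(1, g); names(up_mult) <- genes
  up_mult[planted_up] <- 2^spec$effect_size
  up_mult[planted_down] <- 2^(-spec$effect_size)
  tumor_mult <- up_mult * cnv_fold
  n <- spec$n_cells
  n_tumor <- round(spec$tumor_fraction * n)
  datasets <- vector("list", spec$n_datasets)
  for (d in seq_len(spec$n_datasets)) {
    ds_name <- paste0("synth", d)
    batch <- 2^rnorm(g, 0, spec$batch_sd)
    labels <- sample(rep(c("Tumor", "Normal"), c(n_tumor, n - n_tumor)))
    size_factor <- rlnorm(n, 0, spec$library_sd)
    mu_gene <- base_mean * batch
    mu <- outer(size_factor, mu_gene)
    is_tumor <- labels == "Tumor"
    mu[is_tumor, ] <- sweep(mu[is_tumor, , drop = FALSE], 2, tumor_mult, `*`)
    counts <- matrix(rnbinom(n * g, mu = mu, size = 1 / spec$dispersion),
                     nrow = n, ncol = g)
    cell_ids <- sprintf("%s_cell%04d", ds_name, seq_len(n))
    dimnames(counts) <- list(cell_ids, genes)
    totals <- rowSums(counts)
    totals[totals == 0] <- 1
    norm <- log2(1 + 1e4 * counts / totals)
    datasets[[d]] <- expression_dataset(
      norm, data.frame(cell_type = labels, stringsAsFactors = FALSE),
      counts = counts, dataset_name = ds_name)
  }
  names(datasets) <- vapply(datasets, function(d) d$dataset_name, character(1))
  structure(list(datasets = datasets,
                 truth = list(planted_up = planted_up,
                              planted_down = planted_down,
                              cnv_genes = cnv_genes,
                              cnv_segments = spec$cnv_segments,
                              positions = positions),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d dataset(s) of %d cells x %d genes; %d up / %d down markers planted, %d CNV genes\n",
              length(x$datasets), x$spec$n_cells, x$spec$n_genes,
              length(x$truth$planted_up), length(x$truth$planted_down),
              length(x$truth$cnv_genes)))
  invisible(x)
}

#' Flip a fixed fraction of labels uniformly at random
#'
#' @param labels Character or factor vector of binary labels.
#' @param flip_fraction Fraction in \[0, 1) of labels to flip; exactly
#'   `round(flip_fraction * length(labels))` cells are flipped.
#' @param seed RNG seed.
#' @return List: `labels` (corrupted), `flipped` (integer indices of the
#'   flipped cells).
#' @export
plant_label_noise <- function(labels, flip_fraction, seed = 1) {
  stopifnot(flip_fraction >= 0, flip_fraction < 1)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) > 2) stop("binary labels expected", call. = FALSE)
  n_flip <- round(flip_fraction * length(labels))
  if (n_flip == 0) return(list(labels = labels, flipped = integer(0)))
  set.seed(seed)
  idx <- sort(sample(length(labels), n_flip))
  other <- function(x) if (length(classes) == 2)
    ifelse(x == classes[1], classes[2], classes[1]) else x
  labels[idx] <- other(labels[idx])
  list(labels = labels, flipped = idx)
}
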