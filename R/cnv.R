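# Expression-inferred copy-number profiles and the self-supervised
# proofreading step. The profile is the documented core of expression-based
# CNV inference: genes ordered along the genome, low-expression genes
# dropped, log-normalized counts centered on a reference (normal) cell
# population, clipped, smoothed with a moving average along each chromosome
# (never across a chromosome boundary), and re-centered per cell by its
# median. HMM state calling and tumor subclustering are deliberately not
# part of this: the proofreading classifier consumes the continuous
# profile.

# centered moving average with truncated edges, applied column-block-wise;
# M is cells x genes for one chromosome
.runmean_block <- function(M, half) {
  g <- ncol(M)
  if (g == 1L || half == 0L) return(M)
  cs <- M
  for (j in 2:g) cs[, j] <- cs[, j - 1] + M[, j]
  lo <- pmax(seq_len(g) - half, 1L)
  hi <- pmin(seq_len(g) + half, g)
  out <- M
  for (j in seq_len(g)) {
    left <- if (lo[j] > 1L) cs[, lo[j] - 1L] else 0
    out[, j] <- (cs[, hi[j]] - left) / (hi[j] - lo[j] + 1L)
  }
  out
}

#' Infer smoothed per-cell copy-number profiles from expression
#'
#' @param dataset An [expression_dataset()] with a raw-count layer.
#' @param positions A [gene_positions()] table; only genes present in both
#'   the table and the dataset are used, in genome order.
#' @param reference_cells Character vector of cell ids (or logical vector)
#'   defining the baseline population (e.g. cells labeled normal); at
#'   least 10 required.
#' @param window Odd moving-average window in genes (default 101);
#'   chromosomes shorter than the window are smoothed with a truncated
#'   window (warning).
#' @param cutoff Genes with mean raw count below this are dropped before
#'   smoothing (default 0.1).
#' @return Object of class `cnv_profile`: list with `matrix` (cells x
#'   genome-ordered genes), `gene_order` (the retained position rows),
#'   `window`, `reference_cells`.
#' @export
infer_cnv_profile <- function(dataset, positions, reference_cells,
                              window = 101, cutoff = 0.1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$counts))
    stop("raw counts are required for CNV inference (counts layer missing)",
         call. = FALSE)
  if (window %% 2 != 1 || window < 1)
    stop("window must be an odd positive integer", call. = FALSE)
  if (is.logical(reference_cells))
    reference_cells <- dataset$cell_ids[reference_cells]
  reference_cells <- intersect(reference_cells, dataset$cell_ids)
  if (length(reference_cells) < 10)
    stop("at least 10 reference cells are required", call. = FALSE)
  pos <- positions[positions$gene %in% dataset$gene_symbols, , drop = FALSE]
  counts <- dataset$counts[, pos$gene, drop = FALSE]
  keep <- colMeans(counts) >= cutoff
  pos <- pos[keep, , drop = FALSE]
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) < 2)
    stop("fewer than 2 positioned genes survive the expression cutoff",
         call. = FALSE)
  # log-normalize the retained counts (library size over retained genes)
  totals <- rowSums(counts)
  totals[totals == 0] <- 1
  ln <- log2(1 + 1e4 * counts / totals)
  ref_mean <- colMeans(ln[dataset$cell_ids %in% reference_cells, ,
                          drop = FALSE])
  rel <- sweep(ln, 2, ref_mean)
  rel[rel > 3] <- 3; rel[rel < -3] <- -3
  half <- (window - 1) / 2
  chrom <- pos$chromosome
  if (any(table(chrom) < window))
    warning("chromosome(s) with fewer genes than the smoothing window; ",
            "using a truncated window there", call. = FALSE)
  smooth <- rel
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    smooth[, cols] <- .runmean_block(rel[, cols, drop = FALSE], half)
  }
  smooth <- smooth - apply(smooth, 1, median)
  structure(list(matrix = smooth, gene_order = pos,
                 window = as.integer(window),
                 reference_cells = reference_cells),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> %d cells x %d genome-ordered genes, window %d, %d reference cells\n",
              nrow(x$matrix), ncol(x$matrix), x$window,
              length(x$reference_cells)))
  invisible(x)
}

#' Per-cell mean and variance of the copy-number profile
#'
#' Tumor cells carrying genomic gains/losses show elevated mean and
#' variance of the smoothed profile relative to diploid cells — the
#' diagnostic separating misclassified tumor cells from true normals.
#'
#' @param profile A [infer_cnv_profile()] object.
#' @return `data.frame` with columns `cell_id`, `cnv_mean`, `cnv_var`.
#' @export
cnv_summary <- function(profile) {
  stopifnot(inherits(profile, "cnv_profile"))
  m <- profile$matrix
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (ncol(m) - 1)
  data.frame(cell_id = rownames(m), cnv_mean = as.numeric(mu),
             cnv_var = as.numeric(v), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Proofread labels with a self-supervised CNV classifier
#'
#' Trains a ridge logistic model of the pipeline's own (pseudo) labels on
#' the per-cell CNV profile, predicts on the same cells (a linear model is
#' assumed not to overfit this task), and flips a cell's label when the
#' CNV model assigns the opposite class a probability above
#' `flip_probability`. Concordant labels are never touched.
#'
#' @param profile A [infer_cnv_profile()] object.
#' @param pseudo_labels Per-cell labels (values in Normal/Tumor) covering
#'   all profile cells.
#' @param flip_probability Confidence required to flip (default 0.9; must
#'   be in (0.5, 1)).
#' @param penalty Ridge penalty (glmnet `lambda`) of the CNV logistic
#'   model, default 0.1. The profile has more features (genes) than cells,
#'   so an unpenalized fit can memorize the very pseudo-label errors the
#'   step is meant to repair; a moderate ridge makes the model rely on the
#'   population-level copy-number signal instead, while too strong a
#'   penalty compresses probabilities below any useful flip confidence.
#' @return List (class `proofread_result`): `labels` (corrected factor),
#'   `flips` (data.frame of flipped cells with probabilities),
#'   `probabilities` (cells x 2).
#' @export
cnv_proofread <- function(profile, pseudo_labels, flip_probability = 0.9,
                          penalty = 0.1) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (flip_probability <= 0.5 || flip_probability >= 1)
    stop("flip_probability must be in (0.5, 1)", call. = FALSE)
  labels <- as.character(pseudo_labels)
  m <- profile$matrix
  if (length(labels) != nrow(m))
    stop("pseudo_labels must cover all profile cells", call. = FALSE)
  y <- as.integer(labels == "Tumor")
  if (length(unique(y)) < 2) {
    warning("single-class pseudo-labels: proofreading skipped, labels unchanged",
            call. = FALSE)
    return(structure(list(
      labels = factor(labels, levels = c("Normal", "Tumor")),
      flips = data.frame(cell_id = character(0), from = character(0),
                         to = character(0), probability = numeric(0)),
      probabilities = NULL), class = "proofread_result"))
  }
  fit <- glmnet::glmnet(m, y, family = "binomial", alpha = 0,
                        lambda = penalty, standardize = FALSE,
                        thresh = 1e-9)
  p_tumor <- as.numeric(predict(fit, m, type = "response"))
  probs <- cbind(Normal = 1 - p_tumor, Tumor = p_tumor)
  rownames(probs) <- rownames(m)
  opposite <- ifelse(labels == "Tumor", "Normal", "Tumor")
  p_opp <- ifelse(labels == "Tumor", probs[, "Normal"], probs[, "Tumor"])
  flip <- p_opp > flip_probability
  corrected <- labels
  corrected[flip] <- opposite[flip]
  flips <- data.frame(cell_id = rownames(m)[flip], from = labels[flip],
                      to = opposite[flip], probability = p_opp[flip],
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(labels = factor(corrected, levels = c("Normal", "Tumor")),
                 flips = flips, probabilities = probs),
            class = "proofread_result")
}

#' @export
print.proofread_result <- function(x, ...) {
  cat(sprintf("<proofread_result> %d cells, %d label(s) flipped\n",
              length(x$labels), nrow(x$flips)))
  invisible(x)
}

#' Cross-cohort generalization of CNV-only classifiers
#'
#' A harness probing whether copy-number profiles alone transfer across
#' cohorts: a random-forest classifier is trained on each cohort's
#' expert-labeled profile (plus one on the first two cohorts merged) and
#' evaluated on every cohort, yielding a balanced-accuracy matrix whose
#' off-diagonal entries measure generalization.
#'
#' @param profiles List of [infer_cnv_profile()] objects over a shared gene
#'   order (columns are intersected).
#' @param labels List of per-cell label vectors (Normal/Tumor), parallel to
#'   `profiles`.
#' @param n_trees Random-forest size (default 200).
#' @param seed RNG seed for the forests.
#' @return Numeric matrix: rows = training cohorts (plus `merged_1_2`),
#'   columns = evaluation cohorts, entries = balanced accuracy.
#' @export
train_cnv_baseline <- function(profiles, labels, n_trees = 200, seed = 1) {
  if (length(profiles) < 2)
    stop("at least 2 cohorts are required", call. = FALSE)
  stopifnot(length(profiles) == length(labels))
  common <- Reduce(intersect, lapply(profiles, function(p) colnames(p$matrix)))
  if (length(common) < 2) stop("cohorts share fewer than 2 genes", call. = FALSE)
  xs <- lapply(profiles, function(p) p$matrix[, common, drop = FALSE])
  ys <- lapply(labels, function(l) factor(as.character(l),
                                          levels = c("Normal", "Tumor")))
  nms <- names(profiles)
  if (is.null(nms)) nms <- paste0("cohort", seq_along(profiles))
  train_sets <- as.list(seq_along(xs))
  names(train_sets) <- nms
  train_sets$merged_1_2 <- c(1L, 2L)
  out <- matrix(NA_real_, length(train_sets), length(xs),
                dimnames = list(names(train_sets), nms))
  set.seed(seed)
  for (ti in seq_along(train_sets)) {
    tr <- train_sets[[ti]]
    xtr <- do.call(rbind, xs[tr])
    ytr <- factor(unlist(lapply(ys[tr], as.character)),
                  levels = c("Normal", "Tumor"))
    if (length(unique(ytr)) < 2) {
      warning("training cohort '", names(train_sets)[ti],
              "' lacks both classes; skipped", call. = FALSE)
      next
    }
    rf <- randomForest::randomForest(xtr, ytr, ntree = n_trees)
    for (ei in seq_along(xs)) {
      if (length(unique(ys[[ei]])) < 2) next
      pred <- predict(rf, xs[[ei]])
      out[ti, ei] <- balanced_accuracy(ys[[ei]], pred)
    }
  }
  out
}
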