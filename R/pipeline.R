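# The user-facing model object tying the stages together, mirroring the
# fit/predict workflow: fit derives (or accepts) the gene signatures and
# trains the score classifier on the training datasets; predict scores a
# new dataset, applies the classifier, propagates labels over the
# signature-gene cell graph, and optionally proofreads them against
# inferred copy-number profiles.

#' Fit a tumor-cell classifier
#'
#' Step one of the workflow. Unless ready-made signatures are supplied,
#' tumor-enriched and tumor-depleted gene signatures are derived from the
#' annotated training datasets ([derive_signatures()]); every training
#' dataset is then scored against both signatures ([score_cells()]) and a
#' logistic classifier is fit on the pooled scores
#' ([fit_score_classifier()]). Scores are within-cell rank statistics, so
#' pooling needs no cross-dataset normalization.
#'
#' @param datasets A single [expression_dataset()] or a list of them.
#' @param label_column Annotation column holding cell-type labels.
#' @param tumor_label Label of the tumor class (default `"Tumor"`).
#' @param signatures Optional list with elements `tumor` and `normal`
#'   ([gene_signature()] objects, e.g. from [read_gmt()]); when given, the
#'   signature-derivation stage is skipped.
#' @param normal_labels,n_top,p_adj_threshold Passed to
#'   [derive_signatures()].
#' @param max_rank_fraction,min_coverage Passed to [score_cells()].
#' @param C Inverse ridge strength of the score classifier.
#' @return An object of class `tumor_classifier`: list with `signatures`,
#'   `classifier`, `label_column`, `tumor_label`, `scoring` (the scoring
#'   configuration), `training` (dataset names, cell counts, training
#'   balanced accuracy before propagation).
#' @export
tumor_classifier <- function(datasets, label_column, tumor_label = "Tumor",
                             signatures = NULL, normal_labels = NULL,
                             n_top = 300, p_adj_threshold = 0.1,
                             max_rank_fraction = 0.05, min_coverage = 0.8,
                             C = 1) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  if (is.null(signatures)) {
    signatures <- derive_signatures(datasets, label_column, tumor_label,
                                    normal_labels = normal_labels,
                                    n_top = n_top,
                                    p_adj_threshold = p_adj_threshold)
  } else {
    if (!all(c("tumor", "normal") %in% names(signatures)))
      stop("`signatures` must have elements 'tumor' and 'normal'",
           call. = FALSE)
  }
  score_list <- lapply(datasets, function(d)
    score_cells(d, signatures$tumor, signatures$normal,
                max_rank_fraction = max_rank_fraction,
                min_coverage = min_coverage))
  scores <- do.call(rbind, lapply(score_list, as.data.frame))
  labels <- unlist(lapply(datasets, function(d)
    .get_labels(d, label_column)))
  binary <- ifelse(labels == tumor_label, "Tumor", "Normal")
  clf <- fit_score_classifier(scores, binary, tumor_label = "Tumor", C = C)
  train_pred <- predict(clf, scores, type = "label")
  structure(list(
    signatures = signatures,
    classifier = clf,
    label_column = label_column,
    tumor_label = tumor_label,
    scoring = list(max_rank_fraction = max_rank_fraction,
                   min_coverage = min_coverage),
    training = list(
      dataset_names = vapply(datasets, function(d) d$dataset_name,
                             character(1)),
      n_cells = length(binary),
      n_per_class = table(binary),
      balanced_accuracy = balanced_accuracy(binary, train_pred))),
    class = "tumor_classifier")
}

#' @export
print.tumor_classifier <- function(x, ...) {
  cat("<tumor_classifier>\n")
  cat(sprintf("  tumor signature: %d genes; normal signature: %d genes\n",
              length(x$signatures$tumor), length(x$signatures$normal)))
  cat(sprintf("  trained on: %s (%d cells)\n",
              paste(x$training$dataset_names, collapse = ", "),
              x$training$n_cells))
  cat(sprintf("  training balanced accuracy (pre-propagation): %.3f\n",
              x$training$balanced_accuracy))
  invisible(x)
}

#' @export
summary.tumor_classifier <- function(object, ...) {
  print(object)
  cat("\nScore classifier:\n")
  print(object$classifier)
  invisible(object)
}

#' @export
coef.tumor_classifier <- function(object, ...) coef(object$classifier)

#' Predict tumor/normal labels on a new dataset
#'
#' Step two of the workflow: score the cells against the model's
#' signatures, evaluate the logistic classifier, propagate the class
#' probabilities over the signature-gene cell-cell graph with the decaying
#' stringency threshold, and (optionally) proofread the labels against
#' expression-inferred copy-number profiles, using the cells currently
#' labeled Normal as the reference population.
#'
#' @param object A [tumor_classifier()].
#' @param newdata An [expression_dataset()].
#' @param propagate Run network propagation (default `TRUE`).
#' @param cnv_correct Run copy-number proofreading (default `FALSE`;
#'   requires `positions` and a raw-count layer).
#' @param positions A [gene_positions()] table (needed when
#'   `cnv_correct = TRUE`).
#' @param k,n_pcs Graph parameters ([build_cell_graph()]).
#' @param q0,lambda,change_tol,max_iter Propagation parameters
#'   ([propagate_labels()]).
#' @param flip_probability,window,cutoff Proofreading parameters
#'   ([cnv_proofread()], [infer_cnv_profile()]).
#' @param ... Unused.
#' @return A `data.frame` with columns `cell_id`, `tumor_score`,
#'   `normal_score`, `normal_prob`, `tumor_prob`, `label`. Attributes:
#'   `n_iterations`, `N0`, `coverage`, and (with proofreading) `flips`.
#' @export
predict.tumor_classifier <- function(object, newdata, propagate = TRUE,
                                     cnv_correct = FALSE, positions = NULL,
                                     k = 30, n_pcs = 50, q0 = 0.9,
                                     lambda = 0.25, change_tol = 0.001,
                                     max_iter = 50, flip_probability = 0.9,
                                     window = 101, cutoff = 0.1, ...) {
  stopifnot(inherits(newdata, "expression_dataset"))
  scores <- score_cells(newdata, object$signatures$tumor,
                        object$signatures$normal,
                        max_rank_fraction = object$scoring$max_rank_fraction,
                        min_coverage = object$scoring$min_coverage)
  probs <- predict_proba(object$classifier, scores)
  n_iterations <- 0L; N0 <- NA_real_
  if (propagate) {
    graph <- build_cell_graph(newdata, object$signatures$tumor,
                              object$signatures$normal,
                              k = min(k, nrow(newdata$matrix) - 1L),
                              n_pcs = n_pcs)
    prop <- propagate_labels(probs, scores, graph, q0 = q0, lambda = lambda,
                             change_tol = change_tol, max_iter = max_iter)
    probs <- prop$probabilities
    labels <- prop$labels
    n_iterations <- prop$n_iterations
    N0 <- prop$N0
  } else {
    labels <- factor(c("Normal", "Tumor")[max.col(probs, ties.method = "first")],
                     levels = c("Normal", "Tumor"))
  }
  flips <- NULL
  if (cnv_correct) {
    if (is.null(positions))
      stop("`positions` is required for CNV proofreading", call. = FALSE)
    reference <- newdata$cell_ids[labels == "Normal"]
    profile <- infer_cnv_profile(newdata, positions, reference,
                                 window = window, cutoff = cutoff)
    proof <- cnv_proofread(profile, labels,
                           flip_probability = flip_probability)
    labels <- proof$labels
    flips <- proof$flips
  }
  out <- data.frame(cell_id = newdata$cell_ids,
                    tumor_score = scores$tumor_score,
                    normal_score = scores$normal_score,
                    normal_prob = probs[, 1], tumor_prob = probs[, 2],
                    label = labels, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "n_iterations") <- n_iterations
  attr(out, "N0") <- N0
  attr(out, "coverage") <- attr(scores, "coverage")
  if (!is.null(flips)) attr(out, "flips") <- flips
  out
}

#' Cross-validate dataset pairs for signature derivation
#'
#' For every unordered pair of datasets (and, optionally, every single
#' dataset), derives signatures and trains the classifier on the pair,
#' evaluates on each held-out dataset, and reports the minimum balanced
#' accuracy over the held-out sets — the worst-case generalization of that
#' training choice.
#'
#' @param datasets Named list of at least 3 [expression_dataset()] objects.
#' @param label_column,tumor_label See [tumor_classifier()].
#' @param include_single Also evaluate single-dataset training (default
#'   `TRUE`).
#' @param propagate Whether evaluation predictions use network propagation
#'   (default `TRUE`).
#' @param ... Passed to [tumor_classifier()].
#' @return `data.frame` with one row per training set: `train`,
#'   `n_train_datasets`, `min_balanced_accuracy`, `mean_balanced_accuracy`.
#' @export
crossvalidate_pairs <- function(datasets, label_column,
                                tumor_label = "Tumor",
                                include_single = TRUE, propagate = TRUE,
                                ...) {
  if (length(datasets) < 3)
    stop("configuration error: at least 3 datasets are required ",
         "(>= 1 must be held out)", call. = FALSE)
  nms <- names(datasets)
  if (is.null(nms))
    nms <- vapply(datasets, function(d) d$dataset_name, character(1))
  combos <- utils::combn(seq_along(datasets), 2, simplify = FALSE)
  if (include_single)
    combos <- c(as.list(seq_along(datasets)), combos)
  rows <- lapply(combos, function(tr) {
    model <- tumor_classifier(datasets[tr], label_column,
                              tumor_label = tumor_label, ...)
    held <- setdiff(seq_along(datasets), tr)
    accs <- vapply(held, function(h) {
      pred <- predict(model, datasets[[h]], propagate = propagate)
      truth <- ifelse(.get_labels(datasets[[h]], label_column) == tumor_label,
                      "Tumor", "Normal")
      balanced_accuracy(truth, pred$label)
    }, numeric(1))
    data.frame(train = paste(nms[tr], collapse = "+"),
               n_train_datasets = length(tr),
               min_balanced_accuracy = min(accs),
               mean_balanced_accuracy = mean(accs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signature ablation harness
#'
#' Measures how classification accuracy degrades when genes are removed
#' from the tumor signature before scoring and prediction: either a random
#' fraction of the list (repeated `n_repeats` times) or a specified set of
#' genes (deterministic). The trained classifier and the evaluation run
#' (scoring, classification, propagation — no CNV correction) are otherwise
#' unchanged.
#'
#' @param model A fitted [tumor_classifier()].
#' @param dataset Annotated evaluation [expression_dataset()].
#' @param mode `"fraction"` (remove a random fraction per repeat) or
#'   `"single_gene"` (remove the specified `genes`).
#' @param fraction Fraction of the tumor signature to remove in
#'   `"fraction"` mode (in \[0, 1)); 0 reproduces the unablated run.
#' @param genes Gene(s) to remove in `"single_gene"` mode; every one must
#'   be in the signature.
#' @param n_repeats Repeats per setting (default 25).
#' @param seed RNG seed for the random removals.
#' @param propagate Use network propagation in evaluation (default `TRUE`).
#' @return `data.frame` with columns `repeat_id`, `n_removed`,
#'   `balanced_accuracy`.
#' @export
ablate_signature <- function(model, dataset, mode = c("fraction",
                                                      "single_gene"),
                             fraction = NULL, genes = NULL, n_repeats = 25,
                             seed = 1, propagate = TRUE) {
  stopifnot(inherits(model, "tumor_classifier"))
  mode <- match.arg(mode)
  sig <- model$signatures$tumor
  truth <- ifelse(.get_labels(dataset, model$label_column) ==
                    model$tumor_label, "Tumor", "Normal")
  if (mode == "fraction") {
    stopifnot(!is.null(fraction), fraction >= 0, fraction < 1)
    n_remove <- round(fraction * length(sig$genes))
  } else {
    stopifnot(!is.null(genes))
    missing <- setdiff(genes, sig$genes)
    if (length(missing))
      stop("gene(s) not in the tumor signature: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    n_remove <- length(genes)
    n_repeats <- 1L
  }
  if (length(sig$genes) - n_remove < 1)
    stop("ablation would leave fewer than 1 gene in the signature",
         call. = FALSE)
  set.seed(seed)
  rows <- lapply(seq_len(n_repeats), function(r) {
    removed <- if (mode == "fraction") {
      if (n_remove > 0) sample(sig$genes, n_remove) else character(0)
    } else genes
    kept <- setdiff(sig$genes, removed)
    m2 <- model
    m2$signatures$tumor <- gene_signature(sig$name, kept, sig$direction,
                                          sig$provenance)
    pred <- predict(m2, dataset, propagate = propagate)
    data.frame(repeat_id = r, n_removed = n_remove,
               balanced_accuracy = balanced_accuracy(truth, pred$label))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
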