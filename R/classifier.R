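# Logistic classifier on the two signature scores. Scores are within-cell
# rank statistics, so datasets scored independently can be concatenated for
# training without any cross-dataset normalization.

#' Fit the score classifier
#'
#' Maximum-likelihood logistic regression of the binary tumor/normal label
#' on `(tumor_score, normal_score)`, with a weak ridge penalty for
#' numerical stability (inverse strength `C`, default 1; penalty
#' `lambda = 1 / (C * n)` on the glmnet scale, intercept unpenalized).
#' Class order is fixed as (Normal, Tumor): the tumor probability is always
#' the second column downstream.
#'
#' @param scores A [score_cells()] table (or data.frame with `tumor_score`
#'   and `normal_score` columns).
#' @param labels Per-cell labels; anything equal to `tumor_label` is the
#'   positive class.
#' @param tumor_label Label denoting tumor cells (default `"Tumor"`).
#' @param C Inverse regularization strength (default 1).
#' @return An object of class `score_classifier` with elements
#'   `coefficients` (intercept, tumor_score, normal_score), `classes`,
#'   `training_metadata`.
#' @export
fit_score_classifier <- function(scores, labels, tumor_label = "Tumor",
                                 C = 1) {
  x <- as.matrix(scores[, c("tumor_score", "normal_score")])
  if (anyNA(x) || any(!is.finite(x)))
    stop("validation error: scores contain missing or non-finite values",
         call. = FALSE)
  y <- as.integer(as.character(labels) == tumor_label)
  if (length(y) != nrow(x)) stop("labels/scores length mismatch", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("degenerate target: all labels belong to a single class",
         call. = FALSE)
  n <- nrow(x)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 1 / (C * n), standardize = FALSE,
                        thresh = 1e-12)
  beta <- as.numeric(coef(fit))
  names(beta) <- c("(Intercept)", "tumor_score", "normal_score")
  structure(list(
    coefficients = beta,
    classes = c("Normal", "Tumor"),
    training_metadata = list(
      n_cells = n,
      n_per_class = c(Normal = sum(y == 0), Tumor = sum(y == 1)),
      C = C, penalty = "ridge", lambda = 1 / (C * n))),
    class = "score_classifier")
}

#' @export
print.score_classifier <- function(x, ...) {
  cat("<score_classifier> logistic model P(Tumor | tumor_score, normal_score)\n")
  print(round(x$coefficients, 4))
  md <- x$training_metadata
  cat(sprintf("  trained on %d cells (%d Normal, %d Tumor), ridge C = %g\n",
              md$n_cells, md$n_per_class[["Normal"]],
              md$n_per_class[["Tumor"]], md$C))
  invisible(x)
}

#' @export
coef.score_classifier <- function(object, ...) object$coefficients

#' Class probabilities from a fitted score classifier
#'
#' Direct evaluation of the fitted linear predictor through the logistic
#' function; rows sum to 1 exactly.
#'
#' @param model A [fit_score_classifier()] object.
#' @param scores A score table with `tumor_score` and `normal_score`
#'   columns.
#' @return Numeric matrix (cells x 2) with columns `Normal`, `Tumor`.
#' @export
predict_proba <- function(model, scores) {
  stopifnot(inherits(model, "score_classifier"))
  need <- c("tumor_score", "normal_score")
  if (!all(need %in% colnames(scores)))
    stop("feature mismatch: scores must contain tumor_score and normal_score",
         call. = FALSE)
  x <- as.matrix(scores[, need])
  eta <- model$coefficients[1] + x %*% model$coefficients[-1]
  p_tumor <- plogis(as.numeric(eta))
  out <- cbind(Normal = 1 - p_tumor, Tumor = p_tumor)
  rownames(out) <- if ("cell_id" %in% colnames(scores))
    as.character(scores$cell_id) else rownames(scores)
  out
}

#' @export
predict.score_classifier <- function(object, newdata, type = c("label", "prob"),
                                     ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' Balanced accuracy
#'
#' Mean of per-class recalls, robust to class imbalance (a constant
#' prediction on binary truth scores 0.5 regardless of the imbalance).
#'
#' @param truth,predicted Vectors of the same length; every class present
#'   in `truth` must be represented there (a truth class with no cells is
#'   undefined).
#' @return Numeric scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length", call. = FALSE)
  classes <- sort(unique(truth))
  if (length(classes) < 2)
    stop("undefined class: truth contains fewer than 2 classes", call. = FALSE)
  recalls <- vapply(classes, function(cls) {
    mean(predicted[truth == cls] == cls)
  }, numeric(1))
  mean(recalls)
}

#' Persist / restore a score classifier as JSON
#'
#' @param model A `score_classifier`.
#' @param path File path.
#' @return `path` invisibly; `read_score_classifier` returns the model.
#' @export
write_score_classifier <- function(model, path) {
  stopifnot(inherits(model, "score_classifier"))
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients),
         classes = model$classes,
         training_metadata = model$training_metadata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_classifier
#' @export
read_score_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(obj$coefficients),
                 classes = obj$classes,
                 training_metadata = obj$training_metadata),
            class = "score_classifier")
}
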