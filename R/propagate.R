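# Iterative label propagation over the cell-cell graph with a decaying
# stringency threshold. Cells whose |tumor - normal| score difference falls
# below the current threshold N(t) = N0 * exp(-lambda * t) have both class
# probabilities masked to zero; the surviving confident cells seed a
# connectivity-weighted update (dot product of the graph with the masked
# probabilities), and the loop runs until fewer than change_tol of cell
# annotations change. The threshold decays from a fixed N0 (the q0-quantile
# of the score difference at t = 0), so the set of unmasked seed cells can
# only grow over iterations.

#' Initial stringency threshold
#'
#' The empirical `q0`-quantile (linear interpolation between order
#' statistics, R's default type 7) of the per-cell tumor minus normal
#' score difference.
#'
#' @param scores A [score_cells()] table.
#' @param q0 Quantile (default 0.9).
#' @return Numeric scalar `N0`.
#' @export
initial_stringency <- function(scores, q0 = 0.9) {
  d <- scores$tumor_score - scores$normal_score
  if (anyNA(d) || any(!is.finite(d)))
    stop("scores must be finite", call. = FALSE)
  as.numeric(quantile(d, probs = q0, type = 7, names = FALSE))
}

#' Propagate class probabilities over the cell graph
#'
#' @param probabilities Cells x 2 matrix of class probabilities (columns
#'   Normal, Tumor), rows summing to 1.
#' @param scores The [score_cells()] table the masking statistic is
#'   computed from.
#' @param graph A [build_cell_graph()] object for the same cells.
#' @param q0 Quantile defining the starting threshold `N0` (default 0.9).
#' @param lambda Exponential decay constant of the stringency threshold
#'   (default 0.25 per iteration; must be > 0).
#' @param change_tol Stop when the fraction of cells changing label falls
#'   below this (default 0.001, i.e. 0.1%).
#' @param max_iter Iteration cap (default 50); reaching it emits a warning
#'   with the final changed fraction.
#' @return A list (class `propagation_result`): `labels` (factor
#'   Normal/Tumor), `probabilities` (propagated, renormalized),
#'   `n_iterations`, `N0`, `thresholds`, `changed_trajectory`.
#' @export
propagate_labels <- function(probabilities, scores, graph, q0 = 0.9,
                             lambda = 0.25, change_tol = 0.001,
                             max_iter = 50) {
  stopifnot(inherits(graph, "cell_graph"))
  if (lambda <= 0)
    stop("configuration error: lambda must be > 0", call. = FALSE)
  probs <- as.matrix(probabilities)
  if (ncol(probs) != 2) stop("probabilities must have 2 columns", call. = FALSE)
  n <- nrow(probs)
  if (nrow(graph$connectivities) != n)
    stop("graph and probabilities disagree on cell count", call. = FALSE)
  if (max(abs(rowSums(probs) - 1)) > 1e-6)
    stop("probability rows must sum to 1", call. = FALSE)
  d <- scores$tumor_score - scores$normal_score
  N0 <- initial_stringency(scores, q0)
  W <- graph$connectivities
  labels <- max.col(probs, ties.method = "first")
  current <- probs
  thresholds <- numeric(0); changed_traj <- numeric(0)
  t <- 0L; converged <- FALSE
  while (t < max_iter) {
    Nt <- N0 * exp(-lambda * t)
    thresholds <- c(thresholds, Nt)
    masked <- current
    masked[abs(d) < Nt, ] <- 0
    prop <- as.matrix(W %*% masked)
    rs <- rowSums(prop)
    zero <- rs <= 0
    if (any(!zero)) prop[!zero, ] <- prop[!zero, ] / rs[!zero]
    # isolated / fully masked neighborhoods keep their previous state
    prop[zero, ] <- current[zero, ]
    new_labels <- max.col(prop, ties.method = "first")
    tie <- prop[, 1] == prop[, 2]
    new_labels[tie] <- labels[tie]
    changed <- mean(new_labels != labels)
    changed_traj <- c(changed_traj, changed)
    labels <- new_labels
    current <- prop
    t <- t + 1L
    if (changed < change_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "propagation hit max_iter = %d with changed fraction %.4f",
      max_iter, changed_traj[length(changed_traj)]), call. = FALSE)
  rownames(current) <- rownames(probs)
  structure(list(
    labels = factor(c("Normal", "Tumor")[labels],
                    levels = c("Normal", "Tumor")),
    probabilities = current,
    n_iterations = t, N0 = N0, thresholds = thresholds,
    changed_trajectory = changed_traj, converged = converged),
    class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "<propagation_result> %d cells, %d iteration(s), N0 = %.4f, %s\n",
    length(x$labels), x$n_iterations, x$N0,
    if (x$converged) "converged" else "max_iter reached"))
  print(table(x$labels))
  invisible(x)
}
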